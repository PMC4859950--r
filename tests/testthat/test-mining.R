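test_that("Shannon's index matches its analytic values", {
  expect_equal(shannon_index(c(100, 100)), log(2))
  expect_equal(shannon_index(c(7, 7, 7)), log(3))
  expect_equal(shannon_index(50), 0)
  expect_equal(shannon_index(numeric(0)), 0)
  # a spurious light edge barely moves the score
  expect_lt(abs(shannon_index(c(100, 100, 0.1)) - log(2)), 0.02)
  expect_error(shannon_index(c(1, -1)), "positive")
})

test_that("Shannon's index attains ln(n) on even weights and is invariant", {
  for (n in 1:50)
    expect_equal(shannon_index(rep(13.7, n)), if (n > 1) log(n) else 0,
                 tolerance = 1e-12)
  set.seed(8)
  for (i in 1:20) {
    w <- stats::runif(sample(2:12, 1), 0.1, 100)
    expect_equal(shannon_index(sample(w)), shannon_index(w))
    expect_equal(shannon_index(w * stats::runif(1, 0.01, 50)),
                 shannon_index(w))
    expect_lte(shannon_index(w), log(length(w)) + 1e-12)
  }
})

# minimal hybrid-graph stub for mining functions
mini_hg <- function(edges, n, contig_len = rep(1000L, n)) {
  structure(list(nodes = data.frame(id = seq_len(n), source_level = 1L,
                                    level_node = seq_len(n),
                                    contig_len = contig_len,
                                    n_reads = 1L,
                                    trimmed = rep(FALSE, n)),
                 contigs = rep(strrep("A", 10), n),
                 member_reads = as.list(seq_len(n)),
                 edges = edges, n_nodes = n, read_ids = NULL),
            class = "hybrid_graph")
}

test_that("node scoring uses incident edge weights", {
  hg <- mini_hg(data.frame(u = c(1, 2), v = c(2, 3), w = c(10, 10)), 4)
  sc <- score_all(hg)
  expect_equal(sc$H[sc$node == 2], log(2))   # path-internal, equal weights
  expect_equal(sc$H[sc$node == 1], 0)        # single edge
  expect_equal(sc$H[sc$node == 4], 0)        # isolated
  expect_equal(sc$n_edges, c(1L, 2L, 1L, 0L))
})

test_that("high-node selection applies score, tag and edge-weight filters", {
  # node 1: tagged, H > 1, heavy edges; node 2: tagged, H > 1, light edges;
  # node 3: H > 1 but untagged; node 4: tagged, single edge (H = 0)
  hg <- mini_hg(data.frame(u = c(1, 1, 1, 2, 2, 2, 3, 3, 3, 4),
                           v = c(5, 6, 7, 8, 9, 10, 11, 12, 13, 14),
                           w = c(6000, 5000, 4000, 30, 30, 25, 10, 10, 10,
                                 100)), 14)
  sc <- score_all(hg)
  ann <- data.frame(node = c(1, 2, 4), tag = "transposase")
  expect_true(all(sc$H[sc$node %in% 1:3] > 1))
  sel <- select_high_nodes(sc, ann, hg, threshold = 1.0)
  expect_equal(sel, c(1, 2))
  # the minimum-edge-weight coverage filter removes weakly covered nodes
  sel2 <- select_high_nodes(sc, ann, hg, threshold = 1.0,
                            min_edge_weight_filter = 5000)
  expect_equal(sel2, 1)
})

test_that("taxonomy vectors are length-weighted neighbor shares", {
  hg <- mini_hg(data.frame(u = c(1, 1), v = c(2, 3), w = c(10, 10)), 3,
                contig_len = c(100L, 1000L, 1000L))
  taxa <- data.frame(node = 2:3, genus = c("A", "B"))
  v <- tax_vector(1, hg, taxa)
  expect_equal(unname(v$x[c("A", "B")]), c(0.5, 0.5))
  expect_equal(v$unknown_frac, 0)

  hg2 <- mini_hg(data.frame(u = c(1, 1), v = c(2, 3), w = c(10, 10)), 3,
                 contig_len = c(100L, 3000L, 1000L))
  v2 <- tax_vector(1, hg2, taxa)
  expect_equal(unname(v2$x[c("A", "B")]), c(0.75, 0.25))

  # unknown labels feed unknown_frac
  taxa3 <- data.frame(node = 2:3, genus = c("A", "unknown"))
  v3 <- tax_vector(1, hg2, taxa3)
  expect_equal(v3$unknown_frac, 0.25)
  expect_equal(sum(v3$x) + v3$unknown_frac, 1)

  expect_error(tax_vector(3, mini_hg(data.frame(u = 1, v = 2, w = 1), 3),
                          taxa), "no neighbors")
})

test_that("k-means clustering separates distinct profiles deterministically", {
  mk <- function(node, a, b) list(node = node,
                                  x = c(A = a, B = b), unknown_frac = 0)
  vecs <- c(lapply(1:5, function(i) mk(i, 1 - i / 100, i / 100)),
            lapply(6:10, function(i) mk(i, i / 100, 1 - i / 100)))
  cl <- cluster_transposase_nodes(vecs, k = 2, seed = 4)
  a1 <- cl$assignment[as.character(1:5)]
  a2 <- cl$assignment[as.character(6:10)]
  expect_equal(length(unique(a1)), 1)
  expect_equal(length(unique(a2)), 1)
  expect_true(a1[1] != a2[1])
  # identical seeds give identical output
  cl2 <- cluster_transposase_nodes(vecs, k = 2, seed = 4)
  expect_identical(cl$assignment, cl2$assignment)
  # k = 1: everything together, WSS = total variance
  cl1 <- cluster_transposase_nodes(vecs, k = 1, seed = 4)
  expect_equal(length(unique(cl1$assignment)), 1)
  m <- ogmine:::.tax_matrix(vecs)
  expect_equal(cl1$elbow$wss[1], sum(scale(m, scale = FALSE)^2))
  # WSS is non-increasing in k
  expect_true(all(diff(cl1$elbow$wss) <= 1e-9))

  # the unknown-fraction cap excludes vectors
  vecs2 <- c(vecs, list(list(node = 11, x = c(A = 0.3, B = 0.3),
                             unknown_frac = 0.4)))
  cl3 <- cluster_transposase_nodes(vecs2, k = 2, seed = 4)
  expect_equal(cl3$excluded, 11)
  expect_false("11" %in% names(cl3$assignment))
  expect_error(cluster_transposase_nodes(vecs[1:2], k = 5, seed = 1),
               "fewer eligible")
})

test_that("k-neighborhoods are breadth-first balls", {
  path <- mini_hg(data.frame(u = 1:6, v = 2:7, w = 1), 7)
  expect_equal(k_neighborhood(path, 1, 5), 1:6)
  expect_equal(k_neighborhood(path, 1, 0), 1)
  expect_equal(k_neighborhood(path, 4, 2), 2:6)

  set.seed(15)
  for (trial in 1:5) {
    n <- sample(10:30, 1)
    e <- rand_graph_edges(n, 0.12)
    if (nrow(e) == 0) next
    hg <- mini_hg(e, n)
    for (k in 0:4) {
      center <- sample(n, 1)
      expect_equal(k_neighborhood(hg, center, k),
                   oracle_k_neighborhood(seq_len(n), e, center, k))
    }
  }
})

test_that("Fisher enrichment matches hypergeometric tails with BH control", {
  # implementation vs direct tail summation on random 2x2 tables
  set.seed(19)
  for (i in 1:50) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c_ <- sample(0:30, 1); d <- sample(5:400, 1)
    if (a + c_ == 0) a <- 1
    p_impl <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                                 alternative = "greater")$p.value
    expect_equal(p_impl, oracle_fisher_greater(a, b, c_, d),
                 tolerance = 1e-9)
  }

  # end-to-end report on a toy graph: class X concentrated near node 1
  hg <- mini_hg(data.frame(u = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                           v = c(2, 3, 4, 5, 6, 7, 8, 9, 10), w = 1), 10)
  hits <- data.frame(node = c(1, 2, 3, 6, 7, 8, 9, 10, 4, 5),
                     class = c("X", "X", "X", rep("Y", 5), "Y", "Y"))
  assign <- stats::setNames(1L, "1")
  rep1 <- enrichment_test(assign, hg, hits, radius = 2)
  x <- rep1[rep1$class == "X", ]
  expect_equal(x$in_class, 3)    # nodes 1,2,3 within radius 2
  expect_equal(x$out_class, 0)
  expect_true(x$p < 0.2)
  expect_true(all(rep1$q >= rep1$p))
  # q-values are non-decreasing when ordered by p
  o <- order(rep1$p)
  expect_true(all(diff(rep1$q[o]) >= -1e-12))
})

test_that("two transposon carrier groups are recovered by clustering", {
  # four genomes; one element shared by genomes 1-2, a different element
  # shared by genomes 3-4; resistance linked to the first group only
  cc <- community_config(n_genomes = 4, genome_len = 12000,
                         transposon_carriers = list(c(1, 2), c(3, 4)),
                         resistance_carriers = list(c(1, 2)),
                         n_control = 2, control_clearance = 2500,
                         coverage = 10, seed = 91)
  com <- simulate_community(cc)
  el <- com$elements
  tn <- el[el$kind == "transposon", ]
  expect_equal(nrow(tn), 4)
  # distinct sequences between groups, identical within
  seq_of <- function(i) substr(com$genomes[[tn$genome[i]]],
                               tn$start[i] + 1, tn$end[i])
  expect_identical(seq_of(1), seq_of(2))
  expect_identical(seq_of(3), seq_of(4))
  expect_false(seq_of(1) == seq_of(3))

  sr <- sample_reads(com)
  res <- run_pipeline(sr$reads, coarsen = coarsen_config(min_density = 4))
  hg <- res$hybrid
  ann <- truth_annotations(com, sr$truth, hg)
  sc <- hg$scores
  hi <- select_high_nodes(sc, ann$tags, hg, tag = "transposase",
                          threshold = 1.0)
  expect_gte(length(hi), 2)

  # ground-truth group of each high node from its member reads
  truth_group <- vapply(hi, function(i) {
    ids <- sub("/rc$", "", hg$read_ids[hg$member_reads[[i]]])
    tr <- sr$truth[match(ids, sr$truth$id), ]
    ov <- vapply(seq_len(nrow(tn)), function(j) {
      sel <- tr$genome == tn$genome[j]
      if (!any(sel)) return(0)
      sum(vapply(tr$start[sel], ogmine:::.wrap_overlap, numeric(1),
                 rl = 100L, a = tn$start[j], b = tn$end[j], L = 12000L))
    }, numeric(1))
    by_grp <- tapply(ov, tn$class, sum)
    names(by_grp)[which.max(by_grp)]
  }, character(1))

  vecs <- lapply(hi, tax_vector, hg = hg, contig_taxa = ann$taxa)
  cl <- cluster_transposase_nodes(vecs, k = 2, seed = 91)
  got <- cl$assignment[as.character(hi)]
  # pairwise Rand index between clustering and carrier-group truth
  pairs <- utils::combn(length(hi), 2)
  same_got <- got[pairs[1, ]] == got[pairs[2, ]]
  same_want <- truth_group[pairs[1, ]] == truth_group[pairs[2, ]]
  rand <- mean(same_got == same_want)
  expect_gte(rand, 0.9)
})
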