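# subgraph shorthand: integer nodes with weighted (optionally typed) edges
sub_of <- function(u, v, w, type = NULL, nodes = NULL) {
  e <- data.frame(u = u, v = v, w = w)
  if (!is.null(type)) e$type <- type
  list(nodes = if (is.null(nodes)) sort(unique(c(u, v))) else nodes, edges = e)
}

test_that("cleaning removes spurs, lighter bubble paths and transitive edges", {
  # 5-node path with a 1-node spur hanging off node 3
  sp <- sub_of(c(1, 2, 3, 4, 3), c(2, 3, 4, 5, 6), c(50, 50, 50, 50, 10))
  out <- clean_subgraph(sp)
  expect_setequal(out$nodes, 1:5)
  expect_true(is_single_path(out))

  # short genuine arms at a junction are not eaten when the spur goes first
  sp2 <- sub_of(c(1, 2, 3, 3), c(2, 3, 4, 5), c(50, 50, 50, 10))
  out2 <- clean_subgraph(sp2)
  expect_setequal(out2$nodes, c(1, 2, 3, 4))

  # bubble between 1 and 4 via {2,3} (weights 30+30+30) and via {5,6}
  # (20+20+20), embedded in a path with arms longer than the tip bound;
  # the lighter interior {5,6} is deleted
  bb <- sub_of(c(1, 2, 3, 1, 5, 6, 7, 8, 9, 10, 4, 11, 12, 13),
               c(2, 3, 4, 5, 6, 4, 8, 9, 10, 1, 11, 12, 13, 14),
               c(30, 30, 30, 20, 20, 20, rep(30, 8)))
  outb <- clean_subgraph(bb)
  expect_setequal(outb$nodes, setdiff(1:14, c(5, 6)))
  expect_true(is_single_path(outb))

  # consistent-overlap triangle: the weakest edge (1,3) is transitive
  tri <- sub_of(c(1, 2, 1), c(2, 3, 3), c(80, 80, 60))
  outt <- clean_subgraph(tri)
  expect_equal(nrow(outt$edges), 2)
  expect_false(any(outt$edges$u == 1 & outt$edges$v == 3))
})

test_that("transitive reduction matches the brute-force oracle", {
  set.seed(13)
  for (trial in 1:15) {
    n <- sample(4:8, 1)
    e <- rand_graph_edges(n, 0.5)
    if (nrow(e) == 0) next
    sub <- list(nodes = seq_len(n), edges = e)
    got <- ogmine:::.reduce_transitive(sub)$edges
    want <- oracle_transitive_reduction(e)
    key <- function(d) sort(paste(d$u, d$v, d$w))
    expect_equal(key(got), key(want))
  }
})

test_that("the single-path test accepts paths and rejects everything else", {
  expect_true(is_single_path(sub_of(c(1, 2, 3), c(2, 3, 4), 10)))
  expect_true(is_single_path(list(nodes = 7,
                                  edges = data.frame(u = integer(0),
                                                     v = integer(0),
                                                     w = numeric(0)))))
  # star with three leaves
  expect_false(is_single_path(sub_of(c(1, 1, 1), c(2, 3, 4), 10)))
  # two disconnected 2-paths
  expect_false(is_single_path(sub_of(c(1, 3), c(2, 4), 10)))
  # cycle
  expect_false(is_single_path(sub_of(c(1, 2, 3), c(2, 3, 1), 10)))
})

test_that("contig assembly splices reads along the path", {
  reads <- read_set(c("x", "y"), c("AAAACGT", "ACGTCCC"))
  # overlap of 4 ("ACGT"), x left of y (type 0 with u = x)
  sub <- sub_of(1, 2, 4, type = 0L)
  expect_equal(assemble_contig(sub, reads), "AAAACGTCCC")

  # single node: the read itself
  expect_equal(assemble_contig(list(nodes = 2, edges = sub$edges[0, ]), reads),
               "ACGTCCC")

  # error-free tile set over a 1 kb genome reconstructs it exactly
  set.seed(17)
  genome <- rand_dna(1000)
  starts <- seq(1, 901, by = 20)
  tiles <- read_set(sprintf("t%02d", seq_along(starts)),
                    substring(genome, starts, starts + 99))
  e <- all_vs_all_overlaps(tiles, align_config())
  g0 <- build_overlap_graph(e, tiles$id)
  sub0 <- list(nodes = seq_len(g0$n_nodes), edges = g0$edges)
  cleaned <- clean_subgraph(sub0)
  expect_true(is_single_path(cleaned))
  expect_equal(assemble_contig(cleaned, tiles), genome)
})

test_that("representative selection partitions reads and picks high levels", {
  set.seed(23)
  genome <- rand_dna(800)
  starts <- seq(1, 701, by = 10)
  tiles <- read_set(sprintf("t%02d", seq_along(starts)),
                    substring(genome, starts, starts + 99))
  e <- all_vs_all_overlaps(tiles, align_config())
  g0 <- build_overlap_graph(e, tiles$id)
  lv <- coarsen_all(g0, coarsen_config(min_density = 0))
  hg <- select_representatives(lv, tiles)
  # partition property
  expect_equal(sort(unlist(hg$member_reads)), seq_len(g0$n_nodes))
  # one clean genome: a single representative from the top level
  expect_equal(hg$n_nodes, 1)
  expect_equal(hg$nodes$source_level, lv[[length(lv)]]$level)
  expect_equal(hg$contigs, genome)
})

test_that("hybrid trimming removes contained contigs and transitive edges", {
  hg <- structure(list(
    nodes = data.frame(id = 1:3, source_level = 1L, level_node = 1:3,
                       contig_len = c(2000L, 150L, 2000L),
                       n_reads = c(20L, 2L, 20L)),
    contigs = c(paste0(strrep("AC", 900), strrep("GT", 100)), NA, NA),
    member_reads = list(1:20, 21:22, 23:42),
    edges = data.frame(u = c(1, 2, 1), v = c(2, 3, 3), w = c(500, 400, 300)),
    n_nodes = 3L, hybrid_levels = list(), read_ids = NULL),
    class = "hybrid_graph")
  # node 2's contig is an exact substring of node 1's
  hg$contigs[2] <- substr(hg$contigs[1], 101, 250)
  hg$contigs[3] <- paste0(strrep("TG", 500), strrep("CA", 500))
  out <- trim_hybrid(hg, clean_config(max_containment_len = 200))
  expect_true(out$nodes$trimmed[2])
  expect_false(any(out$nodes$trimmed[c(1, 3)]))
  expect_false(any(out$edges$u == 2 | out$edges$v == 2))

  # identical-length non-contained contigs are both kept
  hg2 <- hg
  hg2$contigs <- c(rand_dna(180, seed = 5), rand_dna(180), rand_dna(180))
  hg2$nodes$contig_len <- rep(180L, 3)
  out2 <- trim_hybrid(hg2, clean_config(max_containment_len = 200))
  expect_false(any(out2$nodes$trimmed))

  # no transitive edges remain after trimming (brute-force check)
  out3 <- trim_hybrid(hg2, clean_config())
  want <- oracle_transitive_reduction(hg2$edges)
  expect_equal(nrow(out3$edges), nrow(want))
})
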