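#' Shannon's index of a weight distribution
#'
#' `H = -sum (w_i/W) ln(w_i/W)` with `W = sum w_i`, over the incident edge
#' weights of a node. Captures both edge richness and the evenness of the
#' weight distribution; the maximum for `n` edges is `ln(n)`. Returns 0 for a
#' node with at most one edge.
#'
#' @param weights positive numeric vector of incident edge weights (possibly
#'   empty, e.g. an isolated node).
#' @return the Shannon's index score (nats).
#' @export
shannon_index <- function(weights) {
  if (length(weights) <= 1L) return(0)
  if (any(weights <= 0)) stop("edge weights must be positive")
  p <- weights / sum(weights)
  -sum(p * log(p))
}

#' Score every hybrid-graph node with Shannon's index
#'
#' @param hg a `hybrid_graph` (ideally trimmed). Trimmed-away nodes are
#'   skipped.
#' @return data.frame with `node`, `n_edges` and `H`.
#' @export
score_all <- function(hg) {
  alive <- if (!is.null(hg$nodes$trimmed)) !hg$nodes$trimmed else
    rep(TRUE, hg$n_nodes)
  ids <- hg$nodes$id[alive]
  wlist <- .incident_weights(hg, ids)
  data.frame(node = ids,
             n_edges = lengths(wlist),
             H = vapply(wlist, shannon_index, numeric(1)))
}

.incident_weights <- function(hg, ids) {
  e <- hg$edges
  node <- c(e$u, e$v); w <- c(e$w, e$w)
  sp <- split(w, factor(node, levels = ids))
  lapply(sp, as.numeric)
}

#' Select high-diversity annotated nodes
#'
#' Nodes whose Shannon's index exceeds `threshold`, that carry `tag` in the
#' annotation table, and (optionally) have at least one incident edge of
#' weight `min_edge_weight_filter` (a coverage filter).
#'
#' @param scores output of [score_all()].
#' @param annotations data.frame with columns `node` and `tag`.
#' @param hg the `hybrid_graph` (needed when `min_edge_weight_filter` is set).
#' @param tag annotation tag to require (default `"transposase"`).
#' @param threshold minimum Shannon's index (exclusive); default 1.
#' @param min_edge_weight_filter optional minimum incident edge weight.
#' @return integer vector of selected node ids.
#' @export
select_high_nodes <- function(scores, annotations, hg = NULL,
                              tag = "transposase", threshold = 1.0,
                              min_edge_weight_filter = NULL) {
  tagged <- unique(annotations$node[annotations$tag == tag])
  sel <- scores$node[scores$H > threshold & scores$node %in% tagged]
  if (!is.null(min_edge_weight_filter)) {
    stopifnot(!is.null(hg))
    wl <- .incident_weights(hg, sel)
    keep <- vapply(wl, function(w) length(w) > 0 &&
                     max(w) >= min_edge_weight_filter, logical(1))
    sel <- sel[keep]
  }
  sort(sel)
}

#' Neighborhood taxonomy-distribution vector of a node
#'
#' Length-weighted genus shares over the node's adjacent neighbors (distance
#' one): component `i` is the summed length of neighboring contigs assigned
#' to genus `i`, normalized by the total length of all neighboring contigs.
#' Contigs without a genus label count towards `unknown_frac`.
#'
#' @param node hybrid node id.
#' @param hg a `hybrid_graph`.
#' @param contig_taxa data.frame with columns `node` and `genus` (label
#'   `"unknown"` allowed).
#' @return list with `node`, `x` (named genus shares) and `unknown_frac`.
#' @export
tax_vector <- function(node, hg, contig_taxa) {
  e <- hg$edges
  nbrs <- unique(c(e$v[e$u == node], e$u[e$v == node]))
  if (length(nbrs) == 0L) stop("node ", node, " has no neighbors")
  len <- hg$nodes$contig_len[match(nbrs, hg$nodes$id)]
  genus <- contig_taxa$genus[match(nbrs, contig_taxa$node)]
  genus[is.na(genus)] <- "unknown"
  tot <- sum(len)
  share <- tapply(len, genus, sum) / tot
  unknown <- if ("unknown" %in% names(share)) unname(share[["unknown"]]) else 0
  x <- share[setdiff(names(share), "unknown")]
  list(node = node, x = stats::setNames(as.numeric(x), names(x)),
       unknown_frac = unknown)
}

# stack tax vectors on a common genus axis
.tax_matrix <- function(vectors) {
  genera <- sort(unique(unlist(lapply(vectors, function(v) names(v$x)))))
  m <- matrix(0, nrow = length(vectors), ncol = length(genera),
              dimnames = list(vapply(vectors, function(v)
                as.character(v$node), character(1)), genera))
  for (i in seq_along(vectors)) m[i, names(vectors[[i]]$x)] <- vectors[[i]]$x
  m
}

#' Cluster high-scoring transposase nodes by phylogenetic distribution
#'
#' K-means (Euclidean distance, k-means++-style multiple restarts via
#' `nstart`) on the neighborhood taxonomy vectors; nodes with more than
#' `max_unknown` of adjacent sequence classified as unknown are excluded.
#' Within-cluster sums of squares for k = 1..`k_max` are returned as elbow
#' data.
#'
#' @param vectors list of [tax_vector()] results.
#' @param k number of clusters.
#' @param max_unknown maximum tolerated unknown fraction (default 0.20).
#' @param seed RNG seed for the clustering (deterministic output).
#' @param k_max largest k evaluated for the elbow curve.
#' @param nstart random restarts per k.
#' @return list with `assignment` (named by node id), `centers`, `elbow`
#'   (data.frame `k`, `wss`) and `excluded` (node ids over the unknown cap).
#' @export
cluster_transposase_nodes <- function(vectors, k, max_unknown = 0.20,
                                      seed = 1L, k_max = 6L, nstart = 50L) {
  stopifnot(k >= 1)
  unknown <- vapply(vectors, function(v) v$unknown_frac, numeric(1))
  excluded <- vapply(vectors, function(v) v$node, numeric(1))[unknown > max_unknown]
  vectors <- vectors[unknown <= max_unknown]
  if (length(vectors) < k)
    stop("fewer eligible vectors (", length(vectors), ") than k = ", k)
  m <- .tax_matrix(vectors)
  withr_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(s)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    expr
  }
  fit_k <- function(kk, s) {
    if (kk >= nrow(m)) {
      # one point per cluster: exact, no randomness involved
      list(cluster = stats::setNames(seq_len(nrow(m)), rownames(m)),
           centers = m, tot.withinss = 0)
    } else {
      withr_seed(s, stats::kmeans(m, centers = kk, nstart = nstart))
    }
  }
  fit <- fit_k(k, seed)
  ks <- seq_len(min(k_max, nrow(m)))
  wss <- vapply(ks, function(kk) fit_k(kk, seed + kk)$tot.withinss, numeric(1))
  list(assignment = stats::setNames(fit$cluster, rownames(m)),
       centers = fit$centers,
       elbow = data.frame(k = ks, wss = wss),
       excluded = excluded)
}

#' k-neighborhood of a node
#'
#' All nodes within graph path distance `k` of `node` (breadth-first ball,
#' center included).
#'
#' @param hg a `hybrid_graph` (or any list with an `edges` data.frame).
#' @param node center node id.
#' @param k radius in edges (default 5).
#' @return sorted integer vector of node ids.
#' @export
k_neighborhood <- function(hg, node, k = 5L) {
  e <- hg$edges
  frontier <- node
  seen <- node
  depth <- 0L
  while (depth < k && length(frontier) > 0) {
    nxt <- unique(c(e$v[e$u %in% frontier], e$u[e$v %in% frontier]))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
    depth <- depth + 1L
  }
  sort(seen)
}

#' Gene-class enrichment in transposase-cluster neighborhoods
#'
#' For each cluster, the union of the `radius`-neighborhoods of its member
#' nodes is taken (deduplicated) and, for each gene class, a 2x2 table of
#' class hits versus other hits, inside versus outside the union, is tested
#' with a one-sided Fisher's exact test (enrichment direction). Hits are
#' counted once per node-class pair. Benjamini-Hochberg FDR correction is
#' applied across all cluster-class pairs.
#'
#' @param assignment named cluster assignment from
#'   [cluster_transposase_nodes()] (names = node ids).
#' @param hg a `hybrid_graph`.
#' @param gene_hits data.frame with columns `node` and `class`.
#' @param radius neighborhood radius (default 5).
#' @return data.frame with one row per cluster-class pair: counts, odds
#'   ratio direction, `p`, `q` and significance stars at 0.05/0.01/0.001.
#' @export
enrichment_test <- function(assignment, hg, gene_hits, radius = 5L) {
  hits <- unique(data.frame(node = gene_hits$node, class = gene_hits$class))
  classes <- sort(unique(hits$class))
  if (length(classes) == 0L) stop("no gene hits supplied")
  rows <- list()
  for (cl in sort(unique(assignment))) {
    members <- as.integer(names(assignment)[assignment == cl])
    hood <- sort(unique(unlist(lapply(members, function(nd)
      k_neighborhood(hg, nd, radius)))))
    inside <- hits$node %in% hood
    for (g in classes) {
      is_g <- hits$class == g
      a <- sum(is_g & inside); b <- sum(!is_g & inside)
      c_ <- sum(is_g & !inside); d <- sum(!is_g & !inside)
      if (a + c_ == 0L) next   # class with zero total hits: skipped
      p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE),
                              alternative = "greater")$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, class = g, in_class = a, in_other = b,
        out_class = c_, out_other = d,
        enriched = (a / max(1L, a + b)) > (c_ / max(1L, c_ + d)), p = p)
    }
  }
  rep_df <- do.call(rbind, rows)
  rep_df$q <- stats::p.adjust(rep_df$p, method = "BH")
  rep_df$stars <- cut(rep_df$q, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                      labels = c("***", "**", "*", ""))
  rownames(rep_df) <- NULL
  rep_df
}
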