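#' Coarsening configuration
#'
#' @param min_edge_weight minimum edge weight considered during heavy-edge
#'   matching; hitting a lighter edge terminates a node's neighbor scan.
#' @param min_density minimum density of the would-be merged cluster; a
#'   density failure continues the scan with the next-heaviest neighbor.
#'   The default (8) keeps clusters locally dense at short-read coverages
#'   around 20x: single-copy path clusters stop growing near ~1 kb spans,
#'   while repeat families, whose reads overlap across copies, continue to
#'   collapse into single super nodes. Set to 0 for maximal contiguity
#'   (pure assembly of a low-complexity sample).
#' @param n_passes number of node-visit passes per matching round; nodes with
#'   larger maximum incident edge weights are visited in earlier passes.
#' @param stop_ratio coarsening stops when the ratio of matched nodes to
#'   graph size falls beneath this threshold.
#' @return a `coarsen_config` list.
#' @export
coarsen_config <- function(min_edge_weight = 40, min_density = 8,
                           n_passes = 4L, stop_ratio = 0.1) {
  stopifnot(min_edge_weight >= 0, min_density >= 0, n_passes >= 1,
            stop_ratio > 0, stop_ratio < 1)
  structure(list(min_edge_weight = min_edge_weight, min_density = min_density,
                 n_passes = as.integer(n_passes), stop_ratio = stop_ratio),
            class = "coarsen_config")
}

#' Build the initial overlap graph G0
#'
#' One node per read, edge weight = overlap length. Nodes carry a cluster
#' node weight of one and a cluster edge weight of zero. Node ids are the
#' integer positions of `read_ids`; the mapping to read ids is kept on the
#' graph.
#'
#' @param edges deduplicated edge data.frame from [all_vs_all_overlaps()].
#' @param read_ids character vector of all retained read ids (isolated reads
#'   become isolated nodes). Defaults to the ids appearing in `edges`.
#' @return a `level_graph` (level 0).
#' @export
build_overlap_graph <- function(edges, read_ids = NULL) {
  if (is.null(read_ids)) read_ids <- sort(unique(c(edges$u, edges$v)))
  n <- length(read_ids)
  ui <- match(edges$u, read_ids)
  vi <- match(edges$v, read_ids)
  if (anyNA(ui) || anyNA(vi)) stop("edge endpoint not present in read_ids")
  e <- data.frame(u = pmin(ui, vi), v = pmax(ui, vi),
                  w = as.numeric(edges$overlap_len))
  if (!is.null(edges$type)) {
    e$type <- ifelse(ui <= vi, edges$type, .swap_type(edges$type))
  }
  structure(list(level = 0L, n_nodes = n, edges = e,
                 nw = rep(1L, n), ew = rep(0, n),
                 parent = rep(NA_integer_, n),
                 children = NULL,
                 members = lapply(seq_len(n), identity),
                 read_ids = read_ids),
            class = "level_graph")
}

#' Density of the cluster formed by merging two adjacent nodes
#'
#' The summed weight of the intra-cluster edges of the merged cluster in G0
#' (both nodes' cluster edge weights plus the connecting edge) divided by the
#' number of edges the cluster would have if complete:
#' `2 * (ew_i + ew_j + w_ij) / ((nw_i + nw_j) * (nw_i + nw_j - 1))`.
#'
#' @param vi,vj node ids (must be adjacent in `g`).
#' @param g a `level_graph`.
#' @return the density (numeric scalar).
#' @export
merge_density <- function(vi, vj, g) {
  a <- min(vi, vj); b <- max(vi, vj)
  hit <- g$edges$u == a & g$edges$v == b
  if (!any(hit)) stop("(", vi, ",", vj, ") is not an edge")
  w <- g$edges$w[which(hit)[1]]
  s <- g$nw[vi] + g$nw[vj]
  2 * (g$ew[vi] + g$ew[vj] + w) / (s * (s - 1))
}

# sorted adjacency: per node, neighbors ordered by decreasing edge weight,
# ties by ascending neighbor id
.sorted_adjacency <- function(g) {
  e <- g$edges
  node <- c(e$u, e$v); nbr <- c(e$v, e$u); w <- c(e$w, e$w)
  o <- order(node, -w, nbr)
  node <- node[o]; nbr <- nbr[o]; w <- w[o]
  idx <- split(seq_along(node), factor(node, levels = seq_len(g$n_nodes)))
  list(nbr = nbr, w = w, idx = idx)
}

#' Heavy-edge matching
#'
#' Greedy maximal matching preferring heavy edges. Nodes are visited in
#' `n_passes` groups by decreasing maximum incident edge weight (ascending id
#' within a group). Each unmatched node scans its neighbors in decreasing
#' edge-weight order: an edge below `min_edge_weight` terminates the scan and
#' leaves the node unmatched; an unmatched neighbor is accepted if the
#' density of the merged cluster reaches `min_density`, otherwise the scan
#' continues.
#'
#' @param g a `level_graph`.
#' @param cfg a [coarsen_config()].
#' @return integer matrix with two columns, one matched pair per row.
#' @export
heavy_edge_matching <- function(g, cfg = coarsen_config()) {
  n <- g$n_nodes
  if (nrow(g$edges) == 0) return(matrix(integer(0), ncol = 2))
  adj <- .sorted_adjacency(g)
  maxw <- rep(-Inf, n)
  has <- lengths(adj$idx) > 0
  maxw[has] <- vapply(adj$idx[has], function(ii) adj$w[ii[1]], numeric(1))
  cand <- which(has)
  # quantile buckets by max incident weight, heaviest bucket first
  ranks <- rank(-maxw[cand], ties.method = "min")
  bucket <- ceiling(ranks * cfg$n_passes / length(cand))
  order_visit <- cand[order(bucket, cand)]
  matched <- rep(FALSE, n)
  pairs_u <- integer(0); pairs_v <- integer(0)
  nbr <- adj$nbr; wts <- adj$w; idx <- adj$idx
  nw <- g$nw; ew <- g$ew
  for (vi in order_visit) {
    if (matched[vi]) next
    for (ii in idx[[vi]]) {
      w <- wts[ii]
      if (w < cfg$min_edge_weight) break   # scan terminated, vi unmatched
      vj <- nbr[ii]
      if (matched[vj]) next
      s <- nw[vi] + nw[vj]
      dens <- 2 * (ew[vi] + ew[vj] + w) / (s * (s - 1))
      if (dens >= cfg$min_density) {
        matched[vi] <- TRUE; matched[vj] <- TRUE
        pairs_u <- c(pairs_u, vi); pairs_v <- c(pairs_v, vj)
        break
      }
    }
  }
  cbind(pairs_u, pairs_v, deparse.level = 0)
}

#' Contract a matching into the next graph level
#'
#' Matched pairs become super nodes (`nw` summed; `ew` summed plus the
#' matched edge's weight); unmatched nodes map through unchanged. Parallel
#' edges are combined by adding their weights; self-loops are removed.
#' Parent/children links are recorded.
#'
#' @param g a `level_graph`.
#' @param matching two-column matrix from [heavy_edge_matching()].
#' @return the contracted `level_graph` one level up.
#' @export
contract <- function(g, matching) {
  n <- g$n_nodes
  partner <- rep(NA_integer_, n)
  if (nrow(matching) > 0) {
    partner[matching[, 1]] <- matching[, 2]
    partner[matching[, 2]] <- matching[, 1]
  }
  # new node per unmatched node and per matched pair (keyed by smaller id)
  rep_node <- ifelse(is.na(partner), seq_len(n), pmin(seq_len(n), partner))
  is_rep <- rep_node == seq_len(n)
  new_id <- cumsum(is_rep)
  parent <- new_id[rep_node]
  n_new <- sum(is_rep)
  nw <- as.integer(tapply(g$nw, parent, sum))
  ew <- as.numeric(tapply(g$ew, parent, sum))
  if (nrow(matching) > 0) {
    # add the contracted matched-edge weight into ew
    key_u <- pmin(matching[, 1], matching[, 2])
    key_v <- pmax(matching[, 1], matching[, 2])
    ekey <- paste(g$edges$u, g$edges$v)
    mw <- g$edges$w[match(paste(key_u, key_v), ekey)]
    ew[parent[key_u]] <- ew[parent[key_u]] + mw
  }
  pu <- parent[g$edges$u]; pv <- parent[g$edges$v]
  keep <- pu != pv
  eu <- pmin(pu[keep], pv[keep]); ev <- pmax(pu[keep], pv[keep])
  if (length(eu) > 0) {
    base <- max(ev) + 1
    agg <- rowsum(g$edges$w[keep], eu * base + ev)
    key <- as.numeric(rownames(agg))
    e <- data.frame(u = as.integer(key %/% base), v = as.integer(key %% base),
                    w = as.numeric(agg[, 1]))
    e <- e[order(e$u, e$v), , drop = FALSE]
    rownames(e) <- NULL
  } else {
    e <- data.frame(u = integer(0), v = integer(0), w = numeric(0))
  }
  children <- split(seq_len(n), parent)
  members <- lapply(children, function(ch) sort(unlist(g$members[ch],
                                                       use.names = FALSE)))
  out <- structure(list(level = g$level + 1L, n_nodes = n_new, edges = e,
                        nw = nw, ew = ew,
                        parent = rep(NA_integer_, n_new),
                        children = unname(children),
                        members = unname(members),
                        read_ids = NULL),
                   class = "level_graph")
  attr(out, "prev_parent") <- parent
  out
}

#' Coarsen an overlap graph into the multilevel graph set
#'
#' Repeats heavy-edge matching and contraction until the ratio of matched
#' nodes to graph size falls beneath `stop_ratio`.
#'
#' @param g0 the level-0 `level_graph` from [build_overlap_graph()].
#' @param cfg a [coarsen_config()].
#' @return list of `level_graph`s, G0 first. Parent links in each returned
#'   level point into the next level.
#' @export
coarsen_all <- function(g0, cfg = coarsen_config()) {
  levels <- list(g0)
  g <- g0
  repeat {
    m <- heavy_edge_matching(g, cfg)
    if (nrow(m) * 2 / max(1L, g$n_nodes) < cfg$stop_ratio) break
    nxt <- contract(g, m)
    g$parent <- attr(nxt, "prev_parent")
    levels[[length(levels)]] <- g
    levels[[length(levels) + 1L]] <- nxt
    g <- nxt
  }
  levels
}

#' Relabel G0 by top-level cluster membership (G_final)
#'
#' Nodes co-occurring in a top-level cluster receive consecutive labels so
#' that each cluster occupies a contiguous id block.
#'
#' @param levels multilevel graph set from [coarsen_all()].
#' @return list with `g` (the relabeled copy of G0), `perm` (old id -> new
#'   id) and `ranges` (per top-level super node: `super`, `from`, `to`).
#' @export
relabel_final <- function(levels) {
  stopifnot(length(levels) >= 1)
  g0 <- levels[[1]]
  top <- levels[[length(levels)]]
  n <- g0$n_nodes
  perm <- integer(n)
  from <- integer(top$n_nodes); to <- integer(top$n_nodes)
  nxt <- 1L
  for (s in seq_len(top$n_nodes)) {
    mem <- top$members[[s]]
    perm[mem] <- nxt + seq_along(mem) - 1L
    from[s] <- nxt; to[s] <- nxt + length(mem) - 1L
    nxt <- nxt + length(mem)
  }
  g <- g0
  g$edges$u2 <- perm[g0$edges$u]; g$edges$v2 <- perm[g0$edges$v]
  e <- data.frame(u = pmin(g$edges$u2, g$edges$v2),
                  v = pmax(g$edges$u2, g$edges$v2),
                  w = g0$edges$w)
  if (!is.null(g0$edges$type))
    e$type <- ifelse(g$edges$u2 <= g$edges$v2, g0$edges$type,
                     .swap_type(g0$edges$type))
  e <- e[order(e$u, e$v), , drop = FALSE]
  rownames(e) <- NULL
  g$edges <- e
  g$members <- lapply(seq_len(n), identity)
  g$read_ids <- g0$read_ids[order(perm)]
  list(g = g, perm = perm,
       ranges = data.frame(super = seq_len(top$n_nodes), from = from, to = to))
}

#' Export a graph level as GFA1
#'
#' S-lines carry `nw:i` and `ew:i` tags; L-lines carry the edge weight as
#' `WT:i`. Sequences are omitted (`*`) unless contigs are attached.
#'
#' @param g a `level_graph` (or hybrid graph).
#' @param path output path.
#' @param contigs optional named character vector of node sequences.
#' @param shannon optional named numeric vector of Shannon scores (`SH:f`).
#' @return `path`, invisibly.
#' @export
write_gfa <- function(g, path, contigs = NULL, shannon = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  ids <- seq_len(g$n_nodes)
  for (i in ids) {
    seq_f <- if (!is.null(contigs) && !is.na(contigs[i])) contigs[i] else "*"
    line <- sprintf("S\t%d\t%s\tnw:i:%d\tew:i:%d", i, seq_f,
                    g$nw[i], as.integer(round(g$ew[i])))
    if (!is.null(shannon))
      line <- paste0(line, sprintf("\tSH:f:%.4f", shannon[i]))
    writeLines(line, con)
  }
  if (nrow(g$edges) > 0)
    writeLines(sprintf("L\t%d\t+\t%d\t+\t0M\tWT:i:%d",
                       g$edges$u, g$edges$v, as.integer(round(g$edges$w))), con)
  invisible(path)
}
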