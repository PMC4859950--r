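#' Graph-cleaning configuration
#'
#' @param max_tip_len maximum length, in nodes, of a dead-end branch removed
#'   as a tip.
#' @param max_containment_len hybrid-graph filter: only contigs shorter than
#'   this are tested for containment in neighboring contigs.
#' @param containment_min_identity minimum identity for a containment call.
#' @param max_bubble_len maximum number of nodes per bubble path.
#' @return a `clean_config` list.
#' @export
clean_config <- function(max_tip_len = 3L, max_containment_len = 200L,
                         containment_min_identity = 0.95,
                         max_bubble_len = 5L) {
  stopifnot(max_tip_len >= 1, max_containment_len >= 1,
            containment_min_identity > 0, containment_min_identity <= 1)
  structure(list(max_tip_len = as.integer(max_tip_len),
                 max_containment_len = as.integer(max_containment_len),
                 containment_min_identity = containment_min_identity,
                 max_bubble_len = as.integer(max_bubble_len)),
            class = "clean_config")
}

# induced read-level subgraph of g0 on a member set
.induced_subgraph <- function(g0, members) {
  keep <- g0$edges$u %in% members & g0$edges$v %in% members
  list(nodes = sort(members), edges = g0$edges[keep, , drop = FALSE])
}

# local-index adjacency: nodes are mapped to 1..n so that list access is O(1)
.local_adj <- function(sub) {
  n <- length(sub$nodes)
  lu <- match(sub$edges$u, sub$nodes)
  lv <- match(sub$edges$v, sub$nodes)
  f <- factor(c(lu, lv), levels = seq_len(n))
  m <- nrow(sub$edges)
  list(nbr = split(c(lv, lu), f),
       w = split(c(sub$edges$w, sub$edges$w), f),
       eid = split(rep.int(seq_len(m), 2L), f),
       lu = lu, lv = lv)
}

.drop_nodes <- function(sub, drop) {
  sub$nodes <- setdiff(sub$nodes, drop)
  keep <- !(sub$edges$u %in% drop | sub$edges$v %in% drop)
  sub$edges <- sub$edges[keep, , drop = FALSE]
  sub
}

# iterative tip (dead-end branch) clipping: one tip per round, shortest
# first, so that when several short branches meet at one node the survivors
# are re-examined against the updated graph (a pure path loses its branch
# node once the spur is gone and keeps its genuine ends)
.remove_tips <- function(sub, max_tip_len) {
  repeat {
    adj <- .local_adj(sub)
    deg <- lengths(adj$nbr)
    ends <- which(deg == 1L)
    best <- NULL; best_key <- NULL
    for (e in ends) {
      chain <- e
      wsum <- 0
      prev <- NA_integer_
      cur <- e
      is_tip <- FALSE
      while (length(chain) <= max_tip_len) {
        nbrs <- adj$nbr[[cur]]
        keep <- !nbrs %in% prev
        if (sum(keep) == 0L) break             # isolated end of a pure path
        if (sum(keep) > 1L) break              # reached the branch node itself
        nxt <- nbrs[keep][1]
        wsum <- wsum + adj$w[[cur]][keep][1]
        ndeg <- deg[nxt]
        if (ndeg >= 3L) { is_tip <- TRUE; break }
        if (ndeg == 1L) break                  # whole component is a path
        prev <- cur; cur <- nxt; chain <- c(chain, nxt)
      }
      if (is_tip && length(chain) <= max_tip_len) {
        key <- c(length(chain), wsum, e)       # shortest, then lightest
        if (is.null(best_key) ||
            isTRUE(key[1] < best_key[1] ||
                   (key[1] == best_key[1] && key[2] < best_key[2]) ||
                   (key[1] == best_key[1] && key[2] == best_key[2] &&
                    key[3] < best_key[3]))) {
          best <- chain; best_key <- key
        }
      }
    }
    if (is.null(best)) return(sub)
    sub <- .drop_nodes(sub, sub$nodes[best])
  }
}

# walk a degree-2 chain from `start` (a neighbor of branch node s) until a
# node of degree != 2 is hit; returns interior nodes (local idx), terminal
# node and path weight, or NULL if the chain exceeds the length bound
.walk_chain <- function(adj, deg, s, start, maxlen) {
  interior <- integer(0)
  wsum <- adj$w[[s]][match(start, adj$nbr[[s]])]
  prev <- s; cur <- start
  while (deg[cur] == 2L && length(interior) < maxlen) {
    interior <- c(interior, cur)
    nbrs <- adj$nbr[[cur]]
    nxt <- nbrs[nbrs != prev]
    if (length(nxt) != 1L) return(NULL)
    wsum <- wsum + adj$w[[cur]][match(nxt, nbrs)]
    prev <- cur; cur <- nxt
  }
  if (deg[cur] == 2L) return(NULL)
  list(interior = interior, end = cur, w = wsum)
}

# remove simple bubbles: two chains with degree-2 interiors sharing both
# endpoints; the lighter chain (summed edge weight) is deleted
.remove_bubbles <- function(sub, max_bubble_len) {
  repeat {
    adj <- .local_adj(sub)
    deg <- lengths(adj$nbr)
    branch <- which(deg >= 3L)
    changed <- FALSE
    for (s in branch) {
      nbrs <- adj$nbr[[s]]
      # chains can only start at degree-<=2 neighbors
      nbrs <- nbrs[deg[nbrs] <= 2L]
      if (length(nbrs) < 2L) next
      chains <- lapply(nbrs, function(b) .walk_chain(adj, deg, s, b,
                                                     max_bubble_len))
      ok <- !vapply(chains, is.null, logical(1))
      chains <- chains[ok]
      if (length(chains) < 2L) next
      endv <- vapply(chains, function(ch) ch$end, integer(1))
      for (t in unique(endv[duplicated(endv)])) {
        if (t == s) next
        cand <- chains[endv == t]
        ints <- lapply(cand, function(ch) ch$interior)
        # require node-disjoint interiors
        if (length(unlist(ints)) != length(unique(unlist(ints)))) next
        wts <- vapply(cand, function(ch) ch$w, numeric(1))
        lighter <- which.min(wts)
        drop <- ints[[lighter]]
        if (length(drop) == 0L) {
          # parallel chain vs direct edge: remove the direct s-t edge if it
          # is the lighter path
          hit <- (adj$lu == s & adj$lv == t) | (adj$lu == t & adj$lv == s)
          sub$edges <- sub$edges[!hit, , drop = FALSE]
        } else {
          sub <- .drop_nodes(sub, sub$nodes[drop])
        }
        changed <- TRUE
        break
      }
      if (changed) break
    }
    if (!changed) return(sub)
  }
}

# transitive reduction (weight-consistent witnesses); see the compiled kernel
.reduce_transitive <- function(sub) {
  if (nrow(sub$edges) == 0) return(sub)
  idx <- match(c(sub$edges$u, sub$edges$v), sub$nodes)
  n <- length(sub$nodes)
  ui <- idx[seq_len(nrow(sub$edges))]
  vi <- idx[-seq_len(nrow(sub$edges))]
  keep <- .transitive_reduce_cpp(n, ui, vi, sub$edges$w)
  sub$edges <- sub$edges[keep, , drop = FALSE]
  sub
}

#' Clean a read-level cluster subgraph
#'
#' One cleaning round removes short dead-end branches (tips), then simple
#' bubbles (two paths with shared endpoints; the lighter path is deleted),
#' then applies transitive reduction. Rounds repeat until a fixed point:
#' duplicate reads only become clippable tips after transitive reduction.
#'
#' @param sub subgraph (list with `nodes` and `edges`) from one super node's
#'   cluster.
#' @param cfg a [clean_config()].
#' @return the cleaned subgraph.
#' @export
clean_subgraph <- function(sub, cfg = clean_config()) {
  for (round in 1:5) {
    before <- list(length(sub$nodes), nrow(sub$edges))
    sub <- .remove_tips(sub, cfg$max_tip_len)
    sub <- .remove_bubbles(sub, cfg$max_bubble_len)
    sub <- .reduce_transitive(sub)
    if (identical(before, list(length(sub$nodes), nrow(sub$edges)))) break
  }
  sub
}

#' Is a cleaned subgraph a single contiguous path?
#'
#' True for a single node, or for a connected graph in which every node has
#' degree at most two with exactly two degree-one endpoints (no cycles).
#'
#' @param sub a subgraph.
#' @return logical.
#' @export
is_single_path <- function(sub) {
  n <- length(sub$nodes)
  if (n == 0L) return(FALSE)
  if (n == 1L) return(TRUE)
  if (nrow(sub$edges) != n - 1L) return(FALSE)
  deg <- table(factor(c(sub$edges$u, sub$edges$v), levels = sub$nodes))
  if (any(deg > 2L)) return(FALSE)
  sum(deg == 1L) == 2L && .is_connected(sub)
}

.is_connected <- function(sub) {
  n <- length(sub$nodes)
  if (n <= 1L) return(TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(sub$edges$u), to = as.character(sub$edges$v)),
    directed = FALSE, vertices = as.character(sub$nodes))
  igraph::is_connected(g)
}

# orientation-aware left-to-right layout of a path subgraph; returns 0-based
# offsets named by node id
.layout_path <- function(sub, read_len) {
  nodes <- sub$nodes
  n <- length(nodes)
  if (n == 1L) return(stats::setNames(0, as.character(nodes)))
  adj <- .local_adj(sub)
  deg <- lengths(adj$nbr)
  start <- which(deg == 1L)[1]
  e <- sub$edges
  pos <- rep(NA_real_, n)
  pos[start] <- 0
  prev <- NA_integer_; cur <- start
  repeat {
    nbrs <- adj$nbr[[cur]]
    k <- which(!nbrs %in% prev)
    if (length(k) == 0L) break
    nxt <- nbrs[k[1]]
    i <- adj$eid[[cur]][k[1]]
    ov <- e$w[i]
    type <- if (!is.null(e$type)) e$type[i] else 0L
    cur_is_u <- adj$lu[i] == cur
    cur_left <- if (cur_is_u) type %in% c(0L, 3L) else type %in% c(1L, 2L)
    # dovetail: shift by left read's unshared prefix; containment: the
    # contained read sits at the container's shared end (same arithmetic,
    # since the overlap then spans the whole contained read)
    delta <- read_len[if (cur_left) cur else nxt] - ov
    pos[nxt] <- pos[cur] + if (cur_left) delta else -delta
    prev <- cur; cur <- nxt
  }
  if (anyNA(pos)) stop("path layout failed: disconnected path")
  stats::setNames(pos - min(pos), as.character(nodes))
}

#' Assemble the contig of a single-path read cluster
#'
#' Reads are laid out left to right along the path using the stored overlap
#' lengths and dovetail orientations; the consensus takes the majority base
#' at each column, breaking ties with the base of the earliest-starting read.
#'
#' @param sub a single-path subgraph (see [is_single_path()]).
#' @param reads the processed [read_set()] (rows indexed by G0 node id).
#' @return the contig as a character scalar.
#' @export
assemble_contig <- function(sub, reads) {
  seqs <- reads$seq[sub$nodes]
  names(seqs) <- as.character(sub$nodes)
  rl <- stats::setNames(nchar(seqs), names(seqs))
  pos <- .layout_path(sub, rl)
  pos <- pos[names(seqs)]
  L <- as.integer(max(pos + rl))
  code <- lapply(seqs, function(s)
    match(strsplit(s, "")[[1]], c("A", "C", "G", "T", "N")))
  lin <- unlist(lapply(seq_along(seqs), function(i)
    (as.integer(pos[i]) + seq_len(rl[i]) - 1L) * 5L + code[[i]]),
    use.names = FALSE)
  tab <- tabulate(lin, nbins = 5L * L)
  counts <- matrix(tab, nrow = 5L)
  best <- max.col(t(counts), ties.method = "first")
  # tie-break by earliest-starting read
  mx <- counts[cbind(best, seq_len(L))]
  nties <- colSums(counts == rep(mx, each = 5L) & counts > 0L)
  tie_cols <- which(nties > 1L)
  if (length(tie_cols) > 0) {
    ord <- order(pos)
    for (cc in tie_cols) {
      for (i in ord) {
        off <- cc - as.integer(pos[i])
        if (off >= 1L && off <= rl[i]) { best[cc] <- code[[i]][off]; break }
      }
    }
  }
  paste(c("A", "C", "G", "T", "N")[best], collapse = "")
}

# project G0 edges onto a unit assignment (G0 node -> unit id; NA = dropped);
# returns aggregated inter-unit edges
.project_edges <- function(g0, assign) {
  pu <- assign[g0$edges$u]; pv <- assign[g0$edges$v]
  keep <- !is.na(pu) & !is.na(pv) & pu != pv
  if (!any(keep))
    return(data.frame(u = integer(0), v = integer(0), w = numeric(0)))
  eu <- pmin(pu[keep], pv[keep]); ev <- pmax(pu[keep], pv[keep])
  base <- max(ev) + 1
  agg <- rowsum(g0$edges$w[keep], eu * base + ev)
  key <- as.numeric(rownames(agg))
  e <- data.frame(u = as.integer(key %/% base), v = as.integer(key %% base),
                  w = as.numeric(agg[, 1]))
  e[order(e$u, e$v), , drop = FALSE]
}

#' Select best-representative nodes and build the hybrid graph set
#'
#' Iterates the multilevel set from the most reduced level down to G0. Each
#' super node's read-level cluster subgraph is cleaned and tested for being a
#' single path; passing nodes become best representatives, their contigs are
#' assembled, and all their descendants are blocked from evaluation. The
#' hybrid graph G'0 is the union of best representatives; every edge carries
#' the summed inter-cluster G0 edge weights between the member sets of its
#' endpoints.
#'
#' @param levels multilevel graph set from [coarsen_all()].
#' @param reads the processed [read_set()] whose rows are the G0 nodes.
#' @param cfg a [clean_config()].
#' @return a `hybrid_graph`: list with `nodes` (data.frame: `id`,
#'   `source_level`, `level_node`, `contig_len`, `n_reads`), `contigs`
#'   (character), `member_reads` (list of G0 node ids), `edges`
#'   (`u`,`v`,`w`), and `hybrid_levels` (per-level node composition of
#'   G'_n ... G'_0).
#' @export
select_representatives <- function(levels, reads, cfg = clean_config()) {
  g0 <- levels[[1]]
  n0 <- g0$n_nodes
  taken <- rep(FALSE, n0)
  reps <- list()
  level_status <- vector("list", length(levels))
  for (li in rev(seq_along(levels))) {
    g <- levels[[li]]
    status <- rep("blocked", g$n_nodes)
    # one pass over G0 edges: intra-cluster edge indices per level node
    assign0 <- rep(NA_integer_, n0)
    assign0[unlist(g$members, use.names = FALSE)] <-
      rep.int(seq_len(g$n_nodes), lengths(g$members))
    pu <- assign0[g0$edges$u]; pv <- assign0[g0$edges$v]
    intra <- which(pu == pv)
    edges_by <- split(intra, pu[intra])
    for (v in seq_len(g$n_nodes)) {
      mem <- g$members[[v]]
      if (any(taken[mem])) next
      ei <- edges_by[[as.character(v)]]
      sub <- list(nodes = mem,
                  edges = g0$edges[ei, , drop = FALSE])
      cleaned <- clean_subgraph(sub, cfg)
      if (length(cleaned$nodes) > 0 && is_single_path(cleaned)) {
        contig <- assemble_contig(cleaned, reads)
        reps[[length(reps) + 1L]] <- list(level = g$level, level_node = v,
                                          members = mem, contig = contig)
        taken[mem] <- TRUE
        status[v] <- "selected"
      } else {
        status[v] <- "unselected"
      }
    }
    level_status[[li]] <- status
  }
  nrep <- length(reps)
  nodes <- data.frame(
    id = seq_len(nrep),
    source_level = vapply(reps, function(r) r$level, integer(1)),
    level_node = vapply(reps, function(r) r$level_node, integer(1)),
    contig_len = vapply(reps, function(r) nchar(r$contig), integer(1)),
    n_reads = vapply(reps, function(r) length(r$members), integer(1)))
  contigs <- vapply(reps, function(r) r$contig, character(1))
  member_reads <- lapply(reps, function(r) r$members)
  # G0 node -> hybrid node id
  assign <- rep(NA_integer_, n0)
  for (i in seq_len(nrep)) assign[member_reads[[i]]] <- i
  edges <- .project_edges(g0, assign)
  # per-level hybrid composition G'_l: representatives from levels >= l plus
  # unselected nodes of level l
  hybrid_levels <- lapply(seq_along(levels), function(li) {
    lev <- levels[[li]]$level
    list(level = lev,
         representatives = nodes$id[nodes$source_level >= lev],
         unselected = which(level_status[[li]] == "unselected"))
  })
  structure(list(nodes = nodes, contigs = contigs,
                 member_reads = member_reads, edges = edges,
                 n_nodes = nrep, hybrid_levels = hybrid_levels,
                 read_ids = g0$read_ids),
            class = "hybrid_graph")
}

# containment check: can `short` be mapped inside `long` at the required
# identity? Mismatch/indel budget follows from the identity threshold.
.is_contained <- function(short, long, min_identity) {
  if (nchar(short) > nchar(long)) return(FALSE)
  if (grepl(short, long, fixed = TRUE)) return(TRUE)
  budget <- floor((1 - min_identity) * nchar(short))
  if (budget == 0) return(FALSE)
  hits <- Biostrings::matchPattern(short, Biostrings::DNAString(long),
                                   max.mismatch = budget, with.indels = TRUE)
  length(hits) > 0
}

#' Trim the hybrid graph
#'
#' Nodes whose contigs are shorter than `max_containment_len` and can be
#' mapped into a neighboring contig at `containment_min_identity` are removed
#' with their incident edges (ascending contig length, re-checked to a fixed
#' point); transitive edges are then removed.
#'
#' @param hg a `hybrid_graph`.
#' @param cfg a [clean_config()].
#' @return the trimmed `hybrid_graph` (removed nodes keep their rows in
#'   `nodes` but are flagged `trimmed`).
#' @export
trim_hybrid <- function(hg, cfg = clean_config()) {
  alive <- rep(TRUE, hg$n_nodes)
  e <- hg$edges
  repeat {
    changed <- FALSE
    ord <- order(hg$nodes$contig_len, hg$nodes$id)
    for (i in ord) {
      if (!alive[i] || hg$nodes$contig_len[i] >= cfg$max_containment_len) next
      nbrs <- c(e$v[e$u == i], e$u[e$v == i])
      nbrs <- nbrs[alive[nbrs]]
      for (j in nbrs) {
        if (.is_contained(hg$contigs[i], hg$contigs[j],
                          cfg$containment_min_identity)) {
          alive[i] <- FALSE
          e <- e[e$u != i & e$v != i, , drop = FALSE]
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  if (nrow(e) > 0) {
    ids <- sort(unique(c(e$u, e$v)))
    keep <- .transitive_reduce_cpp(length(ids), match(e$u, ids),
                                   match(e$v, ids), e$w)
    e <- e[keep, , drop = FALSE]
  }
  rownames(e) <- NULL
  hg$edges <- e
  hg$nodes$trimmed <- !alive
  hg
}

#' Write hybrid-graph contigs as FASTA
#'
#' Headers are `<node_id> level=<l> reads=<n>`; trimmed nodes are skipped.
#'
#' @param hg a `hybrid_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(hg, path) {
  keep <- if (!is.null(hg$nodes$trimmed)) !hg$nodes$trimmed else
    rep(TRUE, hg$n_nodes)
  x <- Biostrings::DNAStringSet(hg$contigs[keep])
  names(x) <- sprintf("%d level=%d reads=%d", hg$nodes$id[keep],
                      hg$nodes$source_level[keep], hg$nodes$n_reads[keep])
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
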