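#' Overlap-alignment configuration
#'
#' @param k seed (k-mer) length in bp.
#' @param step scan step between successive query k-mers.
#' @param band half-width of the banded alignment around the seed diagonal.
#' @param min_overlap minimum overlap length (alignment columns) to record an
#'   edge.
#' @param min_identity minimum overlap identity (matches / alignment columns).
#' @return an `align_config` list.
#' @export
align_config <- function(k = 16L, step = 4L, band = 10L,
                         min_overlap = 40L, min_identity = 0.95) {
  stopifnot(k >= 8, step >= 1, band >= 0, min_overlap >= 1,
            min_identity > 0, min_identity <= 1)
  structure(list(k = as.integer(k), step = as.integer(step),
                 band = as.integer(band), min_overlap = as.integer(min_overlap),
                 min_identity = min_identity),
            class = "align_config")
}

#' Build a suffix-array index over a reference read subset
#'
#' Reads are concatenated with `#` separators and indexed by a suffix array
#' supporting exact k-mer lookup.
#'
#' @param ref_reads a [read_set()] (non-empty).
#' @return a `suffix_index` list with the concatenated text, the suffix
#'   array, per-read start offsets and read ids.
#' @export
build_suffix_array <- function(ref_reads) {
  stopifnot(nrow(ref_reads) > 0)
  seqs <- ref_reads$seq
  text <- paste(seqs, collapse = "#")
  starts <- cumsum(c(1L, nchar(seqs) + 1L))[seq_along(seqs)]
  structure(list(text = text, sa = .sa_build_cpp(text), ref_start = starts,
                 ids = ref_reads$id, seqs = seqs),
            class = "suffix_index")
}

#' Exact k-mer lookup in a suffix-array index
#'
#' @param index a [build_suffix_array()] result.
#' @param kmer the query k-mer.
#' @return data.frame of occurrences (`ref_id`, `ref_pos` 0-based), sorted by
#'   position (deterministic). Occurrences spanning read boundaries are
#'   excluded.
#' @export
sa_lookup <- function(index, kmer) {
  pos <- .sa_lookup_cpp(index$text, index$sa, kmer)
  if (length(pos) == 0)
    return(data.frame(ref_id = character(0), ref_pos = integer(0)))
  ri <- findInterval(pos, index$ref_start)
  off <- pos - index$ref_start[ri]
  ok <- off + nchar(kmer) <= nchar(index$seqs[ri])
  data.frame(ref_id = index$ids[ri[ok]], ref_pos = off[ok])
}

# canonical edge orientation codes:
#   0 = u extends left of v (suffix of u overlaps prefix of v)
#   1 = v extends left of u
#   2 = u contained in v
#   3 = v contained in u (identical spans fall here)
.swap_type <- function(type) c(1L, 0L, 3L, 2L)[type + 1L]

#' Seed-and-extend overlap between two reads
#'
#' Extends an exact seed match with banded global alignment of the overlap
#' region implied by the seed diagonal and returns an edge when the dovetail
#' or containment overlap meets the length and identity thresholds.
#'
#' @param query,ref single-row [read_set()]s (or lists with `id` and `seq`).
#' @param seed list with `query_pos` and `ref_pos` (0-based seed offsets).
#' @param cfg an [align_config()].
#' @return one-row edge data.frame (`u`, `v`, `overlap_len`, `identity`,
#'   `type`) or `NULL` when thresholds are not met.
#' @export
find_overlap <- function(query, ref, seed, cfg = align_config()) {
  r <- .overlap_from_seed_cpp(query$seq[[1]], ref$seq[[1]],
                              as.integer(seed$query_pos),
                              as.integer(seed$ref_pos), cfg$band)
  if (r[1] == 0) return(NULL)
  cols <- r[2]; ident <- r[3] / max(1L, cols)
  if (cols < cfg$min_overlap || ident < cfg$min_identity) return(NULL)
  u <- query$id[[1]]; v <- ref$id[[1]]; type <- r[4]
  if (v < u) { tmp <- u; u <- v; v <- tmp; type <- .swap_type(type) }
  data.frame(u = u, v = v, overlap_len = cols, identity = ident, type = type)
}

#' All-vs-all overlap detection over read subsets
#'
#' Every subset pair (including each subset against itself) is scanned
#' query-versus-reference: query reads are decomposed into k-mer seeds at a
#' fixed step, seeds are located in the reference suffix array, and each read
#' pair is aligned once from its first seed. The deduplicated edge list is
#' independent of the number of subsets.
#'
#' @param subsets list of [read_set()]s from [partition_reads()] (or a single
#'   read set).
#' @param cfg an [align_config()].
#' @return sorted, deduplicated edge data.frame (see [sort_dedup_edges()]).
#' @export
all_vs_all_overlaps <- function(subsets, cfg = align_config()) {
  if (is.data.frame(subsets)) subsets <- list(subsets)
  subsets <- Filter(function(s) nrow(s) > 0, subsets)
  m <- length(subsets)
  gid <- 0L
  gids <- lapply(subsets, function(s) {
    out <- gid + seq_len(nrow(s)); gid <<- gid + nrow(s); out
  })
  pieces <- list()
  for (j in seq_len(m)) {
    idx <- build_suffix_array(subsets[[j]])
    for (i in seq_len(j)) {
      sc <- .scan_subset_pair_cpp(subsets[[i]]$seq, gids[[i]],
                                  subsets[[j]]$seq, gids[[j]],
                                  idx$text, idx$sa, idx$ref_start,
                                  cfg$k, cfg$step, cfg$band,
                                  cfg$min_overlap, cfg$min_identity)
      if (nrow(sc) == 0) next
      u <- subsets[[i]]$id[sc$qi]
      v <- subsets[[j]]$id[sc$ri]
      type <- sc$type
      swap <- v < u
      if (any(swap)) {
        tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
        type[swap] <- .swap_type(type[swap])
      }
      pieces[[length(pieces) + 1L]] <-
        data.frame(u = u, v = v, overlap_len = sc$overlap_len,
                   identity = sc$identity, type = type)
    }
  }
  edges <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(u = character(0), v = character(0), overlap_len = integer(0),
               identity = numeric(0), type = integer(0))
  sort_dedup_edges(edges)
}

#' Sort and deduplicate an overlap edge list
#'
#' Edges are ordered by query read id ascending and, within a query id, by
#' descending overlap length; duplicate edges with the same (unordered)
#' endpoints are removed, keeping the longest overlap.
#'
#' @param edges edge data.frame with columns `u`, `v`, `overlap_len` (and
#'   optionally `identity`, `type`).
#' @return the sorted, deduplicated edge data.frame.
#' @export
sort_dedup_edges <- function(edges) {
  if (nrow(edges) == 0) return(edges)
  u <- pmin(edges$u, edges$v); v <- pmax(edges$u, edges$v)
  swap <- edges$u != u
  edges$u <- u; edges$v <- v
  if ("type" %in% names(edges) && any(swap))
    edges$type[swap] <- .swap_type(edges$type[swap])
  o <- order(edges$u, -edges$overlap_len, edges$v)
  edges <- edges[o, , drop = FALSE]
  dup <- duplicated(paste(edges$u, edges$v, sep = "\r"))
  edges <- edges[!dup, , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Write an edge list as TSV
#'
#' Columns: `query_id`, `ref_id`, `overlap_len`, `identity`.
#' @param edges edge data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(edges, path) {
  out <- data.frame(query_id = edges$u, ref_id = edges$v,
                    overlap_len = edges$overlap_len, identity = edges$identity)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
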