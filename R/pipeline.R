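#' Run the full assembly-and-mining pipeline
#'
#' Preprocess reads, detect pairwise overlaps, build and coarsen the overlap
#' graph, select best representatives into the hybrid graph, trim it, and
#' score every node with Shannon's index.
#'
#' @param reads raw [read_set()].
#' @param trim a [trim_config()].
#' @param align an [align_config()].
#' @param coarsen a [coarsen_config()].
#' @param clean a [clean_config()].
#' @param n_subsets read subsets for the pairwise aligner (affects wall time
#'   and memory only, never results).
#' @return list with `reads` (processed), `edges`, `levels`, `hybrid`
#'   (trimmed, with `$scores`), and `stats`.
#' @export
run_pipeline <- function(reads, trim = trim_config(), align = align_config(),
                         coarsen = coarsen_config(), clean = clean_config(),
                         n_subsets = 1L) {
  pre <- preprocess_reads(reads, trim)
  subsets <- partition_reads(pre$reads, n_subsets)
  edges <- all_vs_all_overlaps(subsets, align)
  g0 <- build_overlap_graph(edges, pre$reads$id)
  levels <- coarsen_all(g0, coarsen)
  hg <- select_representatives(levels, pre$reads, clean)
  hg <- trim_hybrid(hg, clean)
  hg$scores <- score_all(hg)
  list(reads = pre$reads, edges = edges, levels = levels, hybrid = hg,
       stats = pre$stats)
}

#' @keywords internal
"_PACKAGE"

#' @useDynLib ogmine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL
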