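#' Construct a read set
#'
#' A read set is a plain data.frame with one row per read: `id` (character),
#' `seq` (character over A/C/G/T/N), `qual` (list column of integer Phred
#' scores, or `NULL` entries when absent, e.g. FASTA input) and `is_revcomp`
#' (logical; whether the record is a generated reverse complement).
#'
#' @param id character vector of read identifiers (unique).
#' @param seq character vector of nucleotide sequences.
#' @param qual optional list of integer vectors, one per read, each the same
#'   length as its sequence. `NULL` for no qualities.
#' @param is_revcomp logical vector, recycled.
#' @return a `read_set` data.frame.
#' @export
read_set <- function(id, seq, qual = NULL, is_revcomp = FALSE) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  stopifnot(length(id) == length(seq), !anyDuplicated(id))
  if (is.null(qual)) {
    qual <- vector("list", length(seq))
  } else {
    stopifnot(length(qual) == length(seq))
    ok <- vapply(seq_along(qual), function(i)
      is.null(qual[[i]]) || length(qual[[i]]) == nchar(seq[[i]]), logical(1))
    if (!all(ok))
      stop("quality vector length must equal sequence length (read ",
           id[which(!ok)[1]], ")")
  }
  df <- data.frame(id = id, seq = seq, is_revcomp = rep_len(is_revcomp, length(seq)),
                   stringsAsFactors = FALSE)
  df$qual <- qual
  class(df) <- c("read_set", "data.frame")
  df
}

#' Read sequences from FASTA or FASTQ
#'
#' Format is detected from the first character (`@` = FASTQ, `>` = FASTA).
#' FASTQ qualities are decoded as Sanger Phred+33.
#'
#' @param path file path.
#' @return a [read_set()].
#' @export
read_sequences <- function(path) {
  first <- substr(readLines(path, n = 1L), 1L, 1L)
  if (identical(first, "@")) {
    # the reader attaches mcols the quality container then drops, warning
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    qual <- lapply(as(Biostrings::quality(x), "IntegerList"), as.integer)
    ids <- sub("\\s.*$", "", names(x))
    read_set(ids, as.character(x), qual)
  } else {
    x <- Biostrings::readDNAStringSet(path)
    ids <- sub("\\s.*$", "", names(x))
    read_set(ids, as.character(x))
  }
}

#' Write a read set to FASTQ (or FASTA when no qualities are present)
#'
#' @param reads a [read_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  has_qual <- !vapply(reads$qual, is.null, logical(1))
  if (all(has_qual) && nrow(reads) > 0) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(reads))) {
      writeLines(c(paste0("@", reads$id[i]), reads$seq[i], "+",
                   rawToChar(as.raw(reads$qual[[i]] + 33L))), con)
    }
  } else {
    x <- Biostrings::DNAStringSet(reads$seq)
    names(x) <- reads$id
    Biostrings::writeXStringSet(x, path)
  }
  invisible(path)
}

#' Trimming configuration
#'
#' @param l1 bases removed from the 5' end (fixed-length trim).
#' @param l2 bases removed from the 3' end.
#' @param w sliding-window length for quality trimming.
#' @param q minimum average window quality (strictly greater passes).
#' @param min_len reads shorter than this after all trimming are discarded.
#' @return a `trim_config` list.
#' @export
trim_config <- function(l1 = 0L, l2 = 0L, w = 10L, q = 25, min_len = 75L) {
  stopifnot(l1 >= 0, l2 >= 0, w >= 1, min_len >= 0)
  structure(list(l1 = as.integer(l1), l2 = as.integer(l2), w = as.integer(w),
                 q = q, min_len = as.integer(min_len)),
            class = "trim_config")
}

#' Fixed-length end trimming
#'
#' Removes `l1` bases from the 5' end and `l2` from the 3' end of each
#' forward read. For reverse-complement records the ends are mirrored (`l2`
#' off the 5' end, `l1` off the 3' end) so that trimming commutes with
#' reverse complementation. Over-trimmed reads become empty and are removed
#' by the downstream length filter, never here.
#'
#' @param reads a [read_set()].
#' @param l1,l2 non-negative trim lengths in bp.
#' @return the trimmed read set.
#' @export
trim_fixed <- function(reads, l1, l2) {
  stopifnot(l1 >= 0, l2 >= 0)
  n <- nchar(reads$seq)
  a <- ifelse(reads$is_revcomp, l2, l1)   # bases off the left end
  b <- ifelse(reads$is_revcomp, l1, l2)   # bases off the right end
  keep_len <- pmax(0L, n - a - b)
  from <- ifelse(keep_len > 0L, a + 1L, 1L)
  to <- ifelse(keep_len > 0L, n - b, 0L)
  reads$seq <- substr(reads$seq, from, to)
  reads$qual <- lapply(seq_len(nrow(reads)), function(i) {
    qv <- reads$qual[[i]]
    if (is.null(qv) || keep_len[i] == 0L) {
      if (is.null(qv)) NULL else integer(0)
    } else qv[from[i]:to[i]]
  })
  reads
}

#' Quality-window trimming
#'
#' Slides a window of length `w` from the 3' end towards the 5' end and stops
#' at the first window whose mean quality is strictly greater than `q`; the
#' read is cut so that the right endpoint of that window becomes the new 3'
#' end. If no window qualifies the read becomes empty (and is discarded by
#' the length filter). For reverse-complement records the scan is mirrored
#' (5' towards 3'). Reads without qualities are left untouched; one warning
#' is emitted per call.
#'
#' @param reads a [read_set()].
#' @param w window length in bp.
#' @param q minimum average quality.
#' @return the trimmed read set.
#' @export
trim_quality <- function(reads, w, q) {
  stopifnot(w >= 1)
  no_qual <- vapply(reads$qual, is.null, logical(1))
  if (any(no_qual) && any(!no_qual | TRUE))
    if (any(no_qual)) warning("reads without qualities skipped quality trimming (",
                              sum(no_qual), " reads)")
  cut_one <- function(qv, mirrored) {
    n <- length(qv)
    if (n == 0L) return(0L)
    if (n < w) return(if (mean(qv) > q) n else 0L)
    if (!mirrored) {
      for (s in (n - w + 1L):1L) {            # window [s, s+w-1], 3' -> 5'
        if (mean(qv[s:(s + w - 1L)]) > q) return(s + w - 1L)
      }
    } else {
      for (s in 1L:(n - w + 1L)) {            # mirrored scan, 5' -> 3'
        if (mean(qv[s:(s + w - 1L)]) > q) return(-s)  # keep suffix from s
      }
    }
    0L
  }
  for (i in seq_len(nrow(reads))) {
    qv <- reads$qual[[i]]
    if (is.null(qv)) next
    k <- cut_one(qv, reads$is_revcomp[i])
    if (k >= 0L) {  # keep prefix 1..k
      reads$seq[i] <- substr(reads$seq[i], 1L, k)
      reads$qual[[i]] <- qv[seq_len(k)]
    } else {        # keep suffix from -k
      s <- -k
      reads$seq[i] <- substr(reads$seq[i], s, nchar(reads$seq[i]))
      reads$qual[[i]] <- qv[s:length(qv)]
    }
  }
  reads
}

REVCOMP_SUFFIX <- "/rc"

#' Reverse complement of a nucleotide string vector
#'
#' @param seq character vector over A/C/G/T/N.
#' @return reverse-complemented character vector.
#' @export
revcomp_seq <- function(seq) {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) stop("non-ACGTN character in sequence ", which(bad)[1])
  vapply(seq, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

#' Reverse complement reads
#'
#' Complements and reverses each sequence (N maps to N), reverses qualities,
#' flips the `is_revcomp` flag and toggles a reserved `/rc` id suffix so that
#' original/reverse-complement pairing is recoverable from output files.
#' Applying it twice returns the original records.
#'
#' @param reads a [read_set()].
#' @return the reverse-complemented read set.
#' @export
revcomp <- function(reads) {
  bad <- grepl("[^ACGTN]", reads$seq)
  if (any(bad))
    stop("non-ACGTN character in read ", reads$id[which(bad)[1]])
  reads$seq <- revcomp_seq(reads$seq)
  reads$qual <- lapply(reads$qual, function(qv) if (is.null(qv)) NULL else rev(qv))
  has_sfx <- endsWith(reads$id, REVCOMP_SUFFIX)
  reads$id <- ifelse(has_sfx,
                     substr(reads$id, 1L, nchar(reads$id) - nchar(REVCOMP_SUFFIX)),
                     paste0(reads$id, REVCOMP_SUFFIX))
  reads$is_revcomp <- !reads$is_revcomp
  reads
}

#' Partition reads into subsets
#'
#' Deterministic contiguous split by input order; subset sizes differ by at
#' most one and their union is the input.
#'
#' @param reads a [read_set()].
#' @param n_subsets number of subsets (>= 1); may exceed the read count, in
#'   which case trailing subsets are empty.
#' @return a list of `n_subsets` read sets.
#' @export
partition_reads <- function(reads, n_subsets) {
  stopifnot(n_subsets >= 1)
  n <- nrow(reads)
  base <- n %/% n_subsets
  extra <- n %% n_subsets
  sizes <- rep(base, n_subsets) + c(rep(1L, extra), rep(0L, n_subsets - extra))
  idx <- cumsum(c(0L, sizes))
  lapply(seq_len(n_subsets), function(i) {
    r <- reads[seq_len(sizes[i]) + idx[i], , drop = FALSE]
    rownames(r) <- NULL
    r
  })
}

#' Preprocess a read set
#'
#' Applies fixed-length trimming, quality-window trimming, the minimum-length
#' discard rule, and generates the reverse complement of every retained read,
#' in that order. The returned set therefore satisfies orientation closure:
#' every retained read has exactly one reverse-complement partner. Output is
#' byte-identical for identical inputs regardless of how reads are later
#' partitioned.
#'
#' @param reads a [read_set()].
#' @param cfg a [trim_config()].
#' @return a list with `reads` (the processed set, originals followed by
#'   their reverse complements) and `stats` (input/discarded/output counts).
#' @export
preprocess_reads <- function(reads, cfg = trim_config()) {
  n_in <- nrow(reads)
  reads <- trim_fixed(reads, cfg$l1, cfg$l2)
  has_qual <- any(!vapply(reads$qual, is.null, logical(1)))
  if (has_qual) reads <- trim_quality(reads, cfg$w, cfg$q)
  keep <- nchar(reads$seq) >= cfg$min_len & nchar(reads$seq) > 0L
  discarded <- sum(!keep)
  reads <- reads[keep, , drop = FALSE]
  rownames(reads) <- NULL
  rc <- revcomp(reads)
  out <- rbind(reads, rc)
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  list(reads = out,
       stats = list(input = n_in, discarded = discarded, output = nrow(out)))
}
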