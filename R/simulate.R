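#' Synthetic community configuration
#'
#' Defaults describe a small multi-genome community: three circular 20 kb
#' genomes that all carry one identical 1 kb transposon-like element (25 bp
#' inverted-repeat flanks), two identical 800 bp rRNA-like segments per
#' genome (shared across genomes, as conserved operons are), a 600 bp
#' "resistance"-class segment placed 2 kb from each element copy, and a few
#' background "control"-class segments far from any element so that
#' enrichment tests have a non-degenerate background. Reads are sampled at
#' uniform 20x coverage from both strands.
#'
#' @param n_genomes number of genomes (one genus each).
#' @param genome_len genome length in bp.
#' @param transposon_len total element length including both inverted
#'   repeats.
#' @param transposon_carriers indices of genomes carrying the element; a
#'   list of index vectors plants one distinct element per carrier group
#'   (each group shares its own sequence).
#' @param ir_len inverted-repeat flank length in bp.
#' @param rrna_copies identical rRNA-like copies per genome.
#' @param rrna_len length of the rRNA-like segment.
#' @param resistance_offset distance (bp) from the element end to the planted
#'   resistance segment.
#' @param resistance_carriers genomes whose element copies get a linked
#'   resistance segment (default: all carriers).
#' @param resistance_len,control_len planted gene-segment lengths.
#' @param n_control control-class segments per genome.
#' @param control_clearance minimum genomic distance (bp) between a control
#'   segment and any transposon element copy, so the background class stays
#'   away from element neighborhoods.
#' @param coverage fold coverage per genome.
#' @param read_len read length in bp.
#' @param error_rate per-base substitution probability.
#' @param qual_mean,qual_sd Phred quality model (Normal, clamped to 2..40).
#' @param circular sample reads across the origin (bacterial chromosomes).
#' @param layout `"uniform"` (random start positions) or `"tiled"`
#'   (deterministic evenly spaced starts covering the whole genome, both ends
#'   included; useful for exact-reconstruction checks).
#' @param seed RNG seed.
#' @return a `community_config` list.
#' @export
community_config <- function(n_genomes = 3L, genome_len = 20000L,
                             transposon_len = 1000L,
                             transposon_carriers = list(seq_len(n_genomes)),
                             ir_len = 25L, rrna_copies = 2L, rrna_len = 800L,
                             resistance_offset = 2000L,
                             resistance_carriers = transposon_carriers,
                             resistance_len = 600L, control_len = 600L,
                             n_control = 4L, control_clearance = 5000L,
                             coverage = 20, read_len = 100L,
                             error_rate = 0, qual_mean = 35, qual_sd = 3,
                             circular = TRUE,
                             layout = c("uniform", "tiled"), seed = 1L) {
  layout <- match.arg(layout)
  if (!is.list(transposon_carriers))
    transposon_carriers <- if (length(transposon_carriers) > 0)
      list(transposon_carriers) else list()
  if (!is.list(resistance_carriers))
    resistance_carriers <- if (length(resistance_carriers) > 0)
      list(resistance_carriers) else list()
  for (nm in c("n_genomes", "genome_len", "transposon_len", "ir_len",
               "rrna_copies", "rrna_len", "resistance_offset",
               "resistance_len", "control_len", "n_control",
               "control_clearance", "read_len", "seed"))
    assign(nm, as.integer(get(nm)))
  rm(nm)
  stopifnot(coverage > 0, ir_len * 2 < transposon_len)
  if (length(transposon_carriers) > 0)
    stopifnot(transposon_len < genome_len / 10)
  structure(as.list(environment()), class = "community_config")
}

.rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

#' Simulate a synthetic microbial community
#'
#' Generates uniform-composition random genomes and plants, by replacement at
#' non-overlapping loci: one transposon-like element (identical across
#' carrier genomes, flanked by an inverted repeat pair), identical rRNA-like
#' segments shared by all genomes, one resistance-class segment near each
#' element copy of the resistance carriers, and background control-class
#' segments away from all elements. Deterministic under the config seed.
#'
#' @param cfg a [community_config()].
#' @return list with `genomes` (named character), `elements` (data.frame of
#'   planted features: `genome`, `start`, `end` 0-based half-open, `kind`,
#'   `class`) and `cfg`.
#' @export
simulate_community <- function(cfg = community_config()) {
  set.seed(cfg$seed)
  L <- cfg$genome_len
  genomes <- vapply(seq_len(cfg$n_genomes), function(i) .rand_seq(L),
                    character(1))
  names(genomes) <- paste0("genome_", seq_len(cfg$n_genomes))
  transposons <- lapply(cfg$transposon_carriers, function(grp) {
    ir <- .rand_seq(cfg$ir_len)
    paste0(ir, .rand_seq(cfg$transposon_len - 2L * cfg$ir_len),
           revcomp_seq(ir))
  })
  rrna <- .rand_seq(cfg$rrna_len)
  resistance <- .rand_seq(cfg$resistance_len)
  controls <- vapply(seq_len(max(1L, cfg$n_control)), function(i)
    .rand_seq(cfg$control_len), character(1))
  margin <- 2L * cfg$read_len
  elements <- list()
  place <- function(g, len, occupied, clear = margin) {
    for (try in 1:200) {
      s <- sample.int(L - len - margin, 1L)
      if (!any(s < occupied$end + clear & s + len + clear > occupied$start))
        return(s)
    }
    stop("could not place a ", len, " bp segment in genome ", g)
  }
  for (g in seq_len(cfg$n_genomes)) {
    occ <- data.frame(start = integer(0), end = integer(0))
    add <- function(s, len, kind, class = NA_character_) {
      elements[[length(elements) + 1L]] <<-
        data.frame(genome = g, start = s, end = s + len, kind = kind,
                   class = class)
      occ <<- rbind(occ, data.frame(start = s, end = s + len))
    }
    splice <- function(s, seqstr) {
      substr(genomes[g], s + 1L, s + nchar(seqstr)) <<- seqstr
    }
    for (k in seq_along(cfg$transposon_carriers)) {
      if (!g %in% cfg$transposon_carriers[[k]]) next
      linked <- g %in% unlist(cfg$resistance_carriers)
      span <- cfg$transposon_len + cfg$resistance_offset + cfg$resistance_len
      s <- place(g, if (linked) span else cfg$transposon_len, occ)
      splice(s, transposons[[k]])
      add(s, cfg$transposon_len, "transposon", paste0("tn", k))
      if (linked) {
        rs <- s + cfg$transposon_len + cfg$resistance_offset -
          cfg$resistance_len
        splice(rs, resistance)
        add(rs, cfg$resistance_len, "gene", "resistance")
        # reserve the spacer so nothing else lands between element and gene
        occ <- rbind(occ, data.frame(start = s, end = rs + cfg$resistance_len))
      }
    }
    for (r in seq_len(cfg$rrna_copies)) {
      s <- place(g, cfg$rrna_len, occ)
      splice(s, rrna)
      add(s, cfg$rrna_len, "rrna")
    }
    for (ci in seq_len(cfg$n_control)) {
      # keep background segments clear of the element so the enrichment
      # background is genuinely outside element neighborhoods
      el_occ <- occ
      idx <- which(vapply(elements, function(e)
        e$genome == g && e$kind == "transposon", logical(1)))
      if (length(idx) > 0) {
        tr <- do.call(rbind, elements[idx])
        el_occ <- rbind(occ, data.frame(
          start = tr$start - cfg$control_clearance,
          end = tr$end + cfg$control_clearance))
      }
      s <- place(g, cfg$control_len, el_occ)
      splice(s, controls[ci])
      add(s, cfg$control_len, "gene", "control")
    }
  }
  list(genomes = genomes, elements = do.call(rbind, elements), cfg = cfg)
}

#' Sample error-bearing reads from simulated genomes
#'
#' Uniform start positions (wrapping across the origin for circular genomes),
#' both strands, i.i.d. substitution errors and Normal Phred qualities
#' clamped to 2..40. Read count per genome is
#' `round(coverage * genome_len / read_len)`.
#'
#' @param community output of [simulate_community()].
#' @return list with `reads` (a [read_set()]) and `truth` (per-read
#'   data.frame: `id`, `genome`, `start` 0-based on the forward strand,
#'   `strand`).
#' @export
sample_reads <- function(community) {
  cfg <- community$cfg
  set.seed(cfg$seed + 1L)
  L <- cfg$genome_len; rl <- cfg$read_len
  n_per <- round(cfg$coverage * L / rl)
  ids <- character(0); seqs <- character(0); quals <- list()
  truth <- list()
  for (g in seq_len(cfg$n_genomes)) {
    gseq <- community$genomes[[g]]
    gseq2 <- paste0(gseq, substr(gseq, 1L, rl))  # wrap pad
    if (cfg$layout == "tiled") {
      stride <- max(1L, as.integer(round(rl / cfg$coverage)))
      starts <- unique(c(seq(0L, L - rl, by = stride), L - rl))
      n_per <- length(starts)
      strands <- rep("+", n_per)
    } else {
      starts <- if (cfg$circular) sample.int(L, n_per, TRUE) - 1L else
        sample.int(L - rl + 1L, n_per, TRUE) - 1L
      strands <- sample(c("+", "-"), n_per, TRUE)
    }
    for (i in seq_len(n_per)) {
      s <- starts[i]
      r <- substr(gseq2, s + 1L, s + rl)
      if (strands[i] == "-") r <- revcomp_seq(r)
      if (cfg$error_rate > 0) {
        nerr <- stats::rbinom(1L, rl, cfg$error_rate)
        if (nerr > 0) {
          pos <- sample.int(rl, nerr)
          cur <- substring(r, pos, pos)
          sub <- vapply(cur, function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
          for (j in seq_len(nerr))
            substr(r, pos[j], pos[j]) <- sub[j]
        }
      }
      qv <- as.integer(pmin(40, pmax(2, round(stats::rnorm(rl, cfg$qual_mean,
                                                           cfg$qual_sd)))))
      id <- sprintf("g%d_r%04d", g, i)
      ids <- c(ids, id); seqs <- c(seqs, r); quals[[length(quals) + 1L]] <- qv
      truth[[length(truth) + 1L]] <-
        data.frame(id = id, genome = g, start = s, strand = strands[i])
    }
  }
  list(reads = read_set(ids, seqs, quals),
       truth = do.call(rbind, truth))
}

# overlap length between a read interval [s, s+rl) (possibly wrapping mod L)
# and a segment [a, b)
.wrap_overlap <- function(s, rl, a, b, L) {
  e <- s + rl
  if (e <= L) return(max(0L, min(e, b) - max(s, a)))
  max(0L, min(L, b) - max(s, a)) + max(0L, min(e - L, b) - a)
}

#' Ground-truth annotation tables for hybrid-graph contigs
#'
#' Labels each hybrid node from its member reads' true source coordinates:
#' genus by majority read vote (genus = source genome), a `transposase` tag
#' when member reads overlap a planted element by at least `min_bp`, and one
#' gene-class hit per planted gene class the members overlap. Stands in for
#' external read-mapping and protein-alignment annotation steps.
#'
#' @param community output of [simulate_community()].
#' @param read_truth per-read truth from [sample_reads()].
#' @param hg a `hybrid_graph`.
#' @param min_bp minimum read/segment overlap (bp) for a feature call.
#' @return list of data.frames: `taxa` (`node`, `genus`), `tags` (`node`,
#'   `tag`), `genes` (`node`, `class`).
#' @export
truth_annotations <- function(community, read_truth, hg, min_bp = 50L) {
  cfg <- community$cfg
  el <- community$elements
  rl <- cfg$read_len; L <- cfg$genome_len
  base_id <- function(ids) sub("/rc$", "", ids)
  taxa <- list(); tags <- list(); genes <- list()
  for (i in seq_len(hg$n_nodes)) {
    mem_ids <- base_id(hg$read_ids[hg$member_reads[[i]]])
    tr <- read_truth[match(mem_ids, read_truth$id), , drop = FALSE]
    if (nrow(tr) == 0L || all(is.na(tr$genome))) {
      taxa[[length(taxa) + 1L]] <- data.frame(node = i, genus = "unknown")
      next
    }
    cnt <- table(tr$genome)
    g_major <- as.integer(names(cnt)[which.max(cnt)])
    taxa[[length(taxa) + 1L]] <-
      data.frame(node = i, genus = paste0("genus_", g_major))
    hit_kinds <- character(0); hit_classes <- character(0)
    for (j in seq_len(nrow(el))) {
      sel <- tr$genome == el$genome[j]
      if (!any(sel)) next
      ov <- vapply(tr$start[sel], .wrap_overlap, numeric(1), rl = rl,
                   a = el$start[j], b = el$end[j], L = L)
      if (max(ov) >= min_bp) {
        hit_kinds <- c(hit_kinds, el$kind[j])
        if (el$kind[j] == "gene") hit_classes <- c(hit_classes, el$class[j])
      }
    }
    if ("transposon" %in% hit_kinds)
      tags[[length(tags) + 1L]] <- data.frame(node = i, tag = "transposase")
    if ("rrna" %in% hit_kinds)
      tags[[length(tags) + 1L]] <- data.frame(node = i, tag = "rrna")
    for (cl in unique(hit_classes))
      genes[[length(genes) + 1L]] <- data.frame(node = i, class = cl)
  }
  bindf <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  list(taxa = bindf(taxa, data.frame(node = integer(0), genus = character(0))),
       tags = bindf(tags, data.frame(node = integer(0), tag = character(0))),
       genes = bindf(genes, data.frame(node = integer(0), class = character(0))))
}
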