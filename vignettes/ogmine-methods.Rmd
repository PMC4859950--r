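---
title: "Assembly-graph mining with ogmine: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly-graph mining with ogmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Short-read assembly collapses read overlap relationships into flat contigs,
discarding exactly the structural information that distinguishes a unique
genomic region from a repeat or from a region conserved between species. In
a metagenome, mobile genetic elements — insertion sequences and composite
transposons, whose cargo often includes antibiotic-resistance genes — and
multi-copy repeats such as rRNA operons are visible *in the assembly graph*
as nodes with many incident edges, even when the flat contigs say nothing
about them. `ogmine` keeps that structure: it assembles reads into a
**hybrid graph** whose nodes represent sequence regions at the coarsest
granularity that still assembles cleanly, scores every node with Shannon's
diversity index over its incident edge weights, and mines high-diversity
nodes for transposase-associated gene-class enrichment in their graph
neighborhoods.

## The pipeline

1. **Preprocessing** (`preprocess_reads`). Fixed-length 5'/3' trimming
   (`l1`, `l2`), quality-window trimming (a window of `w` bases slides from
   the 3' end towards the 5' end until its mean quality strictly exceeds
   `q`; the read is cut at that window's right endpoint), a minimum-length
   discard rule (default 75 bp), and generation of the reverse complement of
   every retained read. Both orientations are treated as alignable reads;
   the `/rc` id suffix keeps pairing recoverable.

2. **Pairwise overlap detection** (`all_vs_all_overlaps`). Reads are
   partitioned into subsets; each subset pair is scanned
   query-versus-reference. The reference subset is concatenated and indexed
   by a suffix array; query reads are decomposed into `k`-mers (default
   k = 16) at step 4, each exact seed match is extended by a banded global
   alignment (half-width 10, match +1 / mismatch −1 / gap −2) of the overlap
   region implied by the seed diagonal, and dovetail or containment
   overlaps of at least 40 columns at ≥ 95 % identity become edges weighted
   by overlap length. One alignment is attempted per read pair (first seed
   wins); the deduplicated edge list — query id ascending, overlap length
   descending, longest record kept per unordered pair — is independent of
   the subset count.

3. **Multilevel coarsening** (`coarsen_all`). The overlap graph G0 (one node
   per read, cluster node weight `nw = 1`, cluster edge weight `ew = 0`) is
   repeatedly reduced by heavy-edge matching and contraction. Nodes are
   visited in passes by decreasing maximum incident edge weight; each node
   scans its neighbors in decreasing edge-weight order, stops (and stays
   unmatched) at the first edge under `min_edge_weight`, and accepts the
   first unmatched neighbor for which the density of the would-be merged
   cluster,
   `2 (ew_i + ew_j + w_ij) / ((nw_i + nw_j)(nw_i + nw_j − 1))`,
   reaches `min_density` — a density failure continues the scan. Matched
   pairs contract into super nodes (`nw` summed; `ew` summed plus the
   contracted edge weight; parallel edges added together), so at every level
   Σ nw equals |G0| and Σ ew + Σ edge weights equals the G0 edge-weight
   total, exactly. Coarsening stops when the matched-node ratio falls under
   `stop_ratio` (default 0.1).

4. **Hybrid-graph integration** (`select_representatives`). From the most
   reduced level downward, each super node's read-level cluster subgraph is
   cleaned — short dead-end branches clipped (≤ 3 nodes, clipping one
   shortest-and-lightest tip at a time so genuine path ends survive), simple
   bubbles resolved in favor of the heavier path, transitive edges removed
   (an edge is transitive when a surviving witness node connects its
   endpoints through edges at least as heavy), iterated to a fixed point —
   and tested for being a single path. Passing nodes become best
   representatives: their contig is assembled by laying reads left-to-right
   along the path with majority-vote consensus, and all their descendants
   are blocked. Level 0 guarantees termination, so the representatives'
   member reads partition the read set. Edges between representatives carry
   the summed inter-cluster G0 overlap weights. The trimming step
   (`trim_hybrid`) then removes nodes whose short contigs (< 2 × read
   length) map into a neighbor's contig at ≥ 95 % identity, re-checking to a
   fixed point, and removes transitive hybrid edges.

5. **Mining** (`score_all`, `select_high_nodes`, `tax_vector`,
   `cluster_transposase_nodes`, `k_neighborhood`, `enrichment_test`). Every
   node receives `H = −Σ (w_i/W) ln(w_i/W)` over its incident edge weights
   (0 for ≤ 1 edge; maximum ln n). A node on a clean path has two roughly
   even edges and scores near ln 2 ≈ 0.69; the high-score threshold is set
   at 1, just under ln 3 ≈ 1.1, so that a unique-region node with one
   spurious light edge is not selected. Transposase-tagged nodes above the
   threshold get a neighborhood taxonomy vector (length-weighted genus
   shares of adjacent contigs; nodes over 20 % unknown are excluded), are
   clustered by k-means on Euclidean distance (fixed seed, 50 restarts;
   within-cluster sum of squares over k = 1..k_max as elbow data), and each
   cluster's union of 5-neighborhoods is tested per gene class with a
   one-sided Fisher's exact test (class hits vs other hits, inside vs
   outside, one count per node-class pair) under Benjamini–Hochberg FDR.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `l1`, `l2` | 0, 0 | fixed 5'/3' trim (bp); studies with adapters use e.g. 20/50 |
| `w`, `q` | 10, 25 | quality window length (bp) and mean-quality floor |
| `min_len` | 75 | post-trim discard threshold (bp) |
| `k`, `step` | 16, 4 | seed length and query scan step (bp) |
| `band` | 10 | alignment band half-width (bp of diagonal drift) |
| `min_overlap`, `min_identity` | 40 bp, 0.95 | edge acceptance thresholds |
| `min_density` | 8 | compactness floor for cluster merges (see below) |
| `n_passes`, `stop_ratio` | 4, 0.1 | HEM visit passes; coarsening stop |
| `max_tip_len` | 3 nodes | dead-end branch clipping bound |
| `max_containment_len` | 200 bp | hybrid filter: only shorter contigs tested |
| Shannon threshold | 1.0 | high-diversity cutoff (just under ln 3) |
| `radius` | 5 | neighborhood ball for enrichment |
| `max_unknown` | 0.20 | unknown-fraction cap for clustering |

**Why `min_density` = 8.** The density of a merged cluster is its total
intra-cluster G0 overlap weight divided by the pair count of a complete
graph on its reads. For ~100 bp reads at ~20× coverage a *single-copy*
linear cluster of m reads has density ≈ 1680/m: it falls as the cluster
grows, so a floor of 8 stops single-copy clusters near ~200 reads (~1 kb
genomic span). A repeat family present in c copies has c-fold more
intra-cluster overlap (density ≈ c·1680/m) and keeps collapsing into one
super node. The default therefore yields hybrid graphs with approximately
uniform ~1 kb node granularity for unique sequence while repeats are fully
reduced — which keeps graph path distance proportional to genomic distance,
the property the fixed-radius neighborhood mining relies on. Earlier
development versions with a much lower floor produced mixed granularity
(multi-kb arcs next to sub-kb fragments) that distorted neighborhood
geometry. For pure assembly of a low-complexity sample (where maximal
contiguity is wanted and no mining follows), set `min_density = 0`.

## The synthetic-data generator

`simulate_community()` emulates the biology the miner targets: by default
three circular 20 kb single-genus genomes, each carrying one identical 1 kb
transposon-like element flanked by 25 bp inverted repeats, two identical
800 bp rRNA-like segments per genome (shared across genomes, as conserved
operons are), one 600 bp "resistance"-class segment ending 2 kb after each
element copy, and four 600 bp "control"-class segments per genome kept at
least 5 kb from the element so the enrichment background is informative.
Passing a list of carrier groups plants one distinct element per group
(identical within a group), which is how the clustering checks build
communities where two transposons travel in different genus sets.
`sample_reads()` draws uniform start positions (wrapping the origin for
circular genomes) on both strands at 20× coverage, applies i.i.d.
substitution errors (default rate 0 for the headline error-free analyses;
no indels) and Normal(35, 3) Phred qualities clamped to 2..40. A `tiled`
layout with deterministic evenly spaced starts is available for
exact-reconstruction checks, since uniform random sampling leaves the outer
few bases of a *linear* genome uncovered with high probability. Circular
genomes are the default both because bacterial chromosomes are circular and
because linear truncation produces zero-entropy end nodes that are artifacts
of the simulation rather than of the method.

`truth_annotations()` stands in for the external read-mapping and
protein-alignment steps a real study would run: each hybrid node is labeled
with the majority source genome of its member reads (genus = genome),
tagged `transposase`/`rrna` when member reads overlap a planted feature by
at least 50 bp, and given one gene-class hit per planted class its members
overlap.

**What the simulation does not capture.** Uniform base composition and
abundances, substitution-only errors, identical repeat copies (no
within-family divergence), no chimeras, no strain variation, and genomes
three orders of magnitude shorter than real bacterial chromosomes. Passing
tests on these data show the algorithmic machinery is correct and that the
planted structural signal is recovered; they do not certify performance on
real gut metagenomes.

## Numerical and degenerate-case choices

- Quality windows pass on *strictly* greater mean quality; ties trim.
- Reads shorter than the quality window are kept only if their whole-read
  mean passes.
- Equal-weight HEM neighbor ties break to the lowest node id; visit order
  within a pass is ascending node id. Everything is deterministic given the
  input order; the subset count changes wall time only.
- Transitive-reduction removals are examined in ascending (weight, u, v)
  order and removed edges cannot serve as witnesses, so a twin pair cannot
  erase both of its links to the chain.
- Consensus ties at overlapping columns resolve to the earliest-starting
  read's base.
- An isolated node scores H = 0; `tax_vector` on a neighbor-less node is an
  error rather than a zero vector.
- A single node counts as a (trivial) single path; cycles do not, so a
  fully merged circular strand is represented by its arcs one level down.
- Containment trimming re-checks neighbors iteratively until a fixed point,
  in ascending contig length, so removal order is deterministic.
- k-means uses `nstart = 50` restarts under a caller-supplied seed; the
  k = n edge case (every point its own cluster) is computed exactly rather
  than delegated.

## Problem sizes used in the checks

The packaged tests run the full pipeline on the default three-genome
community (24 000 read records after reverse complementing; about 2–3
minutes), a 5 kb single-genome exact-reconstruction check, and brute-force
oracle comparisons on reads ≤ 30 bp and graphs ≤ 30 nodes. These sizes were
chosen so the whole suite stays comfortably within an interactive
development loop while still exercising every stage end to end.

## Known limitations

- Overlap detection requires an exact shared k-mer (k = 16) per read pair;
  at error rates above a few percent, sensitivity falls with read length.
- Bubble resolution is bounded (interior degree-2 chains up to 5 nodes);
  larger tangles are left for level descent to resolve.
- The containment filter compares a node only against its current graph
  neighbors, as the hybrid structure suggests, so duplicated contigs
  without a connecting edge are both retained.
- Orientation is carried by keeping both strands as separate reads; the
  hybrid graph therefore represents each double-stranded region twice, and
  downstream counts treat the strands independently.
- With 20 kb genomes a radius-5 neighborhood is a sizable fraction of a
  genome; enrichment contrast relies on the ~1 kb node granularity
  discussed above.
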