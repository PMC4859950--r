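# ogmine — overlap-graph assembly and graph mining for metagenomic reads

Short-read assembly throws away structure: once reads are merged into flat
contigs, the overlap relationships that reveal *which* regions are repeated
within a genome or shared between species are gone. `ogmine` keeps them. It
assembles single-end reads into a **hybrid assembly graph** — nodes are
sequence regions represented at the coarsest granularity that still
assembles into a single contig, edges are summed read-overlap weights — and
then mines that graph for mobile genetic elements: transposase-carrying
regions shared across genomes and the antibiotic-resistance gene classes
enriched in their graph neighborhoods.

It is aimed at microbiome researchers who want more from an assembly than
contigs: where are the insertion sequences, which genera share them, and
what cargo travels with them.

## Method at a glance

- **Overlap graph.** Reads (plus their reverse complements) are pairwise
  aligned by a suffix-array k-mer seed search extended with banded
  Needleman–Wunsch; dovetail/containment overlaps ≥ 40 bp at ≥ 95 %
  identity become edges weighted by overlap length.
- **Multilevel coarsening.** Heavy-edge matching repeatedly contracts the
  graph into levels G₀, G₁, …, Gₙ. A merge of nodes *vᵢ*, *vⱼ* is accepted
  only if the resulting cluster's density

      density(vᵢ, vⱼ) = 2·(ew[vᵢ] + ew[vⱼ] + w(vᵢ,vⱼ))
                        / ((nw[vᵢ]+nw[vⱼ])·(nw[vᵢ]+nw[vⱼ]−1))

  (intra-cluster overlap weight per potential read pair) stays above a
  threshold, so unique-sequence clusters stop growing while repeat
  families, whose reads overlap across copies, keep collapsing.
- **Hybrid graph.** Walking from Gₙ back to G₀, each cluster whose cleaned
  read subgraph (tips clipped, bubbles resolved, transitive edges removed)
  is a single path becomes a *best representative*: its reads are assembled
  into a contig and its descendants are skipped. Contained contigs and
  transitive edges are trimmed away.
- **Shannon scoring.** Every node gets the entropy of its incident edge
  weights, H = −Σ (wᵢ/W)·ln(wᵢ/W). A unique region inside a path has two
  even edges and H ≈ ln 2 ≈ 0.69; repeats and cross-species regions
  accumulate edges and score higher. The high-diversity threshold is 1
  (just under ln 3 ≈ 1.1), so one spurious light edge cannot promote a
  path node.
- **Mining.** High-scoring transposase-tagged nodes are described by the
  genus composition of their neighbor contigs, clustered with k-means, and
  each cluster's 5-neighborhood is tested for gene-class enrichment with
  one-sided Fisher's exact tests under Benjamini–Hochberg FDR.

The package also ships a synthetic-community generator
(`simulate_community`, `sample_reads`, `truth_annotations`) that plants a
shared transposon-like element (inverted-repeat flanks), multi-copy
rRNA-like repeats, and linked resistance-gene segments, with full ground
truth — so the whole pipeline is testable without downloads.

## Worked example

Simulate the default community — three circular 20 kb genomes sharing one
1 kb transposon, two rRNA-like repeats per genome, a resistance-gene
segment 2 kb from each element copy, control genes far from the element,
20× error-free coverage — then run the pipeline and the miner:

```r
library(ogmine)

cc  <- community_config(seed = 42)
com <- simulate_community(cc)
sr  <- sample_reads(com)
res <- run_pipeline(sr$reads)
hg  <- res$hybrid
ann <- truth_annotations(com, sr$truth, hg)

sc <- hg$scores
hi <- select_high_nodes(sc, ann$tags, hg, tag = "transposase", threshold = 1)
vecs <- lapply(hi, tax_vector, hg = hg, contig_taxa = ann$taxa)
cl  <- cluster_transposase_nodes(vecs, k = 1, seed = 42)
enrichment_test(cl$assignment, hg, ann$genes, radius = 5)
```

Output (abridged):

```
processed reads: 24000
overlap edges: 495886
graph levels: 12
hybrid nodes (after trimming): 204
median Shannon score: 0.68
max Shannon on transposase-tagged nodes: 1.65

  cluster      class in_class in_other out_class out_other            p            q stars
1       1    control        0        7        63        17 1.000000e+00 1.000000e+00
2       1 resistance        7        0        17        63 5.923035e-05 1.184607e-04   ***
```

Reading it: the node count distribution peaks at H ≈ 0.68 — unique genomic
regions sit near ln 2, as a clean path predicts. The shared transposon is
recovered as a high-diversity node (H = 1.65 > 1: it touches flanks from
all three genomes), and within the 5-neighborhood of the transposase
cluster every resistance-gene hit and none of the background control hits
is found, giving a strongly significant enrichment (q ≈ 1.2 × 10⁻⁴) — the
planted association between the mobile element and its resistance cargo.

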