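Package: ogmine
Title: Overlap-Graph Assembly and Graph Mining for Metagenomic Read Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds an overlap graph from short sequencing reads, coarsens it
    by iterative heavy-edge matching into a multilevel graph set, integrates
    best-representative nodes into a hybrid assembly graph, scores nodes with
    Shannon's diversity index, and mines high-diversity nodes for mobile
    genetic elements and gene classes enriched in their graph neighborhoods.
    Includes a synthetic-community simulator with planted shared transposons,
    multi-copy rRNA-like repeats and linked resistance-gene segments for
    end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
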