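Package: structent
Title: Structural-Entropy Community Detection and Gene Maps for Cell
    Sample Networks
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects the natural K-level community structure of weighted
    networks by structural-entropy minimisation over partitioning trees,
    and turns gene-expression matrices into cell-sample networks via
    Pearson correlation, noise amplification and an entropy-guided choice
    of the top-k neighbour count.  Provides module and submodule
    detection (K = 2, 3) with greedy merge/combine operators, gene
    classification maps that assign each gene to the sample module it
    most strongly expresses, partition-similarity scoring against known
    labels, and synthetic generators for planted graphs and
    block-structured expression matrices.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
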