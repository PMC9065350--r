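Package: isokit
Title: Alternative Splicing Detection and Expression Utilities for
    Full-Length Transcript Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects candidate alternative-splicing events from paired
    high-scoring segment pairs (HSPs) in all-vs-all transcript alignments,
    removes transcript redundancy by greedy identity/coverage clustering in
    the style of CD-HIT, computes long-read QC statistics (N50, truncated
    mean length, read filtering), and provides expression utilities (FPKM
    conversion, replicate Pearson correlation, 2^-ddCt relative
    quantification) together with a seed-controlled synthetic isoform
    simulator that supplies ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
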