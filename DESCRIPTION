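Package: masc
Title: Mappability-Sensitive Cross-Correlation for Fragment Length Estimation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the mean DNA fragment length of single-end short-read
    sequencing experiments (e.g. ChIP-seq) by cross-correlating positive- and
    negative-strand read-start profiles. Implements both the naive strand
    cross-correlation and a mappability-sensitive variant (MaSC) that restricts
    the computation to doubly-mappable genome positions, which removes the
    "phantom peak" at the read length caused by unmappable regions forcing
    joint zeros into both strand profiles. Provides list-based and bit-vector
    computation backends, moving-average smoothing, per-chromosome and
    whole-genome estimation modes, BED/bedGraph input, a synthetic-data
    generator with ground-truth paired fragments, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
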