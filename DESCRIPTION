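Package: kmerdiff
Title: Reference-Free Genome Size and Composition Comparison from k-mer
    Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates genome sizes from uncropped k-mer spectra of shotgun
    sequencing reads and locates the copy-number classes and repeat families
    responsible for genome-size differences between individuals, without a
    genome assembly. Provides exact canonical k-mer counting with organelle
    k-mer subtraction, geometric copy-number binning of coverage-scaled
    spectra, pairwise difference graphs and joint k-mer spectra, repeat-family
    attribution through family-unique k-mers, cohort ANOVA with a
    label-permutation check, Manhattan/Gower sample distances, and a synthetic
    diploid read simulator with ground-truth tables for validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    methods,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
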