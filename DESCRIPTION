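Package: dripseq
Title: Restriction-Fragment DRIP-seq Analysis of Estrogen-Induced R-Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping R-loops from DRIP-seq (DNA-RNA
    immunoprecipitation sequencing) read counts over restriction
    fragments, and for relating estrogen-induced R-loop formation to
    transcription and breast-cancer mutation burden.  Provides in-silico
    restriction digestion of a genome into count intervals, GC-skew
    profiles, a negative-binomial Wald test for immunoprecipitate
    enrichment and hormone-induced differential signal with
    Benjamini-Hochberg correction, estrogen-responsiveness z-scores with
    GRO-seq cross-categorisation, covariate-matched control gene sets
    with a two-tailed bootstrap-of-medians enrichment test, and a
    synthetic-data generator with planted effects for validating every
    stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
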