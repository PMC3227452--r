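Package: senemeth
Title: Senescence-Associated DNA-Methylation Analysis for Cultured Mesenchymal Stromal Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for replicative-senescence studies of
    mesenchymal stromal cells profiled on promoter CpG methylation arrays.
    Implements quantile normalization and principal-component overviews of
    beta-value matrices, delta-beta filtering, a from-scratch Significance
    Analysis of Microarrays (moderated d statistic with fudge factor,
    permutation null, asymmetric cut-points and permutation-based false
    discovery rates), mapping of CpG sites onto histone-mark and EZH2 target
    sets with hypergeometric and Fisher enrichment tests, growth-kinetics
    formulas (population doublings per passage, cumulative doublings and
    CFU-f-adjusted doublings), single-hit Poisson maximum-likelihood
    estimation of colony-forming-unit frequencies from limiting-dilution
    assays, and a synthetic-data generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
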