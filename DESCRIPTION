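Package: psdmr
Title: Paired-Sample Differentially Methylated Region Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection of differentially methylated regions (DMRs) from paired
    tumor/normal methylation-array profiles by bump hunting on per-CpG paired
    t-statistics: adjacent CpGs are clustered, statistics are loess-smoothed
    within clusters, candidate regions are exceedance runs of the smoothed
    statistic, and region-level family-wise error rates are estimated from a
    sign-flip resampling null. Includes an unpaired (Welch) variant for
    comparison, a synthetic paired-methylome and cfDNA count generator with
    ground truth, promoter annotation and prioritization of significant DMRs,
    cross-dataset concordance summaries, and a targeted cell-free DNA stage
    with RPKM normalization and per-region negative-binomial differential
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
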