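Package: slimamp
Title: Design, Simulation and Variant Calling for Single-Tube Tiled
    Amplicon Panels with Stem-Loop Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Toolkit for stem-loop inhibition mediated amplification
    (SLIMamp) panels: tiling a region of interest with overlapping
    amplicons, constructing tagged primers whose overlap products fold
    into inhibitory terminal stems, simulating the branching multiplex
    PCR kinetics of overlapping amplicons, generating synthetic
    paired-end amplicon reads with injected variants, and calling
    variants from quality-weighted pileups with a per-segment noise
    model. Includes concordance, coverage-uniformity and sample
    throughput reporting with exact binomial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
LinkingTo: Rcpp
Suggests:
    IRanges,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
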