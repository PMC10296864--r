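Package: genefabric
Title: Genomic Fabric Analysis of Replicated Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes a transcriptome per condition by three independent
    per-gene measures - average expression (AVE), relative expression
    variability (REV, a chi-square mid-interval corrected pooled coefficient
    of variation), and all-pairs expression correlation (COR) - and derives
    pathway coordination scores, variability-calibrated fold-change cutoffs
    for significant-regulation calls, weighted individual regulation (WIR),
    and the transcriptomic distance (TD) of each gene from a reference
    condition. Includes pathway coordination networks with remodeling
    reports across conditions and a synthetic-data generator emulating a
    replicated, redundantly probed microarray design with known ground
    truth, so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
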