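Package: amplicnv
Title: Germline Copy-Number Variant Detection from Multiplex-PCR Amplicon
    Read Depths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and visualizes germline copy-number variants (CNVs) from
    the per-amplicon read-depth matrices produced by multiplex-PCR targeted
    sequencing panels (e.g. Ion AmpliSeq custom panels). Read depths are
    normalized per primer pool within each sample, referenced against the
    batch average per amplicon, and rescaled to a copy-dosage scale where
    diploid is 2. Low-coverage amplicons are masked, per-gene profiles are
    smoothed with a five-amplicon moving mean, candidate amplicons beyond one
    standard deviation are flagged, sliding-window Welch t-tests score runs of
    amplicons against the sample background, and contiguous non-diploid runs
    are called with integer copy states. A synthetic amplicon-coverage
    simulator with known CNV truth (primer-pool imbalance, amplification
    efficiency spread, count noise, X dosage by sex, trisomy) makes every
    stage testable without sequencing data.
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
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
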