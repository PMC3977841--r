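Package: subtelcnv
Title: Subtelomeric Copy Number Loss Calling and Case-Control Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Detects copy-number losses in subtelomeric regions from array
    data and tests their case-control association. Implements a four-stage
    bead-array caller (median normalization with GC correction, principal
    component batch removal, per-probe Gaussian-mixture cluster calling, and
    a consecutive-marker stretch rule), a tiling array-CGH segmenter
    (moving-average smoothing of log2 ratios classified against a reference
    panel's median +/- 1 SD envelope), combined multi-region loss
    classification, and exact association statistics (Fisher's exact test by
    hypergeometric enumeration, odds ratios with Woolf confidence intervals,
    chi-square comparisons). A seeded synthetic-cohort module simulates
    two-channel aCGH log2-ratio tracks and bead intensities carrying
    heterozygous deletions with GC bias, batch structure and coverage gaps,
    so the whole pipeline is testable without raw arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
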