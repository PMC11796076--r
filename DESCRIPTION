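Package: swaymarkers
Title: Digital Biomarkers of Postural Sway and Pronator Drift from
    Smartphone Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for turning raw tri-axial smartphone accelerometer
    recordings of quiet-stance (postural sway) and outstretched-arm
    (pronator drift) tests into a panel of digital biomarkers of
    neurological disability.  Covers gravity/tilt calibration of the raw
    traces into medio-lateral, antero-posterior and net (radial)
    acceleration series; four measurement families (root-mean-square
    acceleration, integrated squared jerk, spectral centroid and spectral
    spread); assembly of the 60-biomarker sway and 16-biomarker drift
    panels with condition ratios, hand relabeling and log10 transform;
    ICC(2,1) test-retest reliability screening with Benjamini-Hochberg
    adjustment; age-regression prediction bands and group comparisons;
    and regularized linear models (ridge, lasso, elastic net, with PCA
    variants) validated by Pearson r, R-squared and Lin's concordance
    correlation coefficient.  A synthetic-data module simulates raw
    traces and cohort tables with known ground truth so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
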