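Package: peakgrader
Title: Chromatographic Peak Quality Metrics and Likelihood-Calibrated
    Feature Curation for Untargeted LC-MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Ingalls Lab", "Tools", email = "tools@example.org",
           role = c("aut", "cre"))
Description: Computes per-feature chromatographic peak quality metrics from
    centroided mzML raw data and XCMS-style peak tables, including a
    beta-distribution peak-shape correlation, a within-peak signal-to-noise
    ratio estimated from fit residuals, missed-scan proportions, and 13C
    isotope shape/area verification. Summarizes per-peak metrics across
    files into a per-feature metric table, fits calibrated logistic
    regression models of peak quality against manual Good/Bad labels,
    evaluates false discovery rate and recall at likelihood thresholds,
    and runs model-stability diagnostics. Includes a synthetic
    multi-file chromatogram generator so the entire pipeline is testable
    without real data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
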