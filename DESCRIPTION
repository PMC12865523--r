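Package: placentile
Title: Gestational-Age-Conditional Reference Charts for Placental Perfusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds first-trimester reference centile charts for placental
    perfusion measurements (3D single-vessel fractional moving blood volume)
    against gestational age. Implements four-parameter skew response
    distributions (Box-Cox Cole-Green, Box-Cox power exponential, and skew
    exponential power types 1 and 3), penalized-likelihood LMS fitting with
    P-spline parameter curves and AIC-driven smoothness selection, exact and
    lasso-penalized quantile-regression comparators, centile and Z-score
    calculators with coverage calibration, segmentation quality control
    (Dice triage and per-day Tukey-fence outlier detection), centile-precision
    sample-size arithmetic, healthy-cohort outcome filters, and a synthetic
    cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
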