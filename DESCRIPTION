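Package: phenoTP
Title: Temperature-Precipitation and Classical Spring Leafing Phenology Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts spring leaf-unfolding dates from daily station weather
    using six process models: spring warming (SW), sequential (SM), parallel
    (PM), alternating (AM), growing season index (GSI), and a combined
    temperature-precipitation threshold model (TP) in which leafing requires
    both a degree-day sum and a weighted precipitation sum to reach critical
    values. Includes a least-RMSE simulated-annealing calibrator with an
    odd/even-year calibration-validation protocol, RMSE/R-squared/F model
    statistics, a synthetic continental-monsoon weather and leafing-date
    generator with known ground truth, and CSV/JSON/YAML input-output with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
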