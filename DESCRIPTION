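Package: cropnue
Title: Nutrient Use Efficiency Accounting, Trends and Mapping for Major Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for difference-method nitrogen and phosphorus use
    efficiency (NUE/PUE) accounting in cropping systems: per-record
    efficiency algebra and screening of paired field trials,
    reconstruction of country-by-crop-by-year fertilizer input
    intensities and annual efficiency series from production panels and
    baseline intensity reports, segmented (breakpoint) trend regression,
    random-forest models of soil-derived nutrient uptake with grid
    prediction and ordinary-kriging residual correction, driver analysis
    via rank correlation with false-discovery control and partial least
    squares path modelling, and assessment of efficiency quadrants and
    fertilizer surplus. Includes a synthetic-data generator with known
    ground truth so the full pipeline can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
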