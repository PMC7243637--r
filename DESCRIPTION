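Package: hctnomo
Title: Hematocrit Mass-Balance Modelling and Alignment-Chart Nomograms
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Closed-form mass-balance modelling of hematocrit under blood
    loss, crystalloid infusion, whole-blood and packed red-cell transfusion,
    and dehydration, assuming a weight-proportional blood volume (default
    75 ml/kg). Includes an event-sequence engine with per-event audit
    trails, inverse estimators for unmeasured blood loss and total-body-water
    deficit, a geometrically exact three-axis parallel-scale alignment chart
    (nomogram) for pediatric and adult ranges with a virtual straight-edge
    that replays the chart's graphical procedures, a deterministic SVG
    renderer, and a command-line interface with JSON output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
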