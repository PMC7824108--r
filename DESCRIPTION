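Package: lipidTMT
Title: Sixplex Tandem Mass Tag Workflows for Carboxy- and
    Phosphate-Containing Lipids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for targeted lipidomics with isobaric tandem mass tag
    (TMT) labeling of carboxy- and phosphate-monoester-containing lipids
    (fatty acids, eicosanoids, lysophosphatidic and phosphatidic acids).
    Provides molecular-formula arithmetic and lipid shorthand parsing,
    generation of sixplex selected-reaction-monitoring (SRM) transition
    lists including divalent doubly labeled species, a native
    (underivatized) SRM method builder, bridging-channel relative
    quantification across multiplexed sets, reproducibility statistics
    (coefficient of variation, dilution-series linearity), and a
    synthetic-data simulator with known ground truth for end-to-end
    validation of the pipeline without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
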