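Package: lungtnm
Title: Rule-Based TNM-8 T and N Staging of Free-Text Lung Cancer
    Radiology Reports
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts the T and N stage (8th edition TNM classification,
    lung cancer) from free-text chest CT and PET-CT radiology reports
    using a configurable rule-based pipeline: report sectionizing,
    sentence splitting, measurement extraction with an anatomical
    blacklist, ConText-style negation and uncertainty assertion,
    aggregation into tumor and lymph-node findings, and TNM-8 staging
    logic in which FDG avidity on PET-CT overrules CT size criteria for
    node pathology. Ships a synthetic labeled-report generator with
    tunable adversarial phenomena and an evaluation harness (accuracies,
    support-weighted precision/recall/F1, confusion matrices, categorized
    error reports) so the whole pipeline is testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stringi,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
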