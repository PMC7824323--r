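Package: ethnoindex
Title: Quantitative Ethnobotany Indices and Use-Report Survey Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative ethnobotany built around the use report
    (UR), the atomic citation unit of ethnobotanical surveys: one informant
    citing one taxon for one plant part prepared one way. Provides a
    validated survey data model with botanical-name normalization and
    controlled part/preparation vocabularies, the classical survey
    statistics (ethnobotanicity index, informant consensus factor, cultural
    importance index), a minimum-informant reliability filter, ranked and
    categorical summary tables with alluvial-diagram export, cross-reference
    of used taxa against external edibility or nutraceutical name lists, and
    a seeded synthetic survey generator with Zipf-like taxon popularity that
    emulates the wild food plant dataset of the Catalan linguistic area, so
    that every pipeline stage can be tested without access to restricted
    primary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
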