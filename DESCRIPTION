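Package: fluxscreen
Title: Expression-Binned Autophagic Flux Cytometry and Drug-Repurposing
    Screen Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for rescue-construct autophagy
    cytometry and phenotypic drug-repurposing screens. Implements DEFAC
    (differential expression-function analysis using cytometry): dead-cell
    exclusion, GFP expression-level gating, geometric mean fluorescence
    intensities, and the per-level LC3 flux statistic contrasting
    bafilomycin-A1-treated against untreated cells. Implements the
    dual-criterion triage of an FDA-approved drug library
    (vehicle normalization, cytotoxicity filtering, quadrant hit
    selection, category and named exclusions, funnel accounting), plus
    supporting kinetics and genetics statistics: cycloheximide-chase
    exponential decay and half-life estimation, Mendelian segregation
    chi-square tests, qPCR standard-curve relative quantification, and
    two- and multi-group comparisons. Seeded synthetic-data generators
    emulate flow-cytometry event tables, screening plates, decay courses,
    and mouse litters so every stage runs and is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
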