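Package: microspend
Title: Small-Area Expenditure Estimation by Spatial Microsimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatial microsimulation of household expenditure by iterative
    proportional fitting (IPF). Survey microdata with socio-demographic
    attributes and an expenditure diary are reweighted against zone-level
    marginal constraint tables (age-sex, ethnicity, student status,
    unemployment, household type and income brackets) to produce zone-level
    average weekly expenditure per person for hierarchical COICOP commodity
    categories. Includes constraint-table construction and scaling, a
    separate child model, relative regional consumer price adjustment,
    internal and external validation checks, and a seeded synthetic-world
    generator for end-to-end testing without licensed survey inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
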