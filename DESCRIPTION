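Package: attrpk
Title: Quality-Attribute Pharmacokinetics of Therapeutic Antibodies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitation and mechanistic pharmacokinetic modeling of
    therapeutic antibody quality attributes (post-translational
    modifications and glycoforms) from affinity-purification LC-MS
    peptide-mapping data. Converts light/heavy isotope peak-area tables
    into attribute relative levels and absolute drug concentrations,
    fits a two-compartment original/modified-form ODE model by maximum
    likelihood with attribute-specific constraints, and simulates
    patient exposure (windowed AUC) across initial attribute levels.
    Includes a synthetic-study generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
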