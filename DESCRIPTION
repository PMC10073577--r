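Package: kampopreg
Title: Claims-Based Safety Analysis of Rhubarb-Containing Kampo Laxatives in
    Pregnancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An active-comparator pharmacoepidemiology pipeline for
    administrative health-insurance claims: estimates pregnancy onset and
    delivery dates from gestational-age-annotated diagnoses, constructs a
    mother-infant cohort under month-granular enrollment criteria, classifies
    laxative prescriptions (magnesium oxide, senna glycosides, and Kampo
    formulations containing rhubarb rhizome) into trimester exposure windows
    built from days of supply, ascertains major congenital malformations in
    the infant's first year from ICD-10 diagnoses, and reports crude and
    covariate-adjusted odds ratios, Cochran-Armitage prescription trends, and
    sensitivity analyses. Includes a synthetic claims generator with known
    ground truth so every stage is testable without access to proprietary
    claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
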