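Package: plwhcost
Title: Budget-Impact Model of Comorbidity Costs in People Living with HIV
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic closed-cohort budget-impact model of the direct
    healthcare costs of cardiovascular, renal, bone, and neuropsychiatric
    comorbidities in people living with HIV, projected over annual cycles.
    Two since-diagnosis cohorts are projected under a single mortality rate
    and age-banded, annually decaying comorbidity incidence; prevalent
    person-years are costed from per-comorbidity resource-use profiles and
    unit costs with CPI inflation and annual discounting. Counterfactual
    antiretroviral-toxicity scenarios shift baseline prevalence by absolute
    percentage points, and one-way sensitivity analyses swap cohort
    prevalences. Includes a bisection calibration that recovers incidence
    schedules from endpoint counts, a seeded synthetic parameter generator
    for property testing, YAML configuration I/O, CSV/JSON report layouts,
    and a command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
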