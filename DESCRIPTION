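Package: glaucomaCUA
Title: Lifetime Cost-Utility Markov Model for Trabecular Micro-Bypass
    Stents in Open-Angle Glaucoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort cost-utility model comparing trabecular
    micro-bypass stent implantation with concurrent cataract surgery against
    cataract surgery alone in mild-to-moderate open-angle glaucoma, from a
    national health-service payer perspective. Implements monthly-cycle
    five-state disease progression driven by visual-field decline,
    proportional-hazards switching to trabeculectomy, QALY and cost accrual
    with discounting, one-way deterministic sensitivity analysis (tornado)
    and probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves. Ships a fully parameterised base case, a synthetic
    Gompertz-Makeham life table generator, and an individual-level
    microsimulation used to validate the cohort engine.
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
    rlang,
    stats,
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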