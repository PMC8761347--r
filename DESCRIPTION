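Package: pmslt
Title: Proportional Multistate Lifetables with Consistent Disaggregation by Population Strata
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time proportional multistate lifetable (PMSLT) modelling
    for population health intervention analysis, with exact disaggregation of an
    aggregate cohort into heterogeneity strata (for example socioeconomic
    deprivation quintiles). Given aggregate all-cause mortality, morbidity (YLD)
    and per-disease incidence, case-fatality and prevalence inputs, together
    with stratum rate ratios and initial stratum shares, the package solves the
    unique per-stratum rates per annual cycle such that business-as-usual
    simulations of the strata sum exactly to the aggregate lifetable's deaths,
    person-years, health-adjusted life years (HALYs) and disease compartment
    counts at every time step. Intervention scenarios (all-cause mortality
    scaling, disease incidence scaling, and potential impact fractions from
    relative-risk shifts in a risk-factor exposure distribution) can then be run
    on both the aggregate and stratified models, and health-inequality impact
    measures (rate ratios and differences between strata, percentage shifts to
    the null, HALY gaps) computed per cycle and cumulatively.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
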