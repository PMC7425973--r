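Package: phasecost
Title: Phase-of-Care Attribution of Disease-Associated Healthcare Expenditures from Claims Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates disease-associated healthcare expenditures per patient
    per month (PPPM) from longitudinal monthly claims panels, stratified by
    treatment type and phase of care (initial, continuing, terminal), using
    two statistical approaches: an exactly matched case-control comparison
    (sex, 5-year age band, 15 Charlson comorbidity conditions, anchor month,
    one control per case without replacement) and a within-patient
    fixed-effects panel estimator with time-dependent age and comorbidity
    score. Includes a seeded synthetic claims generator that emulates the
    structure of Japanese national claims data for hepatocellular carcinoma
    (monthly expenditures, diagnosis and treatment-modality flags, an
    end-of-life expenditure surge common to all decedents) with a ground-truth
    table of injected phase-specific incremental costs, price-revision
    deflation to a 2018 base, purchasing-power-parity conversion to US
    dollars, and the proportional and absolute between-method difference
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
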