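Package: hceval
Title: Human-Capital Economic Evaluation of Systems-of-Care Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Economic and societal evaluation of health-care interventions
    evaluated in pre/post cohort designs, using the human-capital approach.
    From sex-specific life tables, binned labour-force data and a patient
    cohort it computes survival probability matrices, age-specific
    labour-force participation, expected remaining working years, the
    discounted present value of foregone future labour income, life-years
    saved, number needed to treat, cost per life and per life-year saved,
    net economic gain, benefit-cost ratios, and a growth-by-discount-rate
    sensitivity grid. Includes seeded synthetic-data generators for cohorts,
    life tables and labour inputs, and an aggregates fixture reproducing the
    headline figures of a state-wide STEMI quality-improvement programme.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
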