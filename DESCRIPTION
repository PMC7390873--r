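Package: hfcea
Title: Markov Cohort Cost-Effectiveness Model of Sacubitril-Valsartan
    versus Enalapril for Heart Failure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic Markov cohort model comparing
    sacubitril-valsartan with enalapril for heart failure with reduced
    ejection fraction from the perspective of Chinese patients. Six health
    states (NYHA classes I-IV plus cardiovascular and non-cardiovascular
    death) evolve in monthly cycles with parametric baseline hazards,
    hazard-ratio treatment effects, age-dependent background mortality and
    a NYHA class-change matrix. Computes discounted costs, quality-adjusted
    life years and incremental cost-effectiveness ratios; supports one-way
    (tornado), two-way (price threshold) and probabilistic sensitivity
    analyses with cost-effectiveness acceptability curves; and includes a
    patient-level microsimulation that serves as a validation oracle and a
    generator of synthetic event-time data for hazard-parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
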