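Package: pdl1cea
Title: Cost-Effectiveness of PD-L1-Guided Pembrolizumab Combination Therapy
    in Nonsquamous NSCLC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort cost-effectiveness model comparing first-line
    chemotherapy, pembrolizumab plus chemotherapy, and PD-L1-test-guided
    treatment strategies for metastatic nonsquamous non-small-cell lung
    cancer, from the United States and China payer perspectives. Includes
    parametric survival extrapolation (Weibull and log-logistic) from
    digitized Kaplan-Meier curves via interval event-count reconstruction,
    a three-state (progression-free, progressed, dead) cohort engine with
    3-week cycles and annual discounting, treatment-cost schedules with
    body-size dosing and the Chinese pembrolizumab donation program,
    incremental cost-effectiveness and dominance-frontier analysis,
    one-way deterministic and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, price-reduction scenarios,
    and a synthetic two-arm trial generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
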