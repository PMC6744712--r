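Package: ehmdecon
Title: Cost-Consequence Decision Model for Exclusive Human Milk Diets in
    Very-Low-Birth-Weight Infants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic cohort decision-tree model comparing an exclusive
    human milk diet (EHMD) with usual practice of care (cow's-milk-based
    fortifier and preterm formula) for very-low-birth-weight infants in a
    neonatal intensive care setting. Computes expected clinical events
    (necrotising enterocolitis and its surgical share, late-onset sepsis,
    mortality, bronchopulmonary dysplasia, retinopathy of prematurity,
    cerebral palsy, short bowel syndrome) and attaches payer and societal
    costs to produce incremental cost-consequence results per 1000-infant
    cohort. Includes threshold (break-even) analysis, one-way parameter
    sweeps, named lower-cost/higher-cost/mortality scenarios, probabilistic
    sensitivity analysis with Beta/log-normal/Gamma parameter distributions,
    and an individual-level microsimulation used to validate the
    expected-value engine. Configuration is read from validated YAML/JSON
    files; results export to CSV, JSON and markdown reports.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
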