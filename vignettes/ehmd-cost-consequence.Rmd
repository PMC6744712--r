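---
title: "Modelling the costs and consequences of an exclusive human milk diet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the costs and consequences of an exclusive human milk diet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehmdecon)
```

## The decision problem

Very-low-birth-weight (VLBW, < 1250 g) infants fed with cow's-milk-based
fortifier and preterm formula face elevated risks of necrotising
enterocolitis (NEC), late-onset sepsis, death during the initial hospital
stay, and downstream sequelae: bronchopulmonary dysplasia (BPD),
retinopathy of prematurity (RoP), cerebral palsy (CP), and — after surgical
NEC — short bowel syndrome (SBS). An exclusive human milk diet (EHMD),
mother's milk plus fortifier and formula manufactured from donor human
milk, reduces these risks but costs far more to feed. `ehmdecon` implements
a cost-consequence model of this trade-off: a single-pass cohort decision
tree that lists expected clinical events and costs separately for each
feeding strategy and reports their incremental differences, rather than
collapsing everything into one cost-effectiveness ratio.

## Model structure and assumptions

A hypothetical cohort (default 1000 infants) passes once through the tree
under each diet:

* **NEC and late-onset sepsis** apply to the *full cohort*. Their joint
  occurrence is the product of the marginal probabilities (independence).
* **Death** during the initial stay applies to the full cohort,
  independently of the events; survivors are the complement.
* **BPD, RoP and CP** apply to *survivors only*, with the NEC/sepsis mix
  among survivors equal to the cohort mix (events independent of
  survival). This assignment is what lets fewer deaths *increase* BPD
  counts in the EHMD arm: more infants survive to be at risk.
* **Surgical NEC** under usual care is total NEC times a surgical share;
  in the EHMD arm it is the usual-care surgical probability times a
  dedicated relative effect `rr_nec_surgical`. No single surgical share can
  reproduce the published total, medical and surgical incremental counts
  simultaneously, so the surgical pathway carries its own effect,
  calibrated (default 0.1132) so the incremental surgical-NEC count matches
  the published clinical results; it is configuration-overridable. Under
  this calibration the implied incremental *medical* NEC count is −21 per
  1000, not the −66 printed alongside the other figures; the latter is
  arithmetically irreconcilable with the printed total (−115) and surgical
  (−94) rows, since medical NEC under usual care is only 61 cases.
* **SBS** follows surgical NEC at a fixed conditional probability
  (default 15.7%, derivable from cohort-level figures via
  `derive_sbs_rate()`). It carries no cost of its own — its treatment cost
  is already inside the surgical-NEC cost.
* **CP** depends only on NEC/sepsis history. The source meta-analysis
  reports an *odds ratio* (1.55) for CP after NEC and identical
  probabilities (14.8%) for sepsis-only and unaffected infants; with both
  events the higher (NEC) value applies. The odds ratio is applied as a
  multiplicative risk factor by default (0.148 × 1.55 = 0.2294) because
  only that reading reproduces the published incremental CP count (−2 per
  1000; the strict odds-scale conversion gives 0.2121 and an incremental of
  −0.6). The strict conversion remains available via
  `cp_or_method = "odds"`.
* **IQ loss** (11 points after NEC, 9 after sepsis alone, never additive)
  is tracked for survivors. It carries no payer cost; it prices into the
  societal view as lifetime earnings lost per IQ point.

All quantities are expectations — there is no rounding and no sampling in
the primary engine. Reported tables round event counts half-to-even
(`round()`), which is why 34.5 avoided NEC cases print as 34 while −115.23
prints as −115, and monetary values to whole dollars; full-precision values
always remain on the model objects and in the JSON exports.

## Costs

Costs (2016 USD, health-care payer perspective) are additive and
incremental to the baseline stay of an uncomplicated VLBW infant
($49,660), which every infant accrues in both arms. The EHMD diet cost is
built from median milk volumes and the fortifier mixing rule: one 30-mL
vial ($187.50) per 70 mL of milk, donor milk at $183/L, mother's milk
free. Vials are deliberately fractional — (1943 + 883)/70 × 187.50 +
0.883 × 183 ≈ $7,731 — because the published total is the continuous
computation, not a whole-vial ceiling. The usual-care diet is a flat $226.
Event costs attach per expected case (surgical NEC $229,431, medical NEC
$85,734, sepsis $12,413, BPD $38,966, RoP $5,939, lifetime CP to the payer
$147,268 — already a present value, never re-discounted). Non-survivors
accrue the diet, the baseline stay and their NEC/sepsis costs, but no
sequela costs.

The shipped defaults are already in 2016 dollars; `adjust_price_year()`
(medical-care CPI index ratio) and `discount()` (3%/year default) are
provided as explicit utilities and never applied silently.

The **societal view** is a flag on any run, not a separate model. It adds
the excess of societal over payer lifetime CP cost, earnings lost per IQ
point, and RoP productivity losses. These unit inputs are not part of the
published base case and therefore have *no defaults*: they must be supplied
in the configuration (the shipped fixture carries clearly-labelled
synthetic placeholders only so the machinery can be exercised). Lost
productivity among non-survivors is deliberately out of scope.

## Reproduced results and known gaps

With the default (base-case) parameters the model reproduces, per 1000
infants: −36 deaths, −115 NEC (−94 surgical), −39 late-onset sepsis, −63
RoP, −2 CP, −15 SBS, and a payer saving of about $16,500 per infant
(published: $16,309; the printed two-significant-figure relative risks
leave ~$170 of slack). The mortality scenario (cohort baseline 0.172 with
the trial effect 0.24) saves 172 × 0.76 ≈ 131 lives per 1000.

Two published figures are *not* reproducible from the printed inputs, and
the package reports its own computation rather than absorbing the
discrepancy:

* The sequelae cost row (published incremental +$18) reconstructs to about
  −$105; the BPD row (+18) reconstructs to +15.5. Both would require
  unrounded source values that were not printed.
* The NEC threshold. The published sweep points imply an affine slope of
  about $156,600 per unit of baseline NEC incidence, but the model that
  reproduces the published surgical-NEC row has slope $146,800; no
  admissible variant reproduces both. Consequently the break-even baseline
  NEC incidence computed here is 5.5% (the published statement is 7%), and
  the cost per NEC case prevented at 5% incidence is about $20 rather than
  $59. The qualitative conclusions — cost-saving down to mid-single-digit
  NEC incidence, cost-saving even at zero sepsis incidence — are unchanged.

## Sensitivity machinery

* `sweep_param()` recomputes incremental outcomes over a grid for one
  parameter, everything else fixed (including relative risks and the
  surgical share).
* `threshold_incidence()` locates the break-even parameter value by
  bracketing bisection (absolute tolerance 1e-6 on the parameter). Because
  the incremental cost is affine in each baseline incidence, the
  closed-form linear solution is computed alongside after a three-point
  affinity check, and the two must agree; `stats::uniroot` provides a
  further independent cross-check in the test suite. When no sign change
  exists over the interval the nearer boundary is returned flagged
  `"always-saving"` or `"never-saving"` (late-onset sepsis is
  always-saving: the EHMD remains cheaper even at zero sepsis incidence).
* `run_scenario()` evaluates the named presets: `lower_cost` (the data
  source per parameter most favourable to the EHMD), `higher_cost` (least
  favourable — including the trial mortality effect, which saves more
  lives and therefore incurs more survivor costs), and `mortality_rct`.

## Synthetic parameters and validation

The deterministic engine is validated two ways, both first-class code:

* **Microsimulation** (`microsimulate()`, or
  `simulate(model, method = "microsimulation")`): per-infant Bernoulli
  sampling following exactly the structural assumptions above, with
  independent RNG streams per arm. Every expected count must lie within
  three Monte-Carlo standard errors of the simulated count; the test suite
  checks this at n = 200,000 per arm, and checks the Monte-Carlo
  convergence rate across n = 10³–10⁵.
* **Random parameter sets** (`param_distributions()` / `draw_params()`):
  Beta for probabilities (mean = base value, concentration κ; shapes mκ,
  (1−m)κ), mean-preserving log-normal for relative risks and the CP odds
  ratio, Gamma for costs and volumes (mean and CV). The source analysis is
  deterministic and prints no uncertainty intervals, so the default spreads
  (κ = 100, log-sd 0.1, CV 0.2) are conventional parameter-uncertainty
  choices, not literature calibrations — probabilistic sensitivity analysis
  here is an extension, and its distributions should be recalibrated before
  substantive use. Draws violating joint validity (a relative risk pushing
  a probability past 1, surgical exceeding total NEC) are clamped rather
  than rejected, so a request for n sets returns exactly n, and the clamp
  count is reported so a misspecified distribution surfaces.

What the synthetic machinery does *not* emulate: correlation between
parameters (none is stated in the source data), correlation between feed
volumes and outcomes, time-varying (Markov) structure, and long-term SBS
consequences. Passing tests therefore demonstrate internal consistency of
the engine under independence, not external validity of the inputs.

## Numerical choices

* Expectations are exact closed-form products; the only iterative numerics
  is the bisection, tolerance 1e-6 on the parameter.
* Ties in reported counts round half-to-even; full precision is never
  discarded internally.
* Degenerate inputs are legitimate: zero baselines, certain death
  (survivor-conditioned counts vanish while cohort-level counts persist),
  zero discount rate, degenerate PSA distributions (κ = ∞, CV = 0)
  returning the base values exactly.
* Problem sizes in the test suite (200,000 microsimulated infants per arm,
  1000 random parameter sets) keep every check comfortably inside a few
  seconds while leaving Monte-Carlo noise far below the tolerances tested.

## Worked example

```{r example}
m <- ehmd_model()
summary(m)

threshold_incidence(m, "p_nec_usual")$value
run_scenario("mortality_rct")$incremental_costs$total
```

Reports (CSV + full-precision JSON + markdown, with a configuration hash
for provenance) are produced by `report_bundle()` and `write_report()`;
configurations are read and validated by `load_params()`, with the
complete base-case configuration shipped at
`system.file("extdata", "base_case.yaml", package = "ehmdecon")`.
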