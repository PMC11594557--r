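---
title: "Interventional mediation analysis on discrete person-period data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interventional mediation analysis on discrete person-period data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmediate)
```

## The problem

How much of the excess mortality associated with a chronic, relapsing
exposure — major depressive disorder (MDD) in the default configuration —
runs through physical diseases that the exposure makes more likely? The
question is longitudinal and causally delicate: the exposure varies over
time, the candidate mediators (HIV, tuberculosis, diabetes and chronic
kidney disease, cardiovascular disease, chronic respiratory disease,
cancer) accumulate over time, and other conditions (hypertension, anxiety
disorders) are time-dependent confounders — affected by earlier exposure,
and affecting later mediators and death. Standard regression adjustment
fails here; the g-formula does not.

`gmediate` implements the full estimation pipeline on discrete
person-period data:

1. **Panel construction** (`build_panel()`): follow-up is cut into
   half-open intervals of 182 days (a deterministic "6 months"), up to 16
   periods (8 years). A condition indicator turns 1 in the period
   containing its first diagnosis and stays 1 forever (all conditions are
   treated as chronic); death is terminal; leaving the cohort for any
   other reason marks the row censored.
2. **Per-interval models** (`fit_models()`): one logistic regression per
   period for death (covariates: all condition indicators at t, including
   the exposure, plus baseline sex, age group and population group) and
   one per not-yet-diagnosed condition (covariates: all indicators at
   t − 1 plus baseline; at t = 1, baseline only). Model selection is
   forward–backward stepwise by AIC over main effects and two-way
   interactions, or the full main-effects model, or intercept-only.
3. **G-computation** (`simulate_scenario()`, `run_scenarios()`): Monte
   Carlo forward simulation of counterfactual worlds on the cohort's own
   baseline population, censoring switched off, death absorbing. Several
   runs are averaged (four by default).
4. **Effects** (`gmediate()`, `overall_effect()`,
   `indirect_effect_pct()`): risks, risk differences and ratios at yearly
   horizons (year y is period 2y), and indirect effects as percentages of
   the overall effect.
5. **Inference** (`gmediate_boot()`): nonparametric cluster bootstrap
   resampling whole persons, refitting everything per replicate,
   percentile 2.5/97.5 intervals.

## Scenarios and estimands

All estimands are contrasts of cumulative mortality between simulated
worlds:

* **A, "always exposed"** — exposure set to 1 for everyone at every
  period; mediators and confounders drawn from their fitted conditional
  distributions given that history.
* **B, "never exposed"** — exposure 0 throughout. The *overall effect* is
  `risk_A − risk_B` (reported in percentage points) and `risk_A / risk_B`.
* **C, joint mediator shift** — everyone exposed, but from period 2
  onward each mediator model receives exposure input 0: mediators are
  drawn, conditional on surviving the previous period *within this
  scenario*, from the distributions that would prevail without exposure.
  Confounder models keep exposure input 1. Because the period-t + 1
  models condition on the time-t state, the shift propagates into
  confounders and other mediators downstream — nothing else needs to be
  done to realize that flow-through. The *overall indirect effect* is
  `100 · (risk_A − risk_C) / (risk_A − risk_B)`.
* **D, single-mediator shift** — as C for one mediator's model only,
  giving that mediator's indirect-effect percentage.

Shifts act from period 2 because, under the lag assumption, period-1
onset models have no exposure input (the sensitivity option
`contemporaneous = TRUE` adds exposure-at-t to every other condition's
onset model, and overrides then apply to that input too).

Interventional indirect effects need not sum: the package reports each
single-mediator percentage and the joint one, and does not assert any
additive decomposition.

## The synthetic truth and its oracles

The study that motivated this machinery used private insurance claims
that cannot be shipped. The package therefore carries its own ground
truth: `scm_params()` describes a complete structural causal model (the
same lag structure the estimator assumes), `generate_cohort()` simulates
cohorts from it, and two oracles validate the estimation pipeline
against it:

* `oracle_enumerate_risk()` — exact scenario risks by dynamic programming
  over all condition-state histories and discrete baseline strata.
  Feasible only for small registries (at most 4 non-exposure conditions,
  4 periods): the `tiny` preset (one mediator, one confounder, 3 periods)
  exists for this.
* `oracle_simulate_risk()` — forward simulation of the true model at
  large n, for presets too big to enumerate.

Four presets fix the study conditions. `paperlike` is coarsely calibrated
to the published margins of a large South African insured cohort: 51.7%
female, 44.4% aged 40+, population-group shares as published, about 15%
ever-diagnosed with the exposure, end-of-follow-up disease prevalences
from 2% (tuberculosis) to 30% (hypertension), a median follow-up near
3 years under a 10%-per-period noninformative censoring hazard, and
8-year counterfactual risks near 7% (always exposed) and 5.7% (never
exposed), risk ratio about 1.24 with roughly 37% of the overall effect
mediated — the same order as the published analysis. `null_exposure`
zeroes every exposure coefficient (sharp null); `null_mediation` zeroes
exposure effects on mediators and confounders but keeps a direct effect
on death; `tiny` is the enumerable workhorse.

What the generator deliberately does *not* emulate: claims-level noise
(miscoded or repeated diagnoses), informative censoring (a switch exists,
off by default, only to demonstrate the bias), seasonal or calendar-time
effects, and continuous age effects — the structural models depend on age
only through the 40-year cutoff, which keeps the baseline strata discrete
and the enumeration oracle exact. Passing tests therefore demonstrate
that the estimator recovers a truth *of the assumed form*; they cannot
certify the lag structure itself in real data.

Within a period, the generator draws all condition states given the
previous period's state (mutually independent given that history, so
registry order is distributionally irrelevant), then censoring, then — for
the uncensored — death given the full current state. Resolving censoring
before death encodes the reading that a person who leaves the cohort
mid-period exits before the period's death outcome is realized; censored
rows then carry no survival information, and dropping them from risk
sets (as the fitting step does) is unbiased under the default
noninformative hazard.

## Numerical and design choices

* **Dates.** 182-day intervals with half-open boundaries; events on a
  boundary belong to the later period. Export uses interval midpoints, so
  `export_event_records()` followed by `build_panel()` is the identity on
  valid panels. A person who dies and exits in the same period is a
  death.
* **Encoding.** Categoricals are one-hot encoded against fixed reference
  levels (male, under 40, Black African), recorded in the model-set
  metadata.
* **Stepwise.** Starts from intercept-only; the best strictly
  AIC-improving single move wins, ties broken by lexicographic term name,
  so selection is deterministic. Interaction hierarchy is enforced (an
  interaction needs both main effects; a main cannot leave while one of
  its interactions stays). Zero-variance candidates are dropped up front;
  coefficients beyond ±15 are treated as separation, the offending terms
  dropped and flagged. Step cap 50; IRLS tolerance 1e-8.
* **Sparse cells.** A per-period model needs `min_events` (default 25)
  events and non-events; below that it falls back to a model pooled over
  the periods sharing its candidate set (death: all periods; onsets:
  periods 2+), with `period` as a covariate, then to the empirical event
  rate. A sparse period-1 onset cell goes straight to the empirical rate,
  because the initial-state model has different structure from the
  transitions and pooling across them would be incoherent.
* **Randomness.** Every stochastic operation takes one integer seed;
  named substreams are derived by hashing (generation, each Monte Carlo
  run, each bootstrap replicate), so components are independently
  reproducible and results are invariant to panel row order. Draws are
  vectorized per (period, response) with full-length uniform vectors, so
  a trajectory never depends on the order in which individuals are
  stored; regenerating with a different n does reshuffle draws — per-person
  streams were traded away for vectorized speed.
* **Common random numbers.** `crn = TRUE` shares the uniform arrays
  across scenarios within a run, cancelling simulation noise in
  contrasts. It is off by default (independent draws match the plain
  description of the algorithm) and on in the package's validation
  studies, where scenario contrasts are the quantity of interest.
* **Indirect-effect floor.** `indirect_effect_pct()` returns a flagged
  `NA` when `|risk_A − risk_B|` is below 1e-6: at early horizons the
  denominator has not yet separated and the ratio is meaningless.
* **Bootstrap.** Percentile intervals (the simplest defensible reading of
  "nonparametric bootstrap"), default 200 replicates, resampling whole
  persons; selection is rerun inside every replicate. Failed replicates
  are excluded and counted; more than 20% failures aborts. Replicate
  refits are warm-started from the point estimate (pure acceleration: the
  likelihood optimum is unchanged); the labeled `fast = TRUE` mode
  additionally relaxes the optimizer tolerance to 1e-6 — with full
  selection the term lists are identical by construction, so only the
  iteration path differs.

## Validation studies and their sizes

The test suite ships reduced-scale validation studies, sized so the whole
collection runs routinely on modest hardware:

* *Oracle equivalence*: simulation from the true `tiny` models at
  n = 500,000 against exact enumeration, all four scenario types, within
  3 binomial standard errors everywhere.
* *Recovery*: 8 replicate `paperlike` cohorts of 20,000, full-selection
  fits; cumulative risks pooled across replicates recover the truth
  within 1 percentage point, and the joint indirect-effect share within
  5 points. Pooling before the ratio matters: with an 8-year overall
  effect of ~1.4 points and a per-cohort standard error near 1 point, the
  within-cohort ratio is ill-conditioned at this n — the published
  analysis needed ~1M people for a ±6-point interval on the same share.
* *Sharp null*: ten `null_exposure` cohorts of 10,000 center the 8-year
  risk ratio on 1 within 0.03.
* *Null mediation*: ten `null_mediation` cohorts (n = 1,800, 8 periods,
  `min_events = 12` so the ~20-death cohorts pool their death models),
  100 bootstrap replicates each in the labeled fast mode; every
  indirect-effect interval covers zero in at least 9 of 10.
* *Coverage*: 100 `tiny` cohorts of 2,000, 100 fast-mode bootstrap
  replicates each; the 95% percentile interval for the final-horizon risk
  difference covers the enumerated truth at the nominal rate within Monte
  Carlo slack.

## A worked example

```{r example, eval = FALSE}
params <- default_scm_params("paperlike")
panel <- generate_cohort(params, n = 20000, seed = 1)
fit <- gmediate(panel, selection = "full", crn = TRUE, seed = 1)
summary(fit)
plot(fit)

boot <- gmediate_boot(panel, selection = "full", n_boot = 200, seed = 1)
confint(boot)
```

Stratified analyses (`strata = c("sex", "age_group")`) rerun the entire
pipeline — model fitting included — within each stratum. The same run is
available from the shell through the wrapper in `inst/cli/gmediate.R`
(`generate`, `build-panel`, `run`, `oracle` subcommands over a YAML or
JSON configuration).

## Known limitations

* Identification rests on the assumed lag structure (exposure affects
  other conditions only at the next period unless the contemporaneous
  option is on), noninformative censoring, positivity and consistency;
  none of these are testable within the package.
* The chronicity convention makes remission invisible by construction.
* At small n the indirect-effect share inherits the instability of a
  ratio of small risk differences; the floor and the replicate-pooled
  validation design are mitigations, not cures.
* Stepwise selection with many interactions is expensive inside the
  bootstrap; `selection = "full"` is the pragmatic default for simulation
  studies, stepwise the faithful one for data analysis.
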