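---
title: "Methods: a tooth-level Markov model for root-caries management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a tooth-level Markov model for root-caries management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootcea)
```

## The decision problem

Adults at high risk of root caries — here, a 45-year-old safety-net dental
patient with 21 residual teeth — can be managed with semiannual topical
fluoride. Two strategies are compared: 38% silver diamine fluoride (SDF),
which both prevents new lesions and arrests active ones, and 5% sodium
fluoride (NaF) varnish, which is preventive only. The package evaluates which
strategy buys more *extraction-free tooth-years* per dollar over a 19-year
horizon (ages 45–64), from a healthcare-system perspective with selected
access-related non-medical costs (care assistance and transportation)
included.

## Model structure

The model is a tooth-level Markov cohort model. Each tooth occupies one of
five states: caries-free (`NO_CARIES`), active root caries (`ROOT_CARIES`),
caries arrest (`ARREST`), persistent root caries (`PERSISTENT`), and
`EXTRACTED`, the unique absorbing state. Extraction is not restricted to
root-caries aetiology — it reflects all-cause extraction as observed in
safety-net practice, which is why caries-free teeth also carry an extraction
risk.

Each model year consists of two 6-month transitions:

1. **Natural history**: caries-free teeth develop an active lesion with
   probability `p_incidence_nat`; nothing else moves.
2. **Treatment visit**: the assigned strategy is applied. Caries-free teeth
   stay caries-free, develop a lesion (`p_incidence_tx`, the strategy's
   preventive failure rate), or are extracted. Carious teeth are arrested
   (`p_arrest`), extracted (`p_extract_caries`), or persist. Under NaF the
   arrest branch is structurally closed (`p_arrest[NAF] = 0`, enforced by
   validation).

At the start of the next cycle the transient states are relabelled: `ARREST`
folds into `NO_CARIES` and `PERSISTENT` into `ROOT_CARIES`. Occupancy is
recorded at the initial boundary and after every half-cycle (before
relabelling), so a 19-year run has 39 boundaries. All probabilities are
stored per 6-month step; nothing is annualised. The state order
(`NO_CARIES`, `ROOT_CARIES`, `ARREST`, `PERSISTENT`, `EXTRACTED`) is fixed
for every vector and matrix representation.

Two further structural choices the sources leave open were resolved as
follows: extraction happens only at the treatment visit (the natural-history
step only toggles caries on), and there is no spontaneous remission — the
only route back to `NO_CARIES` is treatment-induced arrest plus relabelling.

```{r cohort}
params <- default_parameters()
head(run_cohort(params, "SDF"), 4)
```

A per-tooth stochastic microsimulation (`simulate_microsim()`) implements the
same transition rules by simulating individual teeth; since the cohort
occupancies are the exact expectations of its empirical fractions, it serves
as an independent oracle. At 100 000 teeth the two agree within binomial
sampling error (max absolute deviation below 0.005) in the test suite.

## Economics

**Effect.** Each half-cycle contributes half a year times the
utility-weighted occupancy of the non-extracted states, discounted at the
end-boundary time `t = k/2` years (no half-cycle correction; the accrual
sampling matches the default of standard cohort-modelling software). With
unit weights this is the plain extraction-free tooth-year; the default
fixture uses a fitted weight below 1 for the active/persistent caries states
(see *Calibration*), matching the "utility-weighted tooth-year" reading of
the published acceptability curve.

**Cost.** Visits are semiannual, so by default (`cost_schedule =
"semiannual"`) both half-cycle boundaries of each year are visit boundaries;
`"annual"` restricts accrual to the treatment boundary. At each visit a tooth
still in the mouth incurs the application cost of its strategy (SDF \$39, NaF
\$33 at base), and the visit-level costs — oral examination \$36, radiography
\$45, care assistance/transportation \$129 — are allocated by a switch:

* `per_tooth` (default): the visit fee is divided over the 21 teeth and the
  share is charged for every surviving tooth;
* `per_visit_shared`: the full fee is charged once per visit while the
  subject has at least one tooth.

The tooth-level published costs and effects are on different scales: effects
are per-tooth means (a 19-year horizon bounds the discounted effect at 14.4
tooth-years), while costs are cohort totals. The package therefore exposes
separate `effect_aggregation` (default `per_tooth_mean`) and
`cost_aggregation` (default `cohort_sum`) switches rather than one shared
switch.

**Comparison.** `compare()` produces incremental cost and effect, the ICER
(when both increments are positive; dominance flags otherwise, and no
division when the effect difference is zero), per-strategy net monetary
benefit `NMB = WTP × effect − cost` at the reference willingness-to-pay of
US\$50 000 per tooth-year, and the incremental NMB. All derived quantities
use unrounded internal values; only printing rounds.

```{r basecase}
res <- base_case(params)
tidy(res)
```

## Parameters and their file formats

A `ce_parameters` object carries the transition block, the cost table with
one-way ranges (all base values lie at the midpoints of their published
ranges: SDF 31–39–47, NaF 27–33–39, exam 27–36–45, x-ray 37–45–53,
access 93–129–165, 2025 US\$), per-state utility weights, economic settings
(3% annual discount on costs and effects, 19-year horizon, 21 teeth, WTP
50 000), and the PSA distribution table. Two interchangeable on-disk forms
are supported — a structured-key YAML document and a flat CSV mirroring a
supplementary-table layout — both validated on load and lossless on
round-trip. Validation rejects out-of-range probabilities, branch masses
exceeding 1, a non-zero NaF arrest probability, cost bases outside their
ranges, and PSA means that drift from their base values.

## Calibration of the default fixture

The transition probabilities and utilities behind the published base case
were estimated from clinical records and published only in supplementary
material that is not part of the article body. The packaged default fixture
is therefore a **synthetic, calibrated stand-in**:
`calibrate_base_case()` searches the transition-probability space (plus the
shared caries-state utility weight and the visit-cost allocation switch) by
multi-start Nelder-Mead on a logit-transformed box, minimising the summed
squared relative error against the four published base-case observables (NaF
\$8863 / 1.39 tooth-years; SDF \$16 660 / 7.73 tooth-years). To reduce the
dimension of an under-determined fit, the post-NaF incidence is tied to the
natural-history incidence, and a soft penalty keeps the SDF arrest +
extraction mass at or below 0.9 so that beta-distributed PSA draws rarely
leave the simplex.

The shipped fit reproduces all four observables within 0.3% (ICER 1239 vs
1229) under `per_tooth` allocation; with four constraints and eight free
parameters it is one feasible parameterisation, not a unique estimate, and
`inst/extdata/synthetic_calibration_report.json` records its residuals. Three
calibration findings shaped the defaults:

* with costs accrued only annually, the published SDF cost is unreachable
  (the undiscounted-maximum cohort stream is too small), so semiannual
  accrual is the default;
* with unit utilities, the published NaF effect of 1.39 tooth-years is
  incompatible with the published NaF cost under any allocation mode — the
  surviving NaF teeth must be mostly carious and down-weighted; the fitted
  caries-state weight is ≈ 0.19;
* charging the full visit fee to every tooth overshoots the published costs
  by roughly a factor of five, which is why that reading is not offered.

The published one-way sensitivity table is reproduced in *direction*
(ICER rises with SDF cost and each visit-level cost, falls with NaF cost)
but not in magnitude: that table's own base-value rows quote five slightly
different base ICERs (1228–1240), and the cost slopes it implies (equal for
examination and access costs but three times smaller for radiography, both
per-visit charges) cannot be produced by any single allocation rule that
also fits the base case. The package recomputes both strategies for every
one-way point and reports what the model implies.

## Probabilistic sensitivity analysis

Beta distributions are assigned to transition probabilities and gamma
distributions to costs. `fit_beta()`/`fit_gamma()` match the requested mean
exactly (the mean pins one parameter) and refine the remaining degree of
freedom one-dimensionally from a method-of-moments warm start (implied
variance `((high − low)/3.92)^2`) so the central 95% interval is matched as
closely as the family allows; self-consistent specifications round-trip
within 1e-3. Fixture probability specs use a beta effective sample size of
150 with the interval taken from the distribution itself; cost specs take
their spread from the one-way ranges.

Draws are independent across parameters (no correlation structure is
published). A single root seed spawns one deterministic substream per
parameter name, so adding or removing a parameter never perturbs the others'
draws; utilities are held at base. Joint draws that violate a structural
constraint are rejected and redrawn on a per-round substream (truncation to
the feasible region; ≈0.2% of fixture draws). 1000 Monte Carlo draws are
evaluated under both strategies; the cost-effectiveness acceptability curve
reports, at each willingness-to-pay on a 0–5000 grid (step 50), the fraction
of draws in which each strategy has the strictly highest NMB, with exact
ties split equally so the curve is a pointwise partition.
`ceac_crossover()` interpolates the smallest WTP at which SDF's
acceptability reaches 0.5; under the fixture's mean-preserving uncertainty
it lands within a few percent of the deterministic ICER.

## What the synthetic generator does and does not emulate

`generate_parameter_set()` draws transition probabilities uniformly from
documented scenario boxes (default / pessimistic / optimistic), fixes costs
at the published bases, prevalence at 0.68, and attaches self-consistent PSA
specs. It emulates the *structure* of the study's parameter table — not the
correlations, visit-level heterogeneity, or record-derived uncertainty of
real clinical data. Tests passing on generated sets therefore demonstrate
structural and economic correctness of the machinery, not clinical validity
of any particular probability; exact replication of the source analysis
requires transcribing the original supplementary values into a config.

## Numerical choices and problem sizes

Occupancy vectors must sum to 1 within 1e-12 after every operation;
extraction mass is non-decreasing by construction. Degenerate inputs are
handled explicitly: zero incidence leaves occupancy unchanged, all-zero
branch probabilities route carious teeth to persistence, a zero effect
difference yields a flagged, division-free comparison. The test suite uses
100 000 microsimulated teeth for the oracle comparison, 200–1000 PSA draws,
and a 3-start × 400-iteration calibration for parameter recovery (relative
error below 0.1%); the full suite runs in under two minutes on one core.

## Limitations

Teeth are independent and identically parameterised; restorative pathways
(e.g. root canal treatment) are not modelled; one-way analysis covers cost
parameters (probabilities can be varied through `set_parameter()` but have
no published ranges); and the default fixture's probabilities are calibrated
stand-ins whose individual values should not be quoted as clinical
estimates.
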