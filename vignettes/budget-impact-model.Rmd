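---
title: "A closed-cohort budget-impact model of comorbidity costs in people living with HIV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-cohort budget-impact model of comorbidity costs in people living with HIV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plwhcost)
library(dplyr)
```

## The problem

Antiretroviral therapy has brought the life expectancy of people living
with HIV (PLWH) close to that of the general population, but an ageing,
long-treated population accumulates non-HIV comorbidities — cardiovascular,
renal, bone, and neuropsychiatric disease — at rates influenced by both
chronic immune activation and the toxicity profiles of specific regimens
(tenofovir disoproxil and renal/bone effects, boosted protease inhibitors
and cardiovascular risk, integrase inhibitors and neuropsychiatric
symptoms). For a national payer, the question is not whether these
conditions cost money but how fast the bill grows over a planning horizon,
and how much faster it would grow if regimen toxicity raised the prevalent
burden at model entry. `plwhcost` answers that question with a
deterministic, closed-cohort budget-impact model with one-year cycles,
parameterised for Spain 2024–2034 in the packaged base case but fully
configurable through YAML.

## Model structure and assumptions

Two cohorts are fixed at baseline: people diagnosed less than 10 years ago
(mean age 34) and at least 10 years ago (mean age 48). The cohorts are
closed — no incident HIV inflow, no migration between cohorts — so each
alive count decays geometrically under a single annual mortality
probability applied identically to people with and without comorbidities,
and the cohort mean age advances one year per cycle. These are deliberate
simplifications: the model projects the *stock* of diagnosed PLWH as of the
base year, not the epidemic.

Each comorbidity is an absorbing state (no remission) projected
independently per cohort — a person may be counted in several comorbidity
pools, so pools must not be summed across comorbidities as if they were
disjoint people. Annual incidence is age-banded on the cohort *mean* age
with an inclusive threshold at 50 years (a cohort entering at 48 switches
band in its third cycle), and decays by 1% per year as a conservative
reflection of improving treatment toxicity. Two update rules are
implemented because the semantics of the source incidence schedules are not
published:

* **at-risk** (default): incidence applies to the comorbidity-free pool,
  `P' = [P + i (N − P)] (1 − m)`;
* **whole-cohort**: incidence applies to all alive,
  `P' = [P + i N] (1 − m)`, capped at the surviving cohort so prevalence
  never exceeds 1.

The at-risk rule is the default because the scenario-versus-current gaps in
the published endpoint tables shrink faster than survival alone would
explain, which is the signature of at-risk-pool dynamics. Counts are
measured at cycle start, mortality applies at cycle end, and no half-cycle
correction is used; person-years (PY) are the plain sum of prevalent counts
over the 11 cycles.

Fractional persons are carried through every computation and rounded
half-up only in presentation layouts: published tables round outputs, and
rounding intermediates would compound that artifact.

## Costing

Per-patient annual cost is the dot product of six resource-use quantities
(hospital admissions, diagnostic tests, emergency visits, non-HIV and HIV
outpatient visits, blood tests) with unit costs, each inflated from its
origin year to the base year by a CPI index ratio. In the packaged base
case the unit costs are already expressed in 2024 euros, so the CPI path is
an identity there; it exists for reused configurations with older cost
sources. Costs accrue for every prevalent person-year and are discounted at
3% per year with whole-year exponents, base year at factor exactly 1 —
standard Spanish health-economic practice. Drug-acquisition, indirect, and
societal costs are out of scope, as are utilities.

```{r costing}
cfg <- spain_fixture()
per_patient_cost(cfg)
```

## Calibration of unpublished incidence

Baseline prevalences are published 2024 prevalent counts divided by
published cohort sizes, but the incidence schedules behind the 2034 counts
are not published. `calibrate_incidence()` recovers them by bisection on
`[0, 1]`: the endpoint count is strictly increasing in the base incidence
(given a baseline below the cohort size), so bisection is globally
convergent; the bracket is halved until narrower than `1e-10` (far below
person-level resolution, ~34 iterations) with a 200-iteration guard that
reports the bracket state on failure. Residuals are below 0.5 persons for
every (comorbidity, cohort) pair by construction, and the procedure is
deterministic, hence idempotent.

Two published endpoints cannot identify two free band rates, so one scalar
per (comorbidity, cohort) is calibrated and the old band is tied to the
young band by a configurable ratio, default 1. For the recent cohort the
choice is immaterial (it never reaches age 50 in-horizon); for the
longstanding cohort the published cost curves show a small inflection when
the cohort crosses 50, which qualitatively suggests a ratio above 1, but no
published number pins it down — the default keeps the calibrated rate
interpretable as a single annual probability, and `spain_fixture(old_young_ratio = 2)`
recalibrates under any other assumption while still matching the endpoints.

```{r calibration}
attr(cfg, "calibration")
```

## Scenarios and sensitivity analyses

Counterfactual regimen scenarios add absolute percentage-point deltas to
the 2024 baseline prevalence — the prevalent stock at model entry — and
leave incidence, mortality, and costs untouched, isolating the burden
attributable to prior regimen exposure. Each scenario is a full-exposure
counterfactual, run one regimen at a time and never market-share weighted.
Percentage increases are reported on two bases, labelled separately:
undiscounted person-years and discounted cost. The two coincide exactly
only at a zero discount rate, and published increment figures mix the two
bases inconsistently for one comorbidity, so neither basis is asserted as
canonical — both are exposed for inspection.

```{r scenario}
run_scenario_comparison(cfg, "cardiovascular_darunavir") |>
  filter(comorbidity == "cardiovascular")
```

Literature-sourced neuropsychiatric deltas are published only for the
recent cohort, but the published scenario endpoint counts imply the same
delta was applied to both cohorts; the fixture follows that arithmetic.

One-way sensitivity analyses swap the baseline prevalence of selected
cohorts for values from an alternative source (`run_sensitivity_swap()`);
comorbidities the replacement source does not cover are flagged
`evaluated = FALSE` rather than silently kept, mirroring cohort studies
that omit some conditions. The replacement values themselves are user input —
the alternative-source prevalences behind the published sensitivity runs
are not published, so the test suite exercises the mechanism with synthetic
values only.

## Synthetic bundles and what the tests show

`generate_synthetic_params(seed)` draws a complete schema-valid
configuration from documented ranges (cohort sizes 10³–10⁵, prevalence
0–0.3, incidence 0–0.05, mortality 0–0.05, decay 0–0.02, resource
quantities 0–10 events/patient-year, unit costs €20–6000, discount 0–0.05,
deltas 0–5 pp) and records the generating truth for recovery tests. The
property suite checks, across seeds and both update rules: conservation of
persons, boundedness (`0 ≤ P ≤ N`), monotonicity in incidence,
zero-discount equivalences, agreement of the vectorized engine with an
independently written per-cycle scalar loop, and recovery of generating
incidence to `|error| < 1e-5`.

These synthetic draws emulate the *structure* of the data — closed cohorts,
age-banded absorbing-state incidence, linear costing — not its empirical
correlations: quantities are drawn independently, whereas real resource use
co-varies with severity and age, and real prevalences are not uniform on
their ranges. Passing tests therefore demonstrate that the arithmetic
engine is correct and self-consistent, not that the base-case parameters
are right; the base case stands on its published inputs.

## Numerical choices and reproduced figures

The base case is small (2 cohorts × 4 comorbidities × 11 cycles) and every
routine is exact arithmetic plus a short bisection, so the full fixture
build with calibration runs in well under a second; the property sweeps in
the test suite use 100 synthetic bundles for engine-oracle equivalence and
50 for incidence recovery. Reproduced against the published analysis:
survivors after ten mortality cycles (113 081 total, 44 780 recent) and
alive person-years (1 384 058) to within 0.1%; all eight 2034 endpoint
counts to within 0.5 persons by construction; the darunavir 2024 baseline
shift (3 271) to within 0.5%; and the four 2024 cost figures (€83.19M,
€47.53M, €54.77M, €96.92M) to within 1%. The residual ~0.1–0.35% cost gaps
trace to the published inputs being rounded (prevalent counts to whole
persons, cohort sizes to whole persons), not to model structure; published
*full-horizon* scenario cost totals additionally depend on the unpublished
incidence semantics and are inspected, not asserted.

## Known limitations

* No incident-HIV inflow, cohort re-assignment, or differential mortality
  by comorbidity status; the projection is a stock model of the 2024
  diagnosed population.
* Multimorbidity is not modelled: pools overlap and cost totals assume
  additivity across conditions.
* The old:young incidence structure of the longstanding cohort is
  underdetermined by the available endpoints (see Calibration).
* Scenario deltas are expert-elicited point values applied as full-exposure
  counterfactuals; no probabilistic sensitivity analysis is offered, by
  design.
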