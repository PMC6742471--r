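---
title: "Modelling the cost effectiveness of certified assistance dogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost effectiveness of certified assistance dogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dogcea)
```

## The decision problem

Individuals with severe functional impairments or intractable diabetes use
large amounts of health care, municipal services and informal care, and many
lose working time. A certified assistance dog — a physical service dog
trained to help with daily tasks, or a diabetes alert dog trained to signal
blood-sugar excursions — may reduce that resource use and improve
health-related quality of life relative to keeping an ordinary companion
dog. `dogcea` implements a decision-analytic model that weighs the extra
cost of certifying a dog against those downstream savings and
quality-of-life gains, expressed as an incremental cost-effectiveness
ratio (ICER):

$$\mathrm{ICER} = \frac{C_{\text{certified}} - C_{\text{companion}}}
                       {E_{\text{certified}} - E_{\text{companion}}},$$

with costs $C$ in USD and effects $E$ in quality-adjusted life years
(QALYs). When the certified arm is cheaper *and* more effective it is
reported as *Dominant* and no ratio is formed.

## Model structure

The model is a year-1 decision tree feeding a nine-year Markov cohort, for
a 10-year horizon in one-year cycles.

**Year 1 (cycle 0).** Owners on the certified track take a minor and a
major suitability test and, after the training year begins, a final exam.
The certified fraction is the product of the three pass probabilities;
everyone else continues with an uncertified dog. During this year the whole
cohort accrues the baseline (companion-dog) cost and utility profile, plus
the certified-track year-1 dog costs (purchase, upkeep, suitability tests).

**Years 2–10 (cycles 1–9).** Five states: *certified dog*, *dog retired*,
*dog not certified*, *dog dead*, *owner dead*. Certified owners face, in
order, the owner's annual death risk, the dog's annual death risk, forced
retirement once the dog reaches the retirement age (default 10, entering
the model at age 2), and an annual risk of failing the certification
maintenance test. The risks are applied as sequential conditional risks, so
each transition row sums to one by construction. Owner-dead and dog-dead
are absorbing; a dead dog's owner reverts to the baseline cost and utility
profile, and owner death accrues nothing.

Internally the *dog not certified* state is split into owners who never
certified (baseline profile) and owners whose dog lost certification
(who take the retired/decertified profile, as the published parameter
tables assign one column to both situations). The reported five-state
trace merges the two, so occupancy always satisfies the five-state
contract.

Costs and QALYs accrue per cycle as occupancy-weighted state values times
the discount factor $(1+r)^{-k}$, $r = 3\%$ by default, cycle 0
undiscounted. No half-cycle correction is applied: the model reproduces a
plain annual-cycle spreadsheet design.

### Timing conventions

Two conventions were genuinely open and are settable:

* `benefit_start_cycle` (default 1): the certified cost/utility profile
  applies from cycle 1, i.e. the decision-tree year accrues baseline
  values for everyone. The year-2 dog-cost band carries the training and
  cape costs, matching the published schedule. Setting it to 0 models
  immediate certification (used by the fully-trained-dog scenario).
* Mortality timing: the transition into cycle $k$ uses the ages attained
  in cycle $k$; deaths during a cycle accrue nothing that cycle, and the
  decision-tree year itself carries no death risk — annual risks begin
  with the nine Markov years.

## Parameters

The packaged bundle (`default_bundle()`) carries the published annual
costs per state and category (health care, municipal services, informal
care, productivity loss; USD per owner-year), the dog-cost schedule
(year-1 / year-2 / subsequent bands per track), per-state QALY weights,
and the gamma/beta parameters attached to each of them.

* **Retired/decertified state.** Where a retired column is absent,
  `derive_retired_profile()` takes the category-wise arithmetic mean of
  the companion and certified values, truncated to whole USD (the
  convention that reproduces the published retired-state cells); utility
  weights are averaged without truncation. The packaged fixtures store
  the published retired cells verbatim — including the physical-service
  retired weight 0.309, which is *not* the arithmetic midpoint of 0.226
  and 0.351 — so derivation is a fallback, not a reinterpretation.
* **Test-pass and decertification probabilities.** Not published. The
  defaults — 0.9 for each of the three tests, 0.02 annual
  decertification — are package assumptions, surfaced as warnings by
  every file-writing entry point and overridable in `transitions.cfg`.
  Because of them the model's absolute QALY totals are *not* expected to
  reproduce the published headline totals; the incremental cost comes
  close (about −6,200 vs the published −5,959 USD for physical service
  dogs) but the incremental QALYs are sensitive to the certified
  fraction.
* **Mortality.** The owner life table and dog survival schedule shipped
  in the bundle are synthetic, produced by `make_owner_lifetable()`
  (Gompertz, anchored at q(44) = 0.002 doubling every 10 years — a
  plausible general-population magnitude for a middle-aged cohort) and
  `make_dog_lifetable()` (increasing hazard scaled so that cumulative
  mortality from age 2 through age 11 is 20%, the midpoint of the 30%
  and 10% anchors used by the life-span scenarios). Real tables drop in
  through the same CSV dialect.
* **Perspectives.** `societal` (all categories) is the base case;
  `societal_no_productivity` zeroes productivity losses;
  `healthcare` keeps health-care plus dog costs — the intervention cost
  must remain in any payer perspective — with the retained set
  configurable.

## Probabilistic sensitivity analysis

`run_psa()` (or `simulate()` on a fit) redraws every cost from its gamma
distribution and every utility weight from its beta distribution,
independently across parameters, and reruns both arms per draw; transition
probabilities and mortality stay fixed, as only costs and utilities carry
published distributions. Draws are parameter-major from one seeded stream,
so a seed fully determines the run.

The published (alfa, beta) pairs do not have means equal to the published
base-case values (e.g. a gamma(27, 704) mean is 19,008, not 8,928), so by
default sampling is *moment matched*: gamma draws keep the published shape
(hence coefficient of variation) with the scale reset so the mean equals
the base case; beta draws keep the precision alfa+beta with the mean moved
to the base case. This keeps the PSA centred on the deterministic result —
the standard convention — while `psa_anchor: printed_params` reproduces
the raw pairs for anyone wanting the literal published spread.

Acceptability curves report, for each willingness-to-pay threshold
$\lambda$ on a configurable grid (default 0–150,000 USD/QALY in 2,500
steps), the fraction of draws with positive net monetary benefit
$\lambda\,\Delta E - \Delta C$; an exact tie counts as not cost-effective,
which is immaterial for continuous draws.

## Deterministic scenarios

`builtin_scenarios()` encodes the eleven one-way analyses: discounting at
0% and 5%; short and long dog life span (cumulative mortality by age 11 of
30% and 10%, obtained by rescaling the baseline dog hazard with a
multiplier solved by bisection to 1e-10); retirement at 8 and at 12;
exponential cost increase with utility decrease in retirement; inclusion
of unrelated care; purchase of a fully trained dog for 17,569 USD; and the
two alternative perspectives. Three of them need values the source never
printed, chosen once here and configurable:

* Scenario 7 uses cost growth 1.05 and utility decay 0.95 per cycle,
  counted from the (deterministic) retirement cycle and applied to the
  retired state only.
* Scenario 8's unrelated-cost add-on table ships as zeros with a
  documented per-state slot, since no magnitudes were printed; with the
  zero table the scenario equals the base case by design.
* Scenario 9 is modelled as immediate certification: purchase cost
  replaced, suitability/training/cape components removed, pass
  probabilities 1 and benefits from cycle 0.

Because these rates are assumptions, the published scenario ICERs are not
reproduction targets; the scenario *structure* is what the package
guarantees.

## Synthetic pseudo-study data

`simulate_pseudo_study()` emulates the pre-post design behind the
parameter tables: each subject contributes a baseline observation drawn
from the companion-state distributions and a follow-up observation from
the certified-state distributions, as quarterly costs (one quarter of an
annual draw) and an EQ-5D-scale utility clipped to the tariff range
[−0.594, 1]. `estimate_parameters()` annualises (×4), takes per-arm means
and refits gamma/beta distributions by the method of moments, so
generate-then-estimate recovery tests close the loop on the distribution
machinery.

The generator reproduces the *distributional* structure only. It does not
emulate self-selection, recall error in three-month interviews,
within-subject correlation between baseline and follow-up, or
between-category cost correlation — all present in real study data — so
passing recovery tests certify the package's statistics, not the
robustness of the original study design.

## Numerical choices

* Sequential-risk factorisation guarantees row sums of exactly 1; trace
  conservation is asserted to 1e-12.
* Cost midpoints truncate toward zero to whole USD; utilities are never
  truncated.
* Dog-cost band totals use the published totals, validated against
  component sums within ±1 USD (the published sums carry ±1 rounding).
* Dog life-table calibration brackets then bisects the hazard multiplier
  (200 iterations, interval width 1e-10), with hazards capped at 1.
* The engine is verified to 1e-9 against an independent path-enumeration
  oracle at short horizons.
* Test problem sizes: conservation on 1,000 randomised parameter sets,
  oracle comparisons at 3-cycle horizons, PSA reproducibility at a few
  hundred draws, parameter recovery at 5,000 pseudo-subjects; the
  acceptance script runs the full 10,000-draw PSA per dog type.

## Known limitations

* Absolute QALY and cost totals depend on unpublished pass probabilities
  and on the original (non-redistributable) life tables; only the
  published-table arithmetic is treated as exactly reproducible.
* Dog death and owner death are absorbing: owners do not acquire a
  replacement dog, and (a structural simplification) no further owner
  mortality is applied after the dog dies within the horizon.
* Decertification risk is time-homogeneous; there is no microsimulation
  mode, no correlated sampling, and no value-of-information analysis.

## A worked run

```{r example}
fit <- dog_cea(dog_type = "physical_service")
summary(fit)
psa <- simulate(fit, nsim = 500, seed = 1)
psa
head(run_dsa(fit$params)[, c("scenario_id", "incremental_cost", "icer")], 3)
```
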