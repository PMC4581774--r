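---
title: "Comparing conservation easements and land purchase under dispute risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing conservation easements and land purchase under dispute risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(easementsim)
```

## The problem

Land trusts protecting biodiversity on private land choose between two
instruments: buying parcels outright (fee-simple purchase) or acquiring
conservation easements — permanent legal agreements that restrict land use
while the owner keeps title. Easements are far cheaper up front, but they
carry long-term liabilities that purchase does not: annual monitoring and
staff costs, and the risk that a landowner breaches the agreement and the
trust must enforce it in court. `easementsim` simulates both strategies
over a 100-year horizon on a synthetic coastal-Pacific landscape and asks
when disputes erode the easement strategy's cost advantage.

## The model

### Reserve networks

Each parcel carries an area (acres), an assessed value (CAD) and a
dimensionless *beta-diversity score* — its contribution to landscape-level
habitat heterogeneity (old-forest and savannah community value in the
system that motivates the defaults). A reserve network is a parcel subset
whose summed beta score reaches a protection target, by default 20% of the
landscape total. The production selector is a greedy minimum-set heuristic
(descending `beta_score / cost`, ties to the smaller id); an optional
simulated-annealing solver (`select_network_annealed()`) minimises
`cost + penalty x target shortfall` with geometric cooling, seeded
restarts and a drop/swap polish. Both stand in for the systematic
reserve-design software (Marxan) used in the original study, which ran on
private cadastral data; the downstream cost/dispute simulation — the part
this package is really about — only needs an ensemble of target-meeting
networks of realistic size. Ensemble variability is emulated by perturbing
parcel costs with independent `Uniform(1 ± 0.05)` multipliers before each
greedy selection (`generate_solution_set()`), standing in for solver
run-to-run variability, which the source material does not parameterise.

### Costs

Purchase: assessed value plus a 15% stewardship endowment, all at year 0.

Easement setup (year 0, per parcel): five fixed components totalling
$14,800 (landowner legal $300, financial advice $300, registration $200,
endowment $10,000, holder legal $4,000) plus three size-scaled components,
each `max(minimum, intercept + slope x ln(acres))` with slope $1,957 per
log-acre: ecological baseline (intercept 2,185, min 1,000), appraisal
(intercept 0, min 1,500) and land survey (intercept 300, min 1,000).
At 1 acre the setup cost is exactly $19,485. Recurring costs are $909.6
per easement-year (monitoring 758 + staff 151.6), independent of area.
All values are present-day CAD with no discounting: a discount rate equal
to inflation followed by reporting in future dollars is hypersensitive to
the chosen rate, so the model stays in real terms throughout. Costs are
carried as exact reals; rounding happens only in reports.

The one ambiguity in the cost schedule is the logarithm: the source
table's caption specifies `ln(...)` while its cells print `log(...)`. The
caption governs; the package uses the natural log.

### Disputes

Each year, each easement independently suffers a dispute with probability
`dispute_rate` (Bernoulli per easement — the published rates count
easements affected per year, not events, so at most one dispute per
easement per year). Default rates are 0, 0.028%, 0.28% and 2.8%/yr.

Dispute cost follows the fitted rank-cost power function
`cost = 4845.78 x disputes^-0.701`, bounded between $1,000 and $400,000.
The fit describes cost as a function of dispute rank, not a sampling
distribution; we draw the dispute index uniformly over the interval that
maps onto the bounds, which is exactly a bounded Pareto on
`[1e3, 4e5]` with shape `1/0.701 ≈ 1.43` — the "inverse" profile in which
small costs are frequent and large ones rare. An optional heavy-tail
mixture (off by default, matching the headline analysis) replaces 1% of
draws with `Normal(4e5, 1e6)` truncated below at its mean, representing
catastrophic lawsuits.

A dispute is *pre-emptive enforcement* (PE) with probability 0.5 — the
trust sues before damage occurs, paying a sampled cost but losing no
habitat — or *damage enforcement* (DE): damage is done, compensation is
recovered (no net monetary cost) but biodiversity is lost. The 0.5 split
reflects "randomly assigned" with no stated weights. DE loss fractions
reuse the cost distribution rescaled linearly from `[$1e3, $4e5]` to
`[0, 1]`, plus `Normal(0, 0.05)` jitter truncated to `[0, 1]`. Losses are
multiplicative on the easement's *remaining* score, so repeated disputes
compound and scores decay toward zero without an arbitrary cap. Easements
are never extinguished and keep paying recurring costs after losses.
Enforcement is assumed to succeed (the survey underlying the cost profile
reports trusts winning all but one case), so there is no
litigation-outcome submodel.

### Cost-effectiveness

For each solution, `ce(t) = (B_e(t)/C_e(t)) / (B_p/C_p)` where `B` is the
fraction of the initially protected beta score still protected (so
`B_p = 1`) and `C` the cumulative cost. With zero disputes the biodiversity
terms cancel and the ratio is just `C_p / C_e(t)`. Loss percentages are
always reported relative to the initially protected scores — the 20%
target is "100%" — never the whole landscape.

## The synthetic landscape

The study region's cadastral, assessment and bird-survey data are private,
so `generate_portfolio()` emulates its printed statistics:

* **Count.** 20,000 parcels by default, a 1:10 scale-down of the region's
  193,623 candidate properties (keeps the full default experiment at
  seconds rather than minutes without changing network-level structure).
* **Price per acre.** Lognormal with parameters solved in closed form
  (`price_lognormal_params()`) so the mean is $2.1M/acre and exactly 8% of
  parcels fall below $100k/acre — the two statistics published for the
  region. Calibration is asserted at n = 10,000 (±3 pp on the 8%, ±25% on
  the mean).
* **Area.** Lognormal, median 5 acres, log-SD 1.5, truncated (by inverse
  CDF) to the printed protected-area size range of 0.01–5,830 acres.
* **Beta score.** Lognormal (`meanlog = log 0.2`, `sdlog = 0.8` — a
  right-skewed score in the sub-1 range typical of community-association
  indices), coupled to price per acre through a Gaussian copula with
  Spearman correlation −0.3. The sign reflects the region's affordable
  high-value rural properties; the magnitude is a modelling choice, made
  once and configurable, because no number is published.

What the generator does **not** emulate: spatial geometry, adjacency and
boundary effects, the species-distribution modelling behind real beta
scores, and the empirical joint distribution of value and habitat inside
selected networks. A green test therefore establishes that the cost and
dispute machinery is correct and that scenario *structure* (orderings,
scalings) is reproduced — not that network-level dollar totals match the
original study, which depended on private data.

## Numerical choices and degenerate inputs

* Year-0 convention: easement setup (and the whole purchase price) is
  charged at year 0; recurring costs and disputes start in year 1. The
  source does not state the convention; year 0 is chosen and documented.
* Target attainment uses a `1e-9` absolute slack to absorb floating-point
  summation error; target fractions are validated into `(0, 1]`.
* `jitter >= 1`, probabilities outside `[0, 1]`, non-positive areas and
  inverted dispute-cost bounds raise typed configuration/input errors.
* Greedy ties break on the smaller parcel id, making selection fully
  deterministic; all stochastic code flows through a single seeded stream
  with sub-seeds derived by `sample.int`, so experiments are
  bit-reproducible for a fixed config seed.
* Config files are JSON (no YAML dependency in the supported stack);
  unknown keys are rejected with their field path rather than silently
  ignored.

## Known limitations

The literal linear rescale of dispute cost to loss fraction yields mean
per-event losses of ~2%, which produces network-level 100-year losses of
~3% at the 2.8%/yr dispute rate — an order of magnitude below the ~32%
reported in the original study, whose archived script evidently used a
more aggressive mapping that its text under-specifies. The mapping is a
deliberate seam (`cost_to_loss_fraction()` / `sample_loss_fraction()`),
and the package's tests assert the *structure* of the loss results
(strictly increasing in rate, near-linear at small `rate x horizon`,
matching the analytic linearization within Monte-Carlo error) rather than
those magnitudes. Also out of scope, matching the original analysis: land
value change under easements (no consensus on sign), protected-area
downgrading (none reported regionally), discounting, and easement resale
or extinguishment.

## A worked run

```{r, eval = FALSE}
cfg <- scenario_config(n_solutions = 20, seed = 42)
res <- run_experiment(config = cfg)
summarize_table2(res)
```

With 20 solutions and the default landscape this takes about two seconds
and shows the qualitative fingerprint of the published comparison:
easements cost ~50% of purchase after 100 years at low dispute rates, and
both cost and biodiversity loss rise strictly with dispute rate.
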