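---
title: "Models and design choices in pigspread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in pigspread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pigspread` forecasts the spread of invasive wild pigs under a
no-intervention counterfactual with two independent frameworks, then values
the resources exposed to the *additional* forecast occupancy. This vignette
is the package's account of the science: the models and their assumptions,
the parameters that matter, what the synthetic world does and does not
emulate, and the choices made where the design was genuinely open.

## 1. Responses and strata

Occupancy is an annual per-county proportion `p` in [0, 1]; the area scale
is `p * A_c` (km²). Annual spread rates are first differences indexed at the
later year, so a history reconstructs exactly from its cumulated deltas
(telescoping, tested). The pre-program response for the county models is the
per-county arithmetic mean of the five pre-program annual deltas, on either
scale. Averaging before fitting is deliberate: single-year deltas carry
reporting noise (polygon mapping varies by state and year), and the mean
rate is the quantity the forecasts must extrapolate.

Counties are stratified over the pre-program window: *persistent* (occupied
every year), *transient* (occupied in at least one but not all years),
*never*. Spread dynamics plausibly differ between long-established and
marginal populations, so the two occupied strata are fit separately.
The occupancy threshold `tau` defaults to 0 — any strictly positive mapped
proportion counts as presence. This choice drives the "newly occupied"
bookkeeping, and because a deterministic forecast adds a typically positive
mean rate to every county, most threshold crossings happen in the first
forecast year. That is a property of the method, not a bug; `tau` is exposed
everywhere for sensitivity analysis.

## 2. Least-squares boosting

The spread-rate response follows no standard parametric family (a spike at
zero with a short negative and long positive tail), and covariate effects
are expected to be non-linear, so the county models use stage-wise
least-squares boosting of regression trees. The base learner is built in
the package (exhaustive exact split search, midpoint thresholds, depth and
leaf-size limits) rather than wrapped from another library, because the
environment provides no tree package and the fitting loop is central enough
to deserve first-class tests: with learning rate nu in (0, 1] each stage
cannot increase training SSE (the added tree is a projection of the
residuals onto leaf indicators), which the suite verifies, along with exact
recovery of a one-split step function.

Hyperparameters (`boost_control`): 500 rounds, shrinkage 0.05, depth 3,
minimum leaf 5. No published values exist for this application; these are
conventional small-data gradient-boosting settings, and tests at reduced
rounds confirm results are not qualitatively sensitive to them.

Model specs A–D cross two response scales (proportion / km²) with
inclusion/exclusion of the previous-year occupancy covariate. The source
description labels that covariate both as "status in the previous year" and
by the pre-window baseline year; the implementation uses previous-year
status, which is the only reading consistent with step-ahead updating.

## 3. Step-ahead forecasting

Each forecast year: predict the per-county change with the stratum's model,
add it, clip to [0, 1] (or [0, A_c]), record threshold crossings, and
recompute the adjacent-mean-occupancy covariate from the updated map. Three
open points were resolved as follows:

* **Never-occupied counties** belong to neither fitted stratum. They are
  forecast with the transient model — a new invasion is closer to a
  transient county's history than to a persistent one's. Configurable by
  swapping the stratum assignment in the models object.
* **Covariate evolution.** Only occupancy-derived covariates (and removals,
  if the optional removal model is enabled) update during forecasting; all
  others hold at last observed values. How land cover or suitability would
  have evolved over eight years is unknowable within the data, and freezing
  them makes the counterfactual attributable to the spread process alone.
* **Noise injection** (sampling predicted changes from a normal with the
  stratum's empirical response SD) exists behind an opt-in flag with a seed;
  the headline forecasts are deterministic, and the flag exists to
  demonstrate the documented effect (more spread overall), not to produce
  reported numbers.

The optional removal model predicts removals/km² from current occupancy,
previous removal covariates, and habitat/land cover, pooled across strata
(no evidence the relationship differs by history). When enabled, its
predictions refresh focal and adjacent removal covariates each year,
holding management intensity at pre-program levels as the front advances.

## 4. Dynamic occupancy simulation

The invasion model is a binomial-logit regression of the occupancy rate
within coarse watersheds (k invaded of n fine units) on six predictors.
Estimation is **penalized maximum likelihood** by default: a ridge penalty
(Gaussian prior, SD 2.5 on standardized coefficients, 10 on the intercept)
fit by IRLS. Sparse occupancy tables separate easily — many
watershed-years are all-zero with extreme distance values — and the
penalized fit is the posterior-mode analogue of the Bayesian estimation the
framework descends from. Plain ML is available (`penalty_sd = NULL`) and
errors informatively on separation. Regional variants (`ri`, `rs`) add
uncorrelated random intercepts or correlated intercepts and
previous-rate slopes over the four regions via `lme4`. The fourth
parameterization is not identified in the source text; it is implemented as
`fixed_reduced` — the fixed-effects model without the two climate
predictors — chosen because it brackets the covariate-set uncertainty the
way models B/D do for the county framework.

Annual invasion and extinction rates are beta-distributed, fit by moments to
the observed 2004–2012 series; exact zeros/ones are shrunk by
`(r(n−1)+0.5)/n` to keep the moments inside the valid region. The observed
invasion rate's denominator is the previously uninvaded (at-risk) units, the
reading consistent with applying drawn counts to "all uninvaded watersheds";
a total-units denominator is a config switch on both the rate computation
and the simulator.

Each simulated year converts the drawn rate to a count by
`round(rate × at-risk units)` (capped at availability, with capping counted
in the output), assigns invasions by probability-weighted sampling without
replacement (a unit invaded in year t is not re-drawn that year), and
removes extinctions uniformly among invaded units — no weighting is stated
for extinction, and uniformity is the minimal assumption. Invasion
probabilities are predicted at the coarse level and shared by member fine
units by default (`level = "fine"` gives each unit its own distance
covariate). Distances are centroid Euclidean on the synthetic plane.
Replicates (default 1000, horizon 8) run on independent child seeds fanned
out from the master seed, so full runs reproduce bit-identically and
per-replicate conservation (`invaded(t+1) = invaded(t) + invasions −
extinctions`) is assertable.

## 5. Valuation

Safeguarded occupancy is `max(0, forecast − observed)` per county-year.
This single formula nests both stated rules — counting additional
forecast-occupied years, and excluding counties observed occupied at full
extent — and extends them to partially occupied counties, where the source
gives no formula. Raw-forecast accounting is available by passing an
all-zero observed table. Amounts are proportion × county total (census-year
ledger held constant; missing county-resource rows are zero, since census
sparsity is normal, not an error). Crops are valued at national price ×
state yield; pasture at state cash rent with the national fallback;
wetlands and livestock carry amounts but no dollars (no defensible
annualized values exist). Dollars are undiscounted constant census-year
values. The conversion constant is fixed at 1 acre = 0.0040468564 km²,
which reproduces every published paired acre/km² figure at one decimal.
Valuation is linear in prices, yields, and proportions, and the per-model
totals are verified against brute-force triple loops.

## 6. The synthetic world

The generator emulates the *statistical structure* the methods consume, not
US geography: grid counties with queen adjacency (the methods use only
adjacency, areas, centroids, and overlap weights), log-normal county areas,
a persistent core and transient fringe placed by distance from a random
invasion origin, and a two-level watershed hierarchy with overlap weights
from a centroid-distance softmax (the real overlap computation is GIS, out
of scope). Defaults follow the documented national proportions: persistent
and transient fractions 0.12 and 0.30 (376 and 926 of ~3100 counties), mean
establishment proportion 0.17, a five-year label window offset one year
into the history so deltas exist for every labelled year, and a rate-series
window reaching back further than the county fit window, as in the source
data.

Annual occupancy increments follow a zero-spike (0.5) + gamma mixture
(positive tail scale 0.06, negative 0.02, P(positive) = 0.85). No
distributional form is published for the real rates beyond shape and range;
this family matches the described shape (high density at zero, short
negative tail, long positive tail) and is flagged as a stand-in. Two
secondary mechanisms keep the world coherent: occupancy tapers (× 0.35,
0.12, 0.04) over the three years before a local extinction, because
cliff-edge extinctions from high occupancy would otherwise produce a heavy
*negative* tail the real data do not show; and fine-watershed presence
(nearest-county proportion exceeding a fixed per-unit threshold) gets small
downward-only flicker (p = 0.05) so observed extinction-rate series are
non-degenerate. Flicker never adds presence, so fine flags remain consistent
with county occupancy.

What a green test does **not** establish: realistic spatial covariance of
real covariates, reporting-effort artifacts, detection error (explicitly
out of scope), or the actual magnitude of national headline figures — those
depend on confidential mapping data and census tables and are excluded as
numeric targets. The tests establish that the machinery is correct:
arithmetic identities, parameter recovery from known truth, simulator
invariants, and oracle equivalence on small instances.

`make_truth_scenario` generates coarse-watershed occupancy counts from
exactly the binomial-logit model the fitting routine estimates, and draws
rate series directly from the stated betas, so recovery tests compare like
with like; the alternative (generating through the beta-count simulator)
would bias GLM recovery and make the test uninterpretable.

## 7. Numerical details

* Beta moment fit refuses zero variance and `v ≥ m(1−m)` (no valid beta).
* Counts from rates use `round()`; capping at availability is logged.
* Rate-summary confidence intervals are mean ± 1.96 SE (the published
  intervals are symmetric and unattributed).
* Tree split search scores exact SSE reduction with a minimum improvement
  of 1e−12 to avoid degenerate splits; thresholds are midpoints between
  adjacent distinct values, so training-set recovery of axis-aligned
  structure is exact.
* All generators fan one master seed into per-table child seeds; rerunning
  any stage with the same config is byte-identical (checksummed manifests).

## 8. Limitations

Synthetic magnitudes are arbitrary-scale; only structure transfers. The
penalized fit approximates a full posterior with its mode; forecasting
consumes only the probability function, but interval statements about
coefficients use the penalized information matrix. The two frameworks share
the synthetic world but not error structure; ensemble summaries treat all
eight models as exchangeable, as the source does.
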