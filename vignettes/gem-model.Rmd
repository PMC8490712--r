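---
title: "A multiplicative genetics x environment x management model for county crop yield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiplicative genetics x environment x management model for county crop yield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemyield)
library(dplyr)
```

## The model and its assumptions

`gemyield` predicts county-year maize yield as the product of three
components, each with an agronomic interpretation:

* **Environment** sets a weekly *growth potential* $G_{c,t,w}$, a quadratic
  form in the week's normalized weather variables and the county's
  normalized soil variables — intercept, linear effects, squares, and every
  bilinear product (weather x weather, soil x soil, weather x soil). The
  seasonal sum of positive weekly potentials,
  $E = \sum_w \max(G_{c,t,w}, 0)$, is the attainable yield under the
  observed weather and soil.
* **Genetics** is a polynomial of order $K$ in the normalized year, shared
  by all counties of a crop reporting district and constrained to $[0, 1]$
  with year-over-year changes in $[-2.5\%, +5\%]$. It absorbs the slow
  yield trend that neither environment nor management explains, which for
  maize is dominated by cultivar improvement.
* **Management** combines plant density $D$ with the share of the crop in
  the ground each week, $P_w - H_w$ (cumulative planting minus cumulative
  harvesting): $M = \sum_w D (P_w - H_w) G_w / E$.

The forward prediction is
$\hat y = (\sum_k \alpha_k t^k)\cdot\sum_w D (P_w - H_w) G_{w}$, and by
construction $\hat y = G\cdot E\cdot M$ whenever $E > 0$.

The structural assumptions are: components multiply (a poor environment
scales down what genetics and management can deliver); weekly
environmental effects add across the season (the same logic as growing
degree days); the season has exactly two coefficient regimes (vegetative,
reproductive) split at the first week with planting 100% complete; and
effects of weather and soil are at most quadratic. These buy convexity of
both calibration subproblems at the price of flexibility — there is no
week-by-week phenology and no higher-order response.

### Conventions and edge cases

* Weeks are fixed 7-day blocks from January 1; days 365/366 fold into week
  52. The summation runs over all 52 weeks: outside the season
  $P_w - H_w = 0$, so the extra weeks contribute nothing.
* The division week itself belongs to the reproductive stage (the two
  stages must partition the 52 weeks; the boundary week is the first
  *after* planting completes).
* The weather-soil cross terms use the week-specific weather value, like
  every other weather term.
* When $E = 0$ (no week with positive potential) the record is flagged,
  $M$ is reported as 0, and $\hat y$ is computed directly from the forward
  model — never from the $G\cdot E\cdot M$ product.
* Only the product $G \cdot E \cdot M$ is identified: a scalar can move
  between the genetic level and the coefficient scale (and, through the
  sign pattern of $G_w$, between $E$ and $M$). Recovery experiments
  therefore test *predictions*, and the interaction map up to one global
  scale factor.

## Normalization

Weather variables, soil variables, plant density and the year index are
min-max scaled to $[0, 1]$; yields and planted areas stay in natural units
(bu/ac, acres). Scalers are fit on the *training* scope only and re-applied
to held-out data, so cross-validation never leaks the held-out records'
ranges; held-out values may then fall slightly outside $[0, 1]$, which the
model tolerates (the quadratic form and the linear density term extrapolate
smoothly). A variable constant over its scaling scope maps to 0 with a
warning rather than an error — degenerate soil columns on tiny panels
should not abort a run.

One consequence worth knowing: because the genetic polynomial is only
constrained on the training years, the package evaluates it with the
normalized year clamped to $[0, 1]$. Predicting a year outside the training
window therefore carries the nearest training year's genetic level forward
instead of extrapolating a high-order polynomial, which is both the
conservative agronomic choice (future genetic gain is unknown) and a
numerical necessity at $K = 10$.

## Calibration

Both subproblems are convex QPs (solved with the dual active-set method of
`quadprog`):

1. **Stage coefficients** $\gamma^V, \gamma^R$ with genetics fixed:
   area-squared-weighted least squares with every subsample record's
   prediction constrained to $[0, 300]$ bu/ac. The cap rules out
   physically absurd fits (for reference, record contest yields are around
   500-600 bu/ac; county averages far lower).
2. **Genetic coefficients** $\alpha$ per district with the growth panel
   fixed: the same weighted least squares under the level bound $[0, 1]$
   and the change bound $[-2.5\%, +5\%]$, enforced at every training
   (district, year) — not only the subsampled records — because the
   constraints are cheap and the intent is a globally sensible trend. The
   change bound is skipped at the earliest year (no predecessor) and
   applied only across calendar-consecutive years.

Each step draws a fresh uniform subsample of $\lfloor 0.8 n\rfloor$ records
without replacement, solves its QP, blends the solution
$0.2\,\text{incumbent} + 0.8\,\text{candidate}$, and accepts only if the
blend strictly improves the full-data weighted RMSE — an
overfitting guard: a candidate that only explains its own subsample is
rejected. One iteration is a $\gamma$ step followed by an $\alpha$ step;
the loop stops after 2 consecutive iterations without any acceptance (or a
hard cap of 50). Initialization is a constant genetic multiplier of 1 and
all-zero stage coefficients.

Numerical details: weights are rescaled to mean 1 before forming the
normal-equations Hessian (conditioning only); if the Hessian is not
positive definite — collinear features, districts with fewer years than
$K + 1$ — an escalating relative ridge ($10^{-12}$ to $10^{-6}$ of the mean
diagonal) is added, starting from none so well-posed problems are solved
exactly. A QP that still fails raises an error carrying the solver status;
there is no silent fallback. Districts absent from a subsample keep their
incumbent coefficients for that step. With a fixed `rng_seed` the whole
trace is bit-reproducible.

### Choosing `K`

`K = 10` is the default, sized for a panel of ~40 years. On short panels a
degree-10 polynomial has almost one degree of freedom per year and will
interpolate year-specific anomalies into the "genetic" trend, which
destroys temporal transfer. The package's own synthetic studies (15 years)
use `K = 3`, matching the generator's trend class. Rule of thumb: keep
$K + 1$ well below the number of training years.

## Evaluation protocols

* **Leave-one-year-out**: fit without year $t$ (scalers refit on the
  training years), predict year $t$ from its observed weather, soil and
  management. Measures temporal transfer.
* **Leave-one-county-out**: fit without county $c$, predict it from its own
  covariates with its district's genetics learned from sibling counties. A
  held-out county that was its district's only member falls back to the
  state-level mean of fitted district coefficients, flagged in the output.
* **Baselines**: nearest-year (same county, closest other year; ties to
  the earlier year) and nearest-county (same year, smallest great-circle
  centroid distance; ties to the smallest county id). Ties are broken
  deterministically so runs are reproducible.
* **Metrics**: RMSE and $R^2$ weighted by squared planted area, so
  large-acreage counties dominate — the convention used throughout, and the
  reason a county's planted area matters as much as its yield.
* **In-season forecasting**: for a target year held out of training,
  observed daily weather through day $d$ is spliced with a historical
  year's weather for days $d+1$ to 365, aggregated to the weekly grid, and
  pushed through the model; one forecast curve per historical scenario
  year. The per-county predictions are averaged with planted-area weights
  from the most recent training year (the target year's areas are unknown
  mid-season). At $d = 365$ nothing is imputed and all curves collapse to
  one value.

## The synthetic generator

Everything is testable without data downloads because the generator builds
panels with the exact structure the model assumes, plus known truth:

* nested geography (counties in districts in states) on a latitude/
  longitude grid;
* weekly weather as a seasonal sinusoid per variable plus a latitude
  gradient, a per-year national anomaly, and i.i.d. weekly noise;
* static soil from a longitude gradient plus noise;
* plant density with a linear upward trend (the dominant real-world
  feature of seeding rates);
* logistic cumulative planting/harvest curves, midpoints shifted by
  latitude, reaching exactly 1;
* district genetic trends as scaled cumulative-logistic curves projected
  onto the degree-`K_true` polynomial basis, with an annual gain of
  1.5-2% so the change bound holds for any panel length;
* sparse stage coefficients with a seasonal sign structure (negative
  off-season potential, positive in-season), rescaled once so the
  area-weighted mean seasonal potential matches `target_potential`
  (default 500 bu/ac, in the range spanned by real-world contest yields
  and potential estimates) and no noiseless yield exceeds the 300 bu/ac
  cap;
* yields = noiseless model prediction + Gaussian noise (sd
  `yield_noise_sd`, default 10 bu/ac, truncated at 0), then
  `missing_fraction` (default 26%) of county-year records dropped — the
  roughly three-quarters coverage typical of national yield surveys.

The default configuration is deliberately compact — 3 states x 2 districts
x 2 counties x 15 years, 3 weather + 2 soil variables, `K_true` = 3 — so
the full test suite and the acceptance study run in minutes on one CPU.
Daily weather for in-season splicing is the piecewise-constant expansion of
the weekly values, making weekly aggregation of spliced series exact.

### What passing tests do and do not show

The generator's realism is *structural* (shapes, trends, nesting,
coverage), not climatological: no attempt is made to match real marginal
distributions of weather or soil, weather noise has no temporal
autocorrelation, and yield noise is homoscedastic. Two artifacts of the
compact scale deserve emphasis:

* Because density is min-max normalized and trend-dominated, early-year
  normalized density is near 0 and early-year synthetic yields are much
  lower than any real panel would show. This is the model's own
  multiplicative structure applied as a generator, kept because the truth
  must stay inside the fitted model class.
* With ~56 free parameters on ~134 records the coefficients are only
  weakly identified even when predictions are accurate: seasonal weather
  variables are collinear, so large compensating coefficient pairs leave
  training predictions unchanged but inflate transfer error. Noise-free
  held-out-year RMSE is therefore several times the training RMSE — at
  the real study's scale (~78,000 records against ~3,600 parameters) this
  gap largely disappears. Interpret coefficient-level quantities (the
  interaction map in particular) on compact panels only up to scale and
  rank of the dominant cells.

## Interaction map

The pairwise grid summarizes, for each unordered pair of distinct
variables, the bilinear coefficient plus each variable's linear and
quadratic effect spread evenly over its $v - 1$ partners
($1/16$ with the full 17-variable set; the package generalizes the factor
to $1/(v-1)$ for reduced variable sets). The intercept is excluded.
Vegetative cells fill one triangle of the matrix and reproductive cells the
other, so a stage's total non-intercept contribution is the sum of its 136
cells. Asymmetry across the diagonal is the interesting signal: the same
weather-soil combination can help one stage and hurt the other.

## Known limitations

* No uncertainty quantification: the calibration heuristic has no sampling
  theory attached, and no prediction intervals are produced.
* The stopping rule (two stagnant iterations) can leave optimization gains
  on the table on small panels; raising `stagnation_limit` trades time for
  a slightly better incumbent.
* Pooled leave-one-year-out error on the default noisy panel sits at the
  upper edge of $[0.8\sigma, 1.5\sigma]$ (about 13-20 bu/ac at
  $\sigma = 10$ depending on the seed), for the identifiability reasons
  above.
* Raw-source ingestion (gridded weather products, soil survey rasters,
  survey web services, shapefiles) is out of scope: the package consumes
  already-aggregated county tables.

```{r example, eval = FALSE}
sim <- sim_panel(sim_config(seed = 1))
fit <- fit_gem(sim$bundle, gem_control(K = 3, rng_seed = 2))
glance(fit)
autoplot(fit)
plot_interaction_map(fit)
cv_leave_year_out(sim$bundle, gem_control(K = 3, rng_seed = 2))
```
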