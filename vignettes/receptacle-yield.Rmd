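---
title: "Receptacle-count-corrected yield prediction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptacle-count-corrected yield prediction: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strawyield)
```

## The problem

A camera-based detector counts strawberry flower receptacles per plant
once a week. Two receptacle facts drive yield prediction: each harvested
fruit develops from exactly one receptacle, and a 2-D image never shows
all receptacles on a plant. The detector's count `n_obs` therefore
undercounts the true number `N`, and any fruiting probability computed
naively as `fruits / n_obs` is biased upward — sometimes above 1. This
package corrects the counts probabilistically, estimates per-cultivar
fruiting probabilities on the corrected scale, and asks which early-season
summaries best predict the final per-plant fruit count.

## The count-correction model

For each plant, `n_obs ~ Binomial(N, theta)`: every true receptacle is
independently captured-and-detected with probability `theta`, pooled
across cultivars (camera geometry, not genetics, drives visibility). A
calibration subsample of plants — by default 4 per cultivar — is fully
hand-counted, giving `(n_obs, n_mis)` pairs. With a uniform `Beta(1, 1)`
prior, the posterior is conjugate:

```{r theta}
cal <- tibble::tibble(n_obs = c(rep(3L, 7), rep(2L, 13)),
                      n_mis = c(2L, rep(1L, 19)))
fit_theta_posterior(cal)
```

For prediction we need `N` given `n_obs`, which requires a prior on `N`.
We adopt the improper flat prior over `N >= n_obs`: it is the
minimal-assumption choice, and under it `n_mis | theta` is negative
binomial with size `n_obs + 1` and success probability `theta`.
Marginalising `theta` over its beta posterior gives the
beta-negative-binomial predictive implemented in `predictive_missed()`,
evaluated in log space via log-gamma so large counts do not overflow,
with the support truncated at the smallest point bringing the tail mass
below `tolerance` (default `1e-8`). The predictive mean has the closed
form `n_obs + (n_obs + 1) * beta / (alpha - 1)` for `alpha > 1`; at
`alpha <= 1` the mean is infinite and flagged, while the pmf remains
valid. A Poisson prior on `N` could be substituted by changing only this
module; the flat prior is deliberately agnostic about receptacle
abundance.

```{r predictive}
pp <- predictive_missed(5, beta_posterior(48, 22))
pp
head(tidy(pp))
```

## Fruiting probabilities under count uncertainty

Fruit set per receptacle is overdispersed across plants — micro-climate
and vigour make some plants set nearly everything and others little — so
a plain binomial understates the uncertainty. `fit_quasibinomial()`
implements the quasi-likelihood treatment: a logit-link binomial fit by
iteratively reweighted least squares (initialised at continuity-corrected
empirical logits, converged at coefficient changes below `1e-10`), with
dispersion `phi` estimated from the Pearson statistic and standard errors
scaled by `sqrt(phi)`.

Quasi-likelihood has no genuine posterior for `pi`, so "the distribution
of `pi` given the data" is realised by *multiple imputation*: for each of
`n_imputations` rounds, a true count `N_i` is drawn per plant from its
posterior predictive, a per-cultivar-intercept quasi-binomial model of
season fruit totals on the imputed totals is fitted, and the round's
fitted `pi` per cultivar is recorded. This is a cut (modular) inference:
the count model informs the fruiting model but not vice versa. Two
further choices:

- `theta` is drawn independently per plant within each round, following
  the composition sampler `sample_total()`. Drawing one shared `theta`
  per round is statistically defensible too (there is a single unknown
  `theta`); the per-plant draws slightly widen the imputation spread and
  keep the sampler embarrassingly vectorisable.
- If a plant's fruit total exceeds its imputed receptacle total, the
  draw is raised to the fruit total — a fruit proves its receptacle
  existed. Occurrences are counted and reported (`attr(-, "n_clipped")`).

## The regression stage

From the first `window_weeks` weeks (default 4, mirroring a one-month
early-season observation window), each plant contributes `frt` and `rec`
— least-squares slopes per week of its cumulative fruit and cumulative
detected-receptacle counts — and the response is the cumulative fruit
count at the final week. Four nested OLS models are compared (M1:
cultivar; M2: + `frt`; M3: cultivar + `logit(prob)` + `rec`; M4: + the
interaction), by AIC under the full Gaussian log-likelihood convention
(with the `2*pi` constant, `sigma^2` counted as a parameter — the
convention of mainstream statistical software), adjusted R², and LOOCV
mean squared error. The LOOCV value is computed by the hat-matrix
identity `mean((e_i / (1 - h_ii))^2)` *and* by explicit refits; the two
must agree to `1e-8` or the function aborts, so the shortcut can never
silently drift from its definition. Rate of change is an OLS slope
rather than a last-minus-first difference because it uses all four weeks
and is insensitive to single-week noise; the difference variant is a
one-line change in `rate_of_change()`.

**Why `logit(prob)` is a per-plant quantity.** A fruiting probability
constant within cultivar is a linear combination of the intercept and
cultivar indicators, so M3/M4 would be exactly rank-deficient. The
models are only identifiable if `prob` varies within cultivar, so
`build_feature_table()` defines it per plant as
`logit((fruits_i + pi_c) / (E[N_i | n_obs_i] + 1))`: the plant's
empirical fruiting ratio on the count-corrected scale, with the cultivar
estimate `pi_c` entering as a one-observation pseudo-count. The
pseudo-count keeps the ratio inside (0, 1) for fruitless plants and makes
a plant fruiting exactly at its cultivar's rate score `logit(pi_c)`.
`prob_level = "cultivar"` restores the cultivar-level value for model
formulas without cultivar terms.

The analysis unit is the plant. In this trial design each cultivar ×
replication cell holds one plant, so per-plant rows and
per-replication-block averages coincide.

## What the synthetic trial emulates — and what it does not

`simulate_trial()` generates a 5-cultivar greenhouse trial observed
weekly over 15 weeks. Defaults are the study conditions of the pipeline:
detection probability 0.686, cultivar fruiting probabilities 0.30, 0.45,
0.55, 0.65, 0.80, 4 calibration plants per cultivar, a 4-week predictor
window. Where no value is dictated by the protocol we fixed, once, what a
greenhouse trial plausibly shows:

- **Receptacle emergence** is Poisson per plant-week with a cultivar
  rate (defaults 2–3.5 per week, giving ~25–45 receptacles per plant per
  season). Emergence is the simplest count law with one parameter; real
  flowering has flushes and a seasonal envelope the simulator does not
  attempt.
- **Overdispersed fruiting** is beta-binomial: each plant draws its
  fruiting probability from a beta distribution with the cultivar mean
  and intra-plant correlation `rho` (default 0.05 — with ~40 receptacles
  per plant this yields Pearson dispersions around 2–3, the regime that
  motivates a quasi-binomial treatment). `rho = 0` collapses exactly to
  binomial fruiting, which the tests exploit.
- **Phenology**: receptacles emerge during weeks 1 to
  `n_weeks - fruit_lag` and each fruiting receptacle is harvested
  `fruit_lag` weeks later (default 2). Flowering ending before the last
  harvest makes every receptacle resolve within the season, so the
  conservation law (total fruits ≤ total receptacles, per plant) is
  exact and season totals identify `pi`. Real maturation times vary per
  fruit; the fixed lag is a simplification.
- **False positives** (a bee sitting on a receptacle, a leaf) are
  additive Poisson noise on the detected count, default 0. When present,
  calibration `n_mis` values are clipped at zero and the clips counted.
- **Box fixtures**: `simulate_box_pairs()` places axis-aligned boxes
  uniformly on a fixed canvas with Gaussian corner jitter, random
  deletions and spurious boxes. These are geometric fixtures for the
  metric code; they carry no image statistics (no occlusion structure,
  no scale distribution), so passing metric tests says nothing about any
  particular detector.

Consequently, passing recovery tests demonstrates that the estimators
are consistent with their own generative assumptions — binomial
thinning, beta-binomial fruiting — not that those assumptions hold in a
particular greenhouse. In real data, `theta` plausibly varies with plant
architecture (violating pooling), and fruit set varies over the season
(violating the single-`pi` model); both would widen true uncertainty
beyond what the intervals state.

## Detection metrics

`iou()` is the overlap-over-union area ratio of two boxes in continuous
corner coordinates. Matching is greedy per image: predictions in
descending confidence order, each taking the unmatched ground-truth box
of highest IoU provided the IoU is at least the threshold (we read
"above the threshold" as the conventional `>=`), one match per
ground-truth box. Average precision uses the 101-point interpolated
precision envelope (the COCO convention — the relevant benchmark here);
the all-point variant is an argument (`interpolation = "all_points"`),
not a fork. `mean_average_precision()` sweeps thresholds 0.50 to 0.95 in
steps of 0.05 and averages. Score ties are broken by stable input order;
on the test fixtures this affects AP at most in the fourth decimal.
Degenerate inputs are pinned down explicitly: no predictions with
non-empty truth gives AP 0, predictions with empty truth gives AP 0, and
both sets empty is an error (the metric is undefined, and silently
returning either 0 or 1 would corrupt threshold averages).

## Numerical choices and degenerate inputs

- Beta-negative-binomial pmf in log space; tail truncation tolerance
  default `1e-8`, validated against an adaptive-quadrature oracle to
  `1e-8` in the tests.
- IRLS separation (probabilities collapsing to 0/1) flags
  `converged = FALSE` with a diagnostic rather than erroring: an
  imputation round with a degenerate cultivar should be inspectable.
- OLS with RSS at rounding-noise level (`<= 1e-12` of the response sum
  of squares) reports `AIC = -Inf` rather than a meaningless large
  negative number; leverage-1 units make the deleted residual undefined
  and raise an error.
- `logit()` rejects 0 and 1 outright; all probability ratios fed to it
  are continuity-corrected at the source.
- One global seed is expanded into recorded per-stage child seeds, so a
  pipeline run is reproduced byte-for-byte from its manifest.

## Problem sizes in the test suite

The suite exercises the estimators at sizes chosen to make Monte-Carlo
bounds sharp while keeping the whole suite under half a minute: 5000
plants for generator rate checks, 10^5+ receptacles for detection-rate
checks, 200 replicates for detection-proportion coverage, a 5 × 25-plant
trial with 200 imputations for fruiting recovery, 50 random fixtures
each for the metric and LOOCV oracle equivalences, and 100 replicates
per arm of the model-selection simulation.

## Known limitations

- A single pooled `theta`; no plant-level detection heterogeneity (a
  per-cultivar option exists for calibration but the reported pipeline
  pools, as the calibration sample is far too small to stratify).
- `pi` is constant over the season within cultivar; no temporal fruiting
  dynamics, no covariates beyond cultivar.
- The yield models are linear with homoscedastic Gaussian errors; counts
  near zero would call for a GLM, but end-of-season totals here are far
  from zero.
- The imputation propagates count uncertainty into `pi` but the
  regression uses `prob` point values; propagating the full `pi`
  distribution into the regression is a documented extension, off by
  default.
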