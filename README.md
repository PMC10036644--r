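# strawyield

Predicting end-of-season strawberry yield per plant from AI-detected
flower receptacle counts.

The receptacle — the yellow centre of the strawberry flower that develops
into the fruit — is a more direct early-season predictor of yield than the
harvest itself. An object detector counting receptacles in 2-D images,
however, misses a substantial fraction of them (and occasionally invents
one), so the raw AI count systematically undercounts the plant. This
package implements the statistical pipeline that turns those imperfect
counts into yield predictions:

1. **Count correction.** For a plant with true receptacle count *N*, the
   detected count is modelled as *n*<sub>obs</sub> ~ Binomial(*N*, θ),
   where θ is the detection proportion. A calibration subsample of
   hand-counted plants (detected *n*<sub>obs</sub> and missed
   *n*<sub>mis</sub> per plant) updates a uniform Beta(1, 1) prior
   conjugately: θ | data ~ Beta(1 + Σ*n*<sub>obs</sub>, 1 + Σ*n*<sub>mis</sub>).
   Under a flat prior on *N*, the posterior predictive of the missed
   count is beta-negative-binomial:
   P(*n*<sub>mis</sub> = *m*) = C(*n*<sub>obs</sub>+*m*, *m*) ·
   B(α + *n*<sub>obs</sub> + 1, β + *m*) / B(α, β),
   with mean *n*<sub>obs</sub> + (*n*<sub>obs</sub>+1)·β/(α−1).
2. **Fruiting probability.** Given imputed true counts, the probability π
   that a receptacle yields a harvested fruit is estimated per cultivar by
   a quasi-binomial GLM (logit link, Pearson-based dispersion φ) — the
   overdispersion-aware treatment of proportion data — under multiple
   imputation of *N*, so the reported spread of π reflects the count
   uncertainty.
3. **Yield regression.** Four nested linear models of the end-of-season
   fruit count μ per plant are compared: M1 cultivar only; M2 + *frt*
   (early-season rate of change of the fruit count); M3 cultivar +
   logit(*prob*) + *rec* (rate of change of the detected receptacle
   count); M4 + the *rec* × logit(*prob*) interaction. Models are ranked
   by AIC, adjusted R², and the mean squared error of leave-one-out
   cross-validation (computed by the hat-matrix identity and verified
   against explicit refits).

The package also implements the standard object-detection evaluation
metrics (IoU, average precision at IoU thresholds 0.50–0.95 in steps of
0.05, and their mean, mAP) on bounding-box sets, plus AI-vs-human count
comparison statistics — and a synthetic greenhouse-trial generator so the
entire pipeline is testable without field data.

## Worked example

Simulate a 5-cultivar × 25-plant trial (detection probability 0.686,
cultivar fruiting probabilities 0.30–0.80), calibrate θ on 4 hand-counted
plants per cultivar, and run the full pipeline:

```r
library(strawyield)

cfg <- pipeline_config(simulation = sim_config(n_plants_per_cultivar = 25),
                       seed = 2026)
res <- run_pipeline(cfg, outdir = "demo")

res$theta_posterior
#> Beta(45, 22) for detection proportion theta; mean 0.6716

res$fruiting[, c("cultivar", "pi_point", "pi_q025", "pi_q975")]
#> # A tibble: 5 × 4
#>   cultivar pi_point pi_q025 pi_q975
#>   <chr>       <dbl>   <dbl>   <dbl>
#> 1 A           0.324   0.305   0.341
#> 2 J           0.431   0.408   0.455
#> 3 K           0.541   0.513   0.563
#> 4 M           0.649   0.609   0.694
#> 5 S           0.825   0.784   0.862

res$comparison
#> Yield model comparison (best by LOOCV MSE: M4 )
#> # A tibble: 4 × 5
#>   model n_terms   aic adj_r2 loocv_mse
#>   <chr>   <dbl> <dbl>  <dbl>     <dbl>
#> 1 M1          5  827.  0.574      43.0
#> 2 M2          6  766.  0.738      26.5
#> 3 M3          7  744.  0.782      22.8
#> 4 M4          8  721.  0.821      20.3
```

The calibration recovers the generating detection proportion (posterior
mean 0.672 against a true 0.686), the cultivar fruiting probabilities are
recovered within their imputation intervals, and model comparison selects
M4 — receptacle growth rate interacting with fruiting probability — over
knowing the first month's harvest (M2), with the lowest LOOCV MSE and
AIC and the highest adjusted R². Every artifact (trial and calibration
CSVs, posterior and model-comparison JSON, manifest with checksums) is
written to `outdir`, and the same seed reproduces them byte for byte.

Detection metrics work directly on box tibbles or COCO-style JSON:

```r
pairs <- simulate_box_pairs(n_images = 50, boxes_per_image = 4,
                            jitter = 8, miss_rate = 0.15, seed = 1)
mean_average_precision(pairs$ground_truth, pairs$predictions)
```

A thin command-line front end is installed at
`inst/scripts/strawyield` (`run-all`, `simulate`, `eval-boxes`
subcommands).

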