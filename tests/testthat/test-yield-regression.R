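test_that("rate of change is the least-squares slope per week", {
  expect_equal(rate_of_change(rep(4, 5)), 0)
  expect_equal(rate_of_change(1:5), 1)
  y <- c(2, 3, 5, 4); x <- 1:4
  expect_equal(rate_of_change(y),
               sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2))
  expect_error(rate_of_change(3), "at least two")
})

test_that("feature table has the dummy-coded shape of the trial", {
  cfg <- sim_config(seed = 8)
  trial <- simulate_detections(simulate_trial(cfg), 0.686, seed = 9)
  post <- beta_posterior(48, 22)
  fruiting <- estimate_pi_per_cultivar(trial, post, n_imputations = 20, seed = 10)
  feats <- build_feature_table(trial, fruiting, post)

  expect_equal(nrow(feats), 25)
  dummies <- as.matrix(feats[, c("J", "K", "M", "S")])
  expect_true(all(rowSums(dummies) <= 1))
  expect_equal(sum(rowSums(dummies) == 0), 5)  # reference cultivar A
  expect_true(all(feats$J[feats$cultivar == "J"] == 1))
  expect_true(all(is.finite(feats$frt)) && all(is.finite(feats$rec)))

  # cultivar-level prob: pi = 0.5 maps to logit_prob 0
  half <- dplyr::mutate(fruiting, pi_point = 0.5)
  feats_cv <- build_feature_table(trial, half, prob_level = "cultivar")
  expect_true(all(feats_cv$logit_prob == 0))

  bad <- dplyr::filter(fruiting, cultivar != "K")
  expect_error(build_feature_table(trial, bad, post), "K")
})

test_that("OLS fit matches the reference implementation and the perfect-fit limit", {
  set.seed(13)
  feats <- make_features_from_truth(b_rec = 3, b_prob = 2, interaction = 1.5,
                                    sigma = 2)
  for (label in c("M1", "M2", "M3", "M4")) {
    fit <- fit_ols(feats, label)
    form <- switch(label,
      M1 = response ~ J + K + M + S,
      M2 = response ~ J + K + M + S + frt,
      M3 = response ~ J + K + M + S + logit_prob + rec,
      M4 = response ~ J + K + M + S + logit_prob + rec + rec:logit_prob)
    ref <- stats::lm(form, data = feats)
    ref_sum <- summary(ref)
    expect_lt(max(abs(unname(fit$coefficients) - unname(stats::coef(ref)))), 1e-8)
    expect_lt(max(abs(unname(fit$standard_errors) -
                        unname(ref_sum$coefficients[, "Std. Error"]))), 1e-8)
    expect_lt(abs(fit$aic - stats::AIC(ref)), 1e-8)
    expect_equal(fit$adj_r2, ref_sum$adj.r.squared, tolerance = 1e-10)
    expect_lte(fit$adj_r2, fit$r2)
    expect_true(all(fit$p_values > 0 & fit$p_values <= 1))
    expect_lt(max(abs(fit$p_values -
                        2 * stats::pt(-abs(fit$t_values), fit$n - fit$p_terms))),
              1e-10)
  }

  # exact linear data: R2 = 1, RSS = 0, AIC reported non-finite
  exact <- feats
  exact$response <- 2 + 3 * exact$rec
  fit0 <- fit_ols(exact, "M3")
  expect_equal(fit0$r2, 1)
  expect_equal(fit0$adj_r2, 1)
  expect_lt(fit0$rss, 1e-18)
  expect_false(is.finite(fit0$aic))
})

test_that("coefficients of the generating model are recovered within 3 SE", {
  set.seed(57)
  feats <- make_features_from_truth(n_per_cultivar = 60, b_frt = 8, sigma = 2)
  fit <- fit_ols(feats, "M2")
  expect_lt(abs(fit$coefficients[["frt"]] - 8), 3 * fit$standard_errors[["frt"]])
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - 14),
            3 * fit$standard_errors[["(Intercept)"]])
})

test_that("rank deficiency is reported with the collinear term", {
  set.seed(3)
  feats <- make_features_from_truth()
  feats$logit_prob <- 2 * feats$rec  # force collinearity with rec
  expect_error(fit_ols(feats, "M3"), "collinear")
})

test_that("hat-matrix LOOCV equals explicit refits across random fixtures", {
  set.seed(29)
  for (r in 1:50) {
    feats <- make_features_from_truth(n_per_cultivar = sample(3:6, 1),
                                      b_rec = runif(1, -3, 3),
                                      interaction = runif(1, -2, 2),
                                      sigma = runif(1, 0.5, 4))
    label <- sample(c("M1", "M2", "M3", "M4"), 1)
    # loocv_mse internally verifies the shortcut against explicit refits
    # to 1e-8 and aborts on disagreement
    expect_silent(v <- loocv_mse(feats, label))
    expect_gte(v, 0)
  }
})

test_that("perfect linear data has zero LOOCV error", {
  set.seed(5)
  feats <- make_features_from_truth()
  feats$response <- 1 + 2 * feats$rec - feats$logit_prob
  expect_lt(loocv_mse(feats, "M3"), 1e-16)
})

test_that("model comparison reports the Table-1 term sets and RSS nesting", {
  set.seed(91)
  feats <- make_features_from_truth(b_rec = 3, b_prob = 2, interaction = 2,
                                    sigma = 2.5)
  cmp <- compare_models(feats)
  expect_equal(cmp$fits$M1$terms, c("(Intercept)", "J", "K", "M", "S"))
  expect_equal(cmp$fits$M2$terms, c("(Intercept)", "J", "K", "M", "S", "frt"))
  expect_equal(cmp$fits$M3$terms,
               c("(Intercept)", "J", "K", "M", "S", "logit(prob)", "rec"))
  expect_equal(cmp$fits$M4$terms,
               c("(Intercept)", "J", "K", "M", "S", "logit(prob)", "rec",
                 "rec:logit(prob)"))
  # adding terms never increases RSS (M1 < M2 and M1 < M3 < M4 nests)
  expect_lte(cmp$fits$M2$rss, cmp$fits$M1$rss)
  expect_lte(cmp$fits$M3$rss, cmp$fits$M1$rss)
  expect_lte(cmp$fits$M4$rss, cmp$fits$M3$rss)
  expect_equal(cmp$best_model,
               cmp$comparison$model[which.min(cmp$comparison$loocv_mse)])

  tidied <- tidy(cmp)
  expect_equal(names(tidied),
               c("model", "term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(tidied), 5 + 6 + 7 + 8)
})

test_that("tidiers expose the coefficient table of a single fit", {
  set.seed(17)
  feats <- make_features_from_truth(sigma = 2)
  fit <- fit_ols(feats, "M1")
  td <- tidy(fit)
  expect_equal(td$estimate, unname(fit$coefficients))
  gl <- glance(fit)
  expect_equal(gl$AIC, fit$aic)
})
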