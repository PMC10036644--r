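test_that("conjugate update pools calibration counts onto the uniform prior", {
  # pooled totals 47 detected / 21 missed across 20 plants
  cal <- tibble::tibble(
    plant_id = sprintf("p%02d", 1:20),
    cultivar = rep(c("A", "J", "K", "M", "S"), each = 4),
    n_obs = c(rep(3L, 7), rep(2L, 13)),
    n_mis = c(2L, rep(1L, 19))
  )
  expect_equal(sum(cal$n_obs), 47)
  expect_equal(sum(cal$n_mis), 21)
  post <- fit_theta_posterior(cal, prior = beta_posterior(1, 1))
  expect_equal(post$alpha, 48)
  expect_equal(post$beta, 22)
  expect_equal(post$alpha / (post$alpha + post$beta), 48 / 70)

  # all-zero counts return the prior unchanged
  zero <- tibble::tibble(n_obs = 0L, n_mis = 0L)
  ident <- fit_theta_posterior(zero, prior = beta_posterior(1, 1))
  expect_equal(c(ident$alpha, ident$beta), c(1, 1))

  expect_error(fit_theta_posterior(cal[0, ]), "empty")
  expect_error(fit_theta_posterior(tibble::tibble(n_obs = -1L, n_mis = 0L)),
               "n_obs")
})

test_that("predictive pmf matches the quadrature oracle and normalizes", {
  post <- beta_posterior(48, 22)
  for (n_obs in c(0L, 1L, 5L, 20L)) {
    pp <- predictive_missed(n_obs, post, tolerance = 1e-8)
    expect_equal(pp$support[1], n_obs)
    m <- pp$support - n_obs
    expect_lt(max(abs(pp$pmf - oracle_bnb_pmf(m, n_obs, 48, 22))), 1e-8)
    expect_lt(abs(sum(pp$pmf) + pp$tail_mass - 1), 1e-10)
    expect_lte(pp$tail_mass, 1e-8)
    expect_equal(pp$mean_total, n_obs + (n_obs + 1) * 22 / 47)
  }
})

test_that("predictive collapses to the observed count under near-perfect detection", {
  pp <- predictive_missed(7, beta_posterior(1e6, 1))
  expect_lt(abs(pp$pmf[1] - 1), 1e-4)
  expect_true(all(sample_total(7, beta_posterior(1e6, 1), 500, seed = 2) == 7))
})

test_that("infinite predictive mean is flagged when alpha <= 1", {
  expect_warning(pp <- predictive_missed(3, beta_posterior(1, 5), tolerance = 1e-4),
                 "infinite")
  expect_identical(pp$mean_total, Inf)
  expect_gt(length(pp$pmf), 0)
})

test_that("composition sampling agrees with the analytic pmf and is seeded", {
  post <- beta_posterior(48, 22)
  draws <- sample_total(5, post, 2e5, seed = 123)
  expect_identical(draws, sample_total(5, post, 2e5, seed = 123))

  pp <- predictive_missed(5, post)
  # per-support-point agreement within 3 binomial SE
  for (k in which(pp$pmf > 1e-4)) {
    p_hat <- mean(draws == pp$support[k])
    se <- sqrt(pp$pmf[k] * (1 - pp$pmf[k]) / length(draws))
    expect_lt(abs(p_hat - pp$pmf[k]), 3 * se + 1e-12)
  }
  # Monte-Carlo mean within 3 SE of the closed form
  expect_lt(abs(mean(draws) - pp$mean_total),
            3 * sd(draws) / sqrt(length(draws)))
})

test_that("credible intervals match beta quantiles and posterior symmetry", {
  expect_equal(unname(theta_interval(beta_posterior(1, 1), 0.95)),
               c(0.025, 0.975))
  sym <- theta_interval(beta_posterior(7, 7), 0.9)
  expect_lt(abs((sym[["lower"]] + sym[["upper"]]) / 2 - 0.5), 1e-10)

  # root-finding oracle on the regularized incomplete beta
  ci <- theta_interval(beta_posterior(48, 22), 0.95)
  lo <- uniroot(function(x) pbeta(x, 48, 22) - 0.025, c(0, 1), tol = 1e-12)$root
  hi <- uniroot(function(x) pbeta(x, 48, 22) - 0.975, c(0, 1), tol = 1e-12)$root
  expect_lt(abs(ci[["lower"]] - lo), 1e-8)
  expect_lt(abs(ci[["upper"]] - hi), 1e-8)
})

test_that("expected missed counts are ordered in alpha and in n_obs", {
  # same alpha + beta: larger alpha (better detection) -> fewer missed
  mean_mis <- function(a, b, n_obs) (n_obs + 1) * b / (a - 1)
  posts <- list(c(30, 40), c(40, 30), c(50, 20), c(60, 10))
  means <- vapply(posts, function(ab) {
    predictive_missed(10, beta_posterior(ab[1], ab[2]))$mean_total - 10
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  # strictly increasing in n_obs
  by_nobs <- vapply(0:8, function(n) {
    predictive_missed(n, beta_posterior(48, 22))$mean_total - n
  }, numeric(1))
  expect_true(all(diff(by_nobs) > 0))
  expect_equal(by_nobs, mean_mis(48, 22, 0:8))
})

test_that("simulated calibration recovers the detection proportion", {
  # ~200 receptacles per replicate at several true detection levels
  for (theta_true in c(0.3, 0.686, 0.9)) {
    n_rep <- 60
    covered <- logical(n_rep)
    est <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      cfg <- sim_config(n_plants_per_cultivar = 4, n_weeks = 7,
                        receptacle_rate_per_week = rep(2, 5),
                        detection_prob = theta_true, seed = 5000 + r)
      trial <- simulate_detections(simulate_trial(cfg), theta_true,
                                   seed = 6000 + r)
      cal <- make_calibration_sample(trial, 4, seed = r, mode = "cumulative")
      post <- fit_theta_posterior(cal)
      ci <- theta_interval(post, 0.95)
      covered[r] <- ci[["lower"]] <= theta_true && theta_true <= ci[["upper"]]
      est[r] <- post$alpha / (post$alpha + post$beta)
    }
    expect_gte(mean(covered), 0.90)
    expect_lt(abs(mean(est) - theta_true), 0.02)
  }
})
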