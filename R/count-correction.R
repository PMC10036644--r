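#' Beta distribution for the detection proportion
#'
#' Container for the prior or posterior of the probability `theta` that a
#' receptacle present on the plant is captured and detected in the image.
#'
#' @param alpha,beta Positive shape parameters.
#' @return A `beta_posterior` object.
#' @export
beta_posterior <- function(alpha, beta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0 ||
      !is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta <= 0) {
    abort_field("alpha/beta", "shape parameters must be single positive numbers")
  }
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "beta_posterior")
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) for detection proportion theta; mean %.4f\n",
              x$alpha, x$beta, x$alpha / (x$alpha + x$beta)))
  invisible(x)
}

#' Conjugate update of the detection-proportion posterior
#'
#' Each calibration plant contributes its detected (`n_obs`) and missed
#' (`n_mis`) receptacle counts; the detected count is binomial in the true
#' total with probability `theta`, so a beta prior updates conjugately by
#' pooling counts across plants:
#' `alpha' = alpha + sum(n_obs)`, `beta' = beta + sum(n_mis)`.
#' A single `theta` is pooled across cultivars.
#'
#' @param calibration Tibble with integer columns `n_obs` and `n_mis`,
#'   one row per hand-counted plant.
#' @param prior A [beta_posterior()]; default the uniform Beta(1, 1).
#' @return The posterior as a [beta_posterior()].
#' @examples
#' # pooled totals 47 detected / 21 missed give Beta(48, 22)
#' cal <- tibble::tibble(n_obs = c(20, 27), n_mis = c(10, 11))
#' fit_theta_posterior(cal)
#' @export
fit_theta_posterior <- function(calibration, prior = beta_posterior(1, 1)) {
  check_columns(calibration, c("n_obs", "n_mis"), "calibration")
  if (nrow(calibration) == 0L) {
    abort("calibration sample is empty", class = "strawyield_validation_error")
  }
  check_nonneg(calibration$n_obs, "n_obs")
  check_nonneg(calibration$n_mis, "n_mis")
  if (!inherits(prior, "beta_posterior")) {
    abort_field("prior", "must be a beta_posterior object")
  }
  beta_posterior(prior$alpha + sum(calibration$n_obs),
                 prior$beta + sum(calibration$n_mis))
}

#' Equal-tailed credible interval for the detection proportion
#'
#' @param posterior A [beta_posterior()].
#' @param level Interval probability in (0, 1).
#' @return Named numeric vector `c(lower, upper)` of beta quantiles.
#' @export
theta_interval <- function(posterior, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    abort_field("level", "must lie strictly inside (0, 1)")
  }
  q <- qbeta(c((1 - level) / 2, 1 - (1 - level) / 2),
             posterior$alpha, posterior$beta)
  c(lower = q[1], upper = q[2])
}

# Beta-negative-binomial log pmf of the missed count m given n_obs and a
# Beta(alpha, beta) posterior on theta, under a flat prior on the true
# count N >= n_obs:
#   P(m) = C(n_obs + m, m) * B(alpha + n_obs + 1, beta + m) / B(alpha, beta)
# Evaluated in log space via log-gamma so large counts do not overflow.
dbnbinom_log <- function(m, n_obs, alpha, beta) {
  lchoose(n_obs + m, m) + lbeta(alpha + n_obs + 1, beta + m) - lbeta(alpha, beta)
}

#' Posterior predictive of the true receptacle count
#'
#' Given an AI count `n_obs` and the beta posterior for the detection
#' proportion, returns the distribution of the true count
#' `N = n_obs + n_mis`. Under a flat prior on `N`, the missed count given
#' `theta` is negative binomial with size `n_obs + 1` and success
#' probability `theta`; marginalising `theta` over its beta posterior
#' yields the beta-negative-binomial pmf, evaluated in log space. The
#' support is truncated at the smallest `N_max` whose tail mass does not
#' exceed `tolerance`.
#'
#' The predictive mean of `N` is `n_obs + (n_obs + 1) * beta / (alpha - 1)`
#' when `alpha > 1`; for `alpha <= 1` the mean is infinite and reported as
#' such (the pmf is still returned).
#'
#' @param n_obs Observed (detected) count, a non-negative integer.
#' @param posterior A [beta_posterior()] for the detection proportion.
#' @param tolerance Maximum allowed truncated tail mass, in (0, 1e-4].
#' @return A `count_predictive` object: list with `n_obs`, `support`
#'   (integers starting at `n_obs`), `pmf`, `tail_mass`, `mean_total`,
#'   `alpha`, `beta`.
#' @export
predictive_missed <- function(n_obs, posterior, tolerance = 1e-8) {
  n_obs <- check_count(n_obs, "n_obs", min = 0L)
  if (!is.numeric(tolerance) || length(tolerance) != 1L ||
      tolerance <= 0 || tolerance > 1e-4) {
    abort_field("tolerance", "must lie in (0, 1e-4]")
  }
  a <- posterior$alpha
  b <- posterior$beta

  m_max <- 64L
  repeat {
    m <- 0:m_max
    pmf <- exp(dbnbinom_log(m, n_obs, a, b))
    tail_mass <- max(0, 1 - sum(pmf))
    if (tail_mass <= tolerance) break
    if (m_max > 5e7) {
      abort("predictive support did not reach the tail tolerance; tail too heavy",
            class = "strawyield_error")
    }
    m_max <- m_max * 4L
  }
  # trim to the smallest N_max meeting the tolerance
  cum_tail <- 1 - cumsum(pmf)
  k <- which(cum_tail <= tolerance)[1]
  m <- 0:(k - 1)
  pmf <- pmf[seq_len(k)]
  tail_mass <- max(0, 1 - sum(pmf))

  if (a > 1) {
    mean_total <- n_obs + (n_obs + 1) * b / (a - 1)
  } else {
    warn("posterior alpha <= 1: predictive mean of N is infinite")
    mean_total <- Inf
  }

  structure(
    list(n_obs = n_obs, support = n_obs + m, pmf = pmf,
         tail_mass = tail_mass, mean_total = mean_total,
         alpha = a, beta = b, tolerance = tolerance),
    class = "count_predictive"
  )
}

#' @export
print.count_predictive <- function(x, ...) {
  cat(sprintf("Posterior predictive of N | n_obs = %d under Beta(%g, %g)\n",
              x$n_obs, x$alpha, x$beta))
  cat(sprintf("  support %d..%d, tail mass %.2e, E[N] = %s\n",
              min(x$support), max(x$support), x$tail_mass,
              ifelse(is.finite(x$mean_total), sprintf("%.3f", x$mean_total), "Inf")))
  invisible(x)
}

#' @rdname predictive_missed
#' @param x A `count_predictive` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.count_predictive <- function(x, ...) {
  tibble::tibble(n_true = x$support, probability = x$pmf)
}

#' Sample true counts by composition
#'
#' Draws `theta` from the beta posterior, then the missed count from the
#' negative binomial with size `n_obs + 1` and success probability
#' `theta`, and returns `N = n_obs + n_mis`.
#'
#' @inheritParams predictive_missed
#' @param n_draws Number of draws.
#' @param seed Integer seed.
#' @return Integer vector of `n_draws` sampled true counts.
#' @export
sample_total <- function(n_obs, posterior, n_draws, seed = 1L) {
  n_obs <- check_count(n_obs, "n_obs", min = 0L)
  n_draws <- check_count(n_draws, "n_draws")
  set.seed(check_count(seed, "seed", min = 0L))
  n_obs + sample_missed_(rep(n_obs, n_draws), posterior)[, 2]
}

# Vectorised composition sampler used internally (consumes the current
# RNG stream): one theta draw and one negative-binomial missed count per
# element of n_obs_vec. Returns cbind(theta, n_mis).
sample_missed_ <- function(n_obs_vec, posterior) {
  theta <- rbeta(length(n_obs_vec), posterior$alpha, posterior$beta)
  n_mis <- rnbinom(length(n_obs_vec), size = n_obs_vec + 1, prob = theta)
  cbind(theta, n_mis)
}
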