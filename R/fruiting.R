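#' Quasi-binomial GLM by iteratively reweighted least squares
#'
#' Fits a binomial-mean logistic regression of successes out of trials on
#' the columns of `design`, then estimates the dispersion `phi` from the
#' Pearson statistic, `phi = X^2 / (n - p)`, and inflates the standard
#' errors by `sqrt(phi)`. This is the quasi-likelihood treatment of
#' overdispersed proportion data: the point estimates are the binomial
#' MLE, only the uncertainty is rescaled.
#'
#' IRLS starts from the empirical logits with a `0.5 / (trials + 1)`
#' continuity correction and stops when the largest coefficient change
#' falls below `1e-10` or after 100 iterations. Complete separation
#' (fitted probabilities collapsing to 0/1 with diverging coefficients)
#' is flagged via `converged = FALSE` with a diagnostic message.
#'
#' @param successes,trials Integer vectors, `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param design Numeric design matrix with full column rank (include an
#'   intercept or group indicator columns yourself).
#' @return A `quasibinomial_fit` object with elements `coefficients`,
#'   `dispersion`, `standard_errors`, `fitted_probs`, `converged`,
#'   `n_iterations`, `df_residual`.
#' @export
fit_quasibinomial <- function(successes, trials, design) {
  design <- as.matrix(design)
  n <- length(successes)
  if (length(trials) != n || nrow(design) != n) {
    abort("successes, trials and design must have matching rows",
          class = "strawyield_validation_error")
  }
  check_nonneg(successes, "successes")
  if (any(trials < 1) || any(trials != floor(trials))) {
    abort_field("trials", "must be integers >= 1")
  }
  if (any(successes > trials)) {
    abort_field("successes", "must not exceed trials")
  }
  p <- ncol(design)
  if (qr(design)$rank < p) {
    abort_field("design", "must have full column rank")
  }

  y <- as.numeric(successes)
  nt <- as.numeric(trials)

  # empirical-logit start with continuity correction
  eta <- log((y + 0.5) / (nt - y + 0.5))
  beta_hat <- qr.coef(qr(design), eta)

  converged <- FALSE
  diagnostic <- NULL
  iter <- 0L
  for (iter in seq_len(100L)) {
    eta <- drop(design %*% beta_hat)
    mu <- plogis(eta)
    w <- nt * mu * (1 - mu)
    if (any(w < 1e-12)) {
      diagnostic <- "fitted probabilities collapsed to 0/1 (possible separation)"
      break
    }
    z <- eta + (y - nt * mu) / w
    sw <- sqrt(w)
    fit <- qr(design * sw)
    beta_new <- qr.coef(fit, z * sw)
    delta <- max(abs(beta_new - beta_hat))
    beta_hat <- beta_new
    if (!all(is.finite(beta_hat))) {
      diagnostic <- "coefficients diverged"
      break
    }
    if (delta < 1e-10) {
      converged <- TRUE
      break
    }
  }
  if (!converged && is.null(diagnostic)) {
    diagnostic <- "IRLS did not converge in 100 iterations"
  }

  eta <- drop(design %*% beta_hat)
  mu <- plogis(eta)
  pearson <- sum((y - nt * mu)^2 / (nt * mu * (1 - mu)))
  df_res <- n - p
  phi <- if (df_res > 0) pearson / df_res else NA_real_

  w <- nt * mu * (1 - mu)
  qrw <- qr(design * sqrt(w))
  ipw <- order(qrw$pivot)
  xtwx_inv <- chol2inv(qr.R(qrw))[ipw, ipw, drop = FALSE]
  se <- sqrt(pmax(phi, 0) * diag(xtwx_inv))

  cn <- colnames(design)
  if (is.null(cn)) cn <- paste0("x", seq_len(p))
  names(beta_hat) <- cn
  names(se) <- cn

  structure(
    list(coefficients = beta_hat, dispersion = phi, standard_errors = se,
         fitted_probs = mu, converged = converged, n_iterations = iter,
         df_residual = df_res, diagnostic = diagnostic, nobs = n),
    class = "quasibinomial_fit"
  )
}

#' @export
print.quasibinomial_fit <- function(x, ...) {
  cat(sprintf("Quasi-binomial fit: %d obs, dispersion phi = %.4f%s\n",
              x$nobs, x$dispersion,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(tidy.quasibinomial_fit(x))
  invisible(x)
}

#' @rdname fit_quasibinomial
#' @param x A `quasibinomial_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.quasibinomial_fit <- function(x, ...) {
  stat <- x$coefficients / x$standard_errors
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$standard_errors),
    statistic = unname(stat),
    p.value = 2 * pt(-abs(unname(stat)), df = x$df_residual)
  )
}

#' @rdname fit_quasibinomial
#' @exportS3Method generics::glance
glance.quasibinomial_fit <- function(x, ...) {
  tibble::tibble(dispersion = x$dispersion, converged = x$converged,
                 n_iterations = x$n_iterations,
                 df.residual = x$df_residual, nobs = x$nobs)
}

#' Cultivar fruiting probabilities with receptacle-count uncertainty
#'
#' Estimates, per cultivar, the probability `pi` that a receptacle yields
#' a harvested fruit, while propagating the uncertainty in each plant's
#' true receptacle total. The true total is unknown because the detector
#' misses receptacles; for each of `n_imputations` rounds a true total is
#' drawn per plant from its posterior predictive (via [sample_total()]'s
#' composition sampler), a per-cultivar-intercept quasi-binomial model of
#' season fruit totals on the imputed receptacle totals is fitted, and
#' each cultivar's fitted `pi` is recorded. The spread of the recorded
#' draws is the reported uncertainty.
#'
#' When a plant's season fruit total exceeds its imputed receptacle total
#' the draw is raised to the fruit total (a fruit proves its receptacle
#' existed); the number of raised draws is reported in attribute
#' `n_clipped`. Plants whose imputed total is zero are dropped from that
#' round's fit; a cultivar losing all its plants in a round records `NA`
#' for that round and is flagged.
#'
#' @param trial Trial tibble with `detected_receptacles_new` filled in.
#' @param theta_posterior A [beta_posterior()] for the detection proportion.
#' @param n_imputations Number of imputation rounds (>= 1).
#' @param seed Integer seed.
#' @param separate_fits Fit each cultivar separately instead of one
#'   per-cultivar-intercept model (same point estimates; per-cultivar
#'   rather than pooled dispersion).
#' @return A `fruiting_estimates` tibble, one row per cultivar, with
#'   `pi_point` (inverse logit of the mean logit draw), draw quantiles,
#'   and logit-scale summaries. Attributes: `draws` (matrix imputations x
#'   cultivars), `dispersion` (phi per round), `n_clipped`.
#' @export
estimate_pi_per_cultivar <- function(trial, theta_posterior, n_imputations = 200L,
                                     seed = 1L, separate_fits = FALSE) {
  check_columns(trial, c("plant_id", "cultivar", "detected_receptacles_new",
                         "fruits_new"), "trial")
  if (anyNA(trial$detected_receptacles_new)) {
    abort("trial has no detected counts; run simulate_detections() first",
          class = "strawyield_validation_error")
  }
  n_imputations <- check_count(n_imputations, "n_imputations")

  plants <- trial |>
    dplyr::group_by(.data$plant_id, .data$cultivar) |>
    dplyr::summarise(n_obs = sum(.data$detected_receptacles_new),
                     fruits = sum(.data$fruits_new), .groups = "drop")
  cultivars <- sort(unique(plants$cultivar))
  k <- length(cultivars)

  set.seed(check_count(seed, "seed", min = 0L))
  draws <- matrix(NA_real_, n_imputations, k, dimnames = list(NULL, cultivars))
  phis <- rep(NA_real_, n_imputations)
  n_clipped <- 0L
  dropped_flag <- rep(FALSE, k)

  for (t in seq_len(n_imputations)) {
    n_true <- plants$n_obs + sample_missed_(plants$n_obs, theta_posterior)[, 2]
    clip <- plants$fruits > n_true
    n_clipped <- n_clipped + sum(clip)
    n_true[clip] <- plants$fruits[clip]

    keep <- n_true > 0
    cultivar_f <- factor(plants$cultivar[keep], levels = cultivars)
    present <- levels(droplevels(cultivar_f))
    dropped_flag <- dropped_flag | !(cultivars %in% present)

    if (separate_fits) {
      for (cv in present) {
        i <- keep & plants$cultivar == cv
        f <- fit_quasibinomial(plants$fruits[i], n_true[i],
                               matrix(1, sum(i), 1, dimnames = list(NULL, cv)))
        draws[t, cv] <- plogis(f$coefficients[[1]])
      }
    } else {
      design <- model.matrix(~ 0 + cultivar_f)
      colnames(design) <- levels(cultivar_f)
      design <- design[, present, drop = FALSE]
      f <- fit_quasibinomial(plants$fruits[keep], n_true[keep], design)
      draws[t, present] <- plogis(f$coefficients[present])
      phis[t] <- f$dispersion
    }
  }

  if (any(dropped_flag)) {
    warn(sprintf("cultivar(s) %s had zero imputed receptacles in some rounds and were excluded there",
                 paste(cultivars[dropped_flag], collapse = ", ")))
  }

  logit_draws <- log(draws / (1 - draws))
  qs <- function(m, p) apply(m, 2, quantile, probs = p, na.rm = TRUE)
  out <- tibble::tibble(
    cultivar = cultivars,
    pi_point = unname(plogis(colMeans(logit_draws, na.rm = TRUE))),
    pi_mean = unname(colMeans(draws, na.rm = TRUE)),
    pi_q025 = unname(qs(draws, 0.025)),
    pi_q25 = unname(qs(draws, 0.25)),
    pi_q50 = unname(qs(draws, 0.50)),
    pi_q75 = unname(qs(draws, 0.75)),
    pi_q975 = unname(qs(draws, 0.975)),
    logit_mean = unname(colMeans(logit_draws, na.rm = TRUE)),
    logit_sd = unname(apply(logit_draws, 2, sd, na.rm = TRUE))
  )
  class(out) <- c("fruiting_estimates", class(out))
  attr(out, "draws") <- draws
  attr(out, "dispersion") <- phis
  attr(out, "n_clipped") <- n_clipped
  out
}

#' @rdname estimate_pi_per_cultivar
#' @param object A `fruiting_estimates` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.fruiting_estimates <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cultivar, y = .data$pi_point)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$pi_q025, ymax = .data$pi_q975)) +
    ggplot2::labs(x = "Cultivar",
                  y = "Fruiting probability per receptacle (95% imputation interval)") +
    ggplot2::ylim(0, 1)
}
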