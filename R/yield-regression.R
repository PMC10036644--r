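#' Per-week rate of change of a weekly series
#'
#' The slope of the ordinary least-squares line of the weekly values on
#' the week index: a one-number summary of how fast the average count is
#' growing over the window.
#'
#' @param values Numeric weekly values (at least two).
#' @param weeks Week indices, default `seq_along(values)`.
#' @return Slope per week.
#' @export
rate_of_change <- function(values, weeks = seq_along(values)) {
  if (length(values) < 2L || length(weeks) != length(values)) {
    abort_field("values", "need at least two weekly values with matching week indices")
  }
  sxx <- sum((weeks - mean(weeks))^2)
  if (sxx == 0) abort_field("weeks", "week indices have no spread")
  sum((weeks - mean(weeks)) * (values - mean(values))) / sxx
}

#' Build the regression feature table
#'
#' One row per plant with: cultivar indicator columns (the
#' alphabetically first cultivar is the reference level and carries no
#' column), `frt` and `rec` — the per-week rates of change of the
#' cumulative fruit count and cumulative detected-receptacle count over
#' the first `window_weeks` weeks — `logit_prob`, and the end-of-season
#' `response` (cumulative fruits at the final week).
#'
#' `logit_prob` is by default the plant-level fruiting probability on the
#' count-corrected scale,
#' `logit((fruits_i + pi_c) / (E[N_i | n_obs_i] + 1))`, where `pi_c` is
#' the cultivar estimate acting as a one-observation pseudo-count and
#' `E[N_i | n_obs_i]` is the posterior-predictive mean of the plant's
#' true receptacle total. A plant fruiting exactly at its cultivar's
#' rate gets `logit(pi_c)`. This per-unit definition is what keeps the
#' M3/M4 designs identifiable: a cultivar-constant probability column
#' would be exactly collinear with the cultivar indicators.
#' `prob_level = "cultivar"` gives the cultivar-level
#' `logit(pi_point)` instead, for model formulas without cultivar terms.
#'
#' @param trial Trial tibble with detected counts filled in.
#' @param fruiting A [estimate_pi_per_cultivar()] result (or any tibble
#'   with `cultivar` and `pi_point`).
#' @param theta_posterior A [beta_posterior()] for the detection
#'   proportion; required for `prob_level = "plant"`.
#' @param window_weeks Number of initial weeks in the predictor window.
#' @param prob_level `"plant"` (default) or `"cultivar"`; see Details.
#' @return A tibble with columns `unit_id`, `cultivar`, one indicator per
#'   non-reference cultivar, `frt`, `rec`, `logit_prob`, `response`.
#' @export
build_feature_table <- function(trial, fruiting, theta_posterior = NULL,
                                window_weeks = 4L,
                                prob_level = c("plant", "cultivar")) {
  prob_level <- match.arg(prob_level)
  check_columns(trial, c("plant_id", "cultivar", "week",
                         "detected_receptacles_new", "fruits_new",
                         "cumulative_fruits"), "trial")
  check_columns(fruiting, c("cultivar", "pi_point"), "fruiting")
  window_weeks <- check_count(window_weeks, "window_weeks", min = 2L)
  if (window_weeks > max(trial$week)) {
    abort_field("window_weeks", "extends beyond the observed weeks")
  }
  missing_pi <- setdiff(unique(trial$cultivar), fruiting$cultivar)
  if (length(missing_pi)) {
    abort(sprintf("no fruiting estimate for cultivar(s): %s",
                  paste(missing_pi, collapse = ", ")),
          class = "strawyield_validation_error")
  }
  if (prob_level == "plant") {
    if (!inherits(theta_posterior, "beta_posterior")) {
      abort_field("theta_posterior",
                  "a beta_posterior is required for plant-level logit_prob")
    }
    if (theta_posterior$alpha <= 1) {
      abort_field("theta_posterior",
                  "alpha must exceed 1 for a finite predictive mean count")
    }
  }

  per_plant <- trial |>
    dplyr::group_by(.data$plant_id, .data$cultivar) |>
    dplyr::arrange(.data$week, .by_group = TRUE) |>
    dplyr::summarise(
      frt = rate_of_change(.data$cumulative_fruits[seq_len(window_weeks)]),
      rec = rate_of_change(cumsum(.data$detected_receptacles_new)[seq_len(window_weeks)]),
      n_obs = sum(.data$detected_receptacles_new),
      fruits = sum(.data$fruits_new),
      response = .data$cumulative_fruits[dplyr::n()],
      .groups = "drop"
    )

  cultivars <- sort(unique(per_plant$cultivar))
  pi_map <- stats::setNames(fruiting$pi_point, fruiting$cultivar)

  lp <- if (prob_level == "cultivar") {
    logit(pi_map[per_plant$cultivar])
  } else {
    n_hat <- per_plant$n_obs + (per_plant$n_obs + 1) *
      theta_posterior$beta / (theta_posterior$alpha - 1)
    # a fruit proves its receptacle existed
    n_hat <- pmax(n_hat, per_plant$fruits)
    logit((per_plant$fruits + pi_map[per_plant$cultivar]) / (n_hat + 1))
  }

  out <- per_plant |>
    dplyr::transmute(
      unit_id = .data$plant_id,
      cultivar = .data$cultivar,
      frt = .data$frt,
      rec = .data$rec,
      logit_prob = unname(lp),
      response = as.numeric(.data$response)
    )
  for (cv in cultivars[-1]) {
    out[[cv]] <- as.integer(out$cultivar == cv)
  }
  dplyr::relocate(out, dplyr::all_of(cultivars[-1]), .after = "cultivar")
}

# Design matrix for one of the four candidate models. Term naming follows
# the comparison table: Intercept, cultivar indicators, frt, logit(prob),
# rec, rec x logit(prob).
model_design <- function(features, model_label) {
  dummy_cols <- setdiff(names(features),
                        c("unit_id", "cultivar", "frt", "rec", "logit_prob",
                          "response"))
  base <- cbind(`(Intercept)` = 1,
                as.matrix(features[, dummy_cols, drop = FALSE]))
  extra <- switch(model_label,
    M1 = NULL,
    M2 = cbind(frt = features$frt),
    M3 = cbind(`logit(prob)` = features$logit_prob, rec = features$rec),
    M4 = cbind(`logit(prob)` = features$logit_prob, rec = features$rec,
               `rec:logit(prob)` = features$rec * features$logit_prob),
    abort_field("model_label", "must be one of M1, M2, M3, M4")
  )
  if (is.null(extra)) base else cbind(base, extra)
}

#' Ordinary least squares fit of one candidate yield model
#'
#' The four candidate models of end-of-season fruits per plant are:
#' M1 cultivar only; M2 cultivar + `frt`; M3 cultivar + `logit(prob)` +
#' `rec`; M4 adds the `rec x logit(prob)` interaction. Coefficient
#' standard errors use `sigma^2 (X'X)^{-1}` with
#' `sigma^2 = RSS / (n - p)`; two-sided p-values use the Student-t with
#' `n - p` degrees of freedom. AIC is the full Gaussian log-likelihood
#' convention (including the `2*pi` constant, counting `sigma^2` as a
#' parameter), matching mainstream statistical software; a perfect fit
#' (RSS = 0) reports `AIC = -Inf`.
#'
#' @param features Tibble from [build_feature_table()].
#' @param model_label One of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @return A `yield_ols` object.
#' @export
fit_ols <- function(features, model_label) {
  X <- model_design(features, model_label)
  y <- features$response
  n <- nrow(X); p <- ncol(X)
  if (n <= p) abort_field("features", "need more rows than model terms")
  qrX <- qr(X)
  if (qrX$rank < p) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    abort(sprintf("rank-deficient design; collinear term(s): %s",
                  paste(colnames(X)[-keep], collapse = ", ")),
          class = "strawyield_validation_error")
  }
  coefs <- qr.coef(qrX, y)
  fitted <- drop(X %*% coefs)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - p)
  ip <- order(qrX$pivot)
  xtx_inv <- chol2inv(qr.R(qrX))[ip, ip, drop = FALSE]
  se <- stats::setNames(sqrt(sigma2 * diag(xtx_inv)), colnames(X))
  tval <- coefs / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  r2 <- 1 - rss / tss
  # RSS at rounding-noise level: the Gaussian log-likelihood diverges
  perfect <- rss <= 1e-12 * max(tss, 1)
  aic <- if (!perfect) n * (log(2 * pi * rss / n) + 1) + 2 * (p + 1) else -Inf
  Q <- qr.Q(qrX)
  structure(
    list(model_label = model_label, terms = colnames(X),
         coefficients = coefs, standard_errors = se,
         t_values = tval, p_values = pval,
         rss = rss, aic = aic, r2 = r2,
         adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p),
         n = n, p_terms = p,
         fitted = fitted, residuals = resid,
         hat = rowSums(Q^2), X = X, y = y),
    class = "yield_ols"
  )
}

#' @export
print.yield_ols <- function(x, ...) {
  cat(sprintf("%s: n = %d, AIC = %.1f, adj-R2 = %.3f\n",
              x$model_label, x$n, x$aic, x$adj_r2))
  print(tidy.yield_ols(x))
  invisible(x)
}

#' @rdname fit_ols
#' @param x A `yield_ols` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.yield_ols <- function(x, ...) {
  tibble::tibble(term = x$terms,
                 estimate = unname(x$coefficients),
                 std.error = unname(x$standard_errors),
                 statistic = unname(x$t_values),
                 p.value = unname(x$p_values))
}

#' @rdname fit_ols
#' @exportS3Method generics::glance
glance.yield_ols <- function(x, ...) {
  tibble::tibble(model = x$model_label, r.squared = x$r2,
                 adj.r.squared = x$adj_r2, AIC = x$aic, rss = x$rss,
                 nobs = x$n, df = x$p_terms)
}

#' Leave-one-out cross-validated mean squared error
#'
#' Each unit is predicted from the model refitted without it. The value
#' is computed twice: by the hat-matrix shortcut
#' `mean((e_i / (1 - h_ii))^2)` and by explicit refits; the two must
#' agree within `1e-8` (an internal consistency check) and the shortcut
#' value is returned.
#'
#' @inheritParams fit_ols
#' @return The LOOCV mean squared prediction error.
#' @export
loocv_mse <- function(features, model_label) {
  fit <- fit_ols(features, model_label)
  if (any(fit$hat >= 1 - 1e-12)) {
    abort("a unit has leverage 1; its deleted residual is undefined",
          class = "strawyield_error")
  }
  shortcut <- mean((fit$residuals / (1 - fit$hat))^2)
  explicit <- mean(vapply(seq_len(fit$n), function(i) {
    b <- qr.coef(qr(fit$X[-i, , drop = FALSE]), fit$y[-i])
    (fit$y[i] - sum(fit$X[i, ] * b))^2
  }, numeric(1)))
  if (abs(shortcut - explicit) > 1e-8 * max(1, shortcut)) {
    abort("internal error: hat-matrix LOOCV disagrees with explicit refits",
          class = "strawyield_error")
  }
  shortcut
}

#' Compare the four candidate yield models
#'
#' Fits M1-M4, computes each model's AIC, adjusted R-squared and LOOCV
#' mean squared error, and names the best model by minimum LOOCV MSE.
#'
#' @inheritParams fit_ols
#' @return A `model_comparison` object: list with `fits` (named list of
#'   [fit_ols()] results), `comparison` (one row per model), and
#'   `best_model`.
#' @export
compare_models <- function(features) {
  labels <- c("M1", "M2", "M3", "M4")
  fits <- lapply(labels, function(l) fit_ols(features, l))
  names(fits) <- labels
  mse <- vapply(labels, function(l) loocv_mse(features, l), numeric(1))
  comparison <- tibble::tibble(
    model = labels,
    n_terms = vapply(fits, function(f) f$p_terms, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    adj_r2 = vapply(fits, function(f) f$adj_r2, numeric(1)),
    loocv_mse = unname(mse)
  )
  structure(
    list(fits = fits, comparison = comparison,
         best_model = labels[which.min(mse)], criterion = "loocv_mse"),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Yield model comparison (best by LOOCV MSE:", x$best_model, ")\n")
  print(x$comparison)
  invisible(x)
}

#' @rdname compare_models
#' @param x A `model_comparison` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.model_comparison <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    dplyr::mutate(tidy.yield_ols(f), model = f$model_label, .before = 1)
  })
}

#' @rdname compare_models
#' @exportS3Method generics::glance
glance.model_comparison <- function(x, ...) {
  x$comparison
}

#' @rdname compare_models
#' @param object A `model_comparison` object.
#' @exportS3Method ggplot2::autoplot
autoplot.model_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object$comparison,
                              cols = c("aic", "adj_r2", "loocv_mse"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_col(fill = "#2c3e50") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}
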