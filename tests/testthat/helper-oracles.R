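# Independent oracles used across the suite. Deliberately naive: scalar
# loops and direct definitions, sharing no code with the package internals.

# Beta-negative-binomial pmf by adaptive quadrature of the binomial-beta
# integrand over theta.
oracle_bnb_pmf <- function(m, n_obs, alpha, beta) {
  vapply(m, function(mm) {
    choose(n_obs + mm, mm) * stats::integrate(
      function(th) th^(n_obs + 1) * (1 - th)^mm * stats::dbeta(th, alpha, beta),
      0, 1, rel.tol = 1e-12, abs.tol = 1e-14
    )$value
  }, numeric(1))
}

# Brute-force average precision: loop-based greedy matching per image in
# descending score order, then the 101-point rule evaluated as a literal
# max over the points at or beyond each recall grid value.
oracle_ap <- function(gt, pred, thr) {
  if (nrow(pred) == 0L) return(0)
  if (nrow(gt) == 0L) return(0)
  ord <- order(-pred$score)
  is_tp <- logical(nrow(pred))
  matched <- logical(nrow(gt))
  for (j in ord) {
    g_idx <- which(gt$image_id == pred$image_id[j] & !matched)
    best <- 0; best_i <- NA
    for (i in g_idx) {
      v <- iou(gt[i, ], pred[j, ])
      if (v >= thr && v > best) { best <- v; best_i <- i }
    }
    if (!is.na(best_i)) { matched[best_i] <- TRUE; is_tp[j] <- TRUE }
  }
  tp <- cumsum(is_tp[ord])
  fp <- cumsum(!is_tp[ord])
  recall <- tp / nrow(gt)
  precision <- tp / (tp + fp)
  grid <- seq(0, 1, by = 0.01)
  mean(vapply(grid, function(r) {
    ok <- recall >= r
    if (any(ok)) max(precision[ok]) else 0
  }, numeric(1)))
}

oracle_map <- function(gt, pred) {
  mean(vapply(seq(0.50, 0.95, by = 0.05),
              function(t) oracle_ap(gt, pred, t), numeric(1)))
}

# Random small box fixtures for oracle-equivalence checks.
random_box_fixture <- function(n_images = 2, max_boxes = 5) {
  make_boxes <- function(n, scores = FALSE) {
    x <- runif(n, 0, 80); y <- runif(n, 0, 80)
    w <- runif(n, 5, 30); h <- runif(n, 5, 30)
    out <- tibble::tibble(
      image_id = sample.int(n_images, n, replace = TRUE),
      x_min = x, y_min = y, x_max = x + w, y_max = y + h
    )
    if (scores) out$score <- runif(n)
    out
  }
  n_gt <- sample.int(max_boxes, 1)
  gt <- make_boxes(n_gt)
  # predictions: jittered copies of some gt boxes plus spurious ones
  n_copy <- sample.int(n_gt, 1)
  copies <- gt[sample.int(n_gt, n_copy), ]
  copies$x_min <- copies$x_min + runif(n_copy, -6, 6)
  copies$x_max <- copies$x_max + runif(n_copy, -6, 6)
  copies$y_min <- copies$y_min + runif(n_copy, -6, 6)
  copies$y_max <- copies$y_max + runif(n_copy, -6, 6)
  bad <- copies$x_max <= copies$x_min | copies$y_max <= copies$y_min
  copies <- copies[!bad, ]
  spurious <- make_boxes(sample.int(3, 1))
  pred <- dplyr::bind_rows(copies, spurious)
  pred$score <- runif(nrow(pred))
  list(gt = gt, pred = pred)
}

# Synthetic feature tables with a known generating model, for
# model-selection simulations. Cultivar effects, rec and logit_prob vary
# per unit; `interaction` is the coefficient on rec * logit_prob.
make_features_from_truth <- function(n_per_cultivar = 5,
                                     cultivar_effects = c(A = 14, J = 17, K = 22,
                                                          M = 18, S = 25),
                                     b_rec = 0, b_prob = 0, interaction = 0,
                                     b_frt = 0, sigma = 3) {
  cultivars <- names(cultivar_effects)
  n <- n_per_cultivar * length(cultivars)
  cultivar <- rep(cultivars, each = n_per_cultivar)
  rec <- runif(n, 1, 4)
  logit_prob <- rnorm(n, 0, 0.8)
  frt <- 0.4 * rec + rnorm(n, 0, 0.3)
  response <- cultivar_effects[cultivar] + b_rec * rec + b_prob * logit_prob +
    interaction * rec * logit_prob + b_frt * frt + rnorm(n, 0, sigma)
  out <- tibble::tibble(
    unit_id = sprintf("%s_%02d", cultivar, rep(seq_len(n_per_cultivar),
                                               times = length(cultivars))),
    cultivar = cultivar, frt = frt, rec = rec, logit_prob = logit_prob,
    response = unname(response)
  )
  for (cv in cultivars[-1]) out[[cv]] <- as.integer(out$cultivar == cv)
  dplyr::relocate(out, dplyr::all_of(cultivars[-1]), .after = "cultivar")
}

# A small fully detected, exactly-half-fruiting trial used in
# no-uncertainty limit checks.
tiny_perfect_trial <- function() {
  cfg <- sim_config(n_cultivars = 2, cultivar_labels = c("A", "B"),
                    n_plants_per_cultivar = 3, n_weeks = 6,
                    receptacle_rate_per_week = c(4, 4),
                    fruiting_prob = c(0.5, 0.5),
                    fruiting_overdispersion = 0, detection_prob = 1,
                    fruit_lag = 2, seed = 11)
  trial <- simulate_trial(cfg)
  # even cohorts, each yielding exactly half its receptacles as fruit
  trial$true_receptacles_new <- 2L * (trial$true_receptacles_new %/% 2L)
  trial$fruits_new <- 0L
  lag <- 2L
  for (pid in unique(trial$plant_id)) {
    idx <- which(trial$plant_id == pid)
    rec <- trial$true_receptacles_new[idx]
    for (w in seq_along(rec)) {
      if (w + lag <= length(idx)) {
        trial$fruits_new[idx[w + lag]] <- rec[w] %/% 2L
      }
    }
    trial$cumulative_fruits[idx] <- cumsum(trial$fruits_new[idx])
  }
  trial$detected_receptacles_new <- trial$true_receptacles_new
  trial
}
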