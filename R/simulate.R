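#' Configuration for a synthetic greenhouse trial
#'
#' Describes a multi-cultivar strawberry trial in which flower receptacles
#' emerge weekly on each plant, each receptacle either ripens into a
#' harvested fruit or not, and a camera+detector observes only a fraction
#' of the receptacles. The defaults emulate a two-row greenhouse trial of
#' five cultivars with five replicate plants each, observed weekly over a
#' 15-week harvest season.
#'
#' Fruiting is overdispersed across plants: each plant draws its own
#' fruiting probability from a beta distribution with mean `fruiting_prob`
#' (per cultivar) and intra-plant outcome correlation
#' `fruiting_overdispersion` (`rho = 0` collapses to pure binomial
#' fruiting). Receptacles emerge during the first `n_weeks - fruit_lag`
#' weeks and each fruiting receptacle is harvested `fruit_lag` weeks after
#' emergence, so every receptacle resolves within the season.
#'
#' @param n_cultivars Number of cultivars.
#' @param cultivar_labels Character labels, one per cultivar.
#' @param n_plants_per_cultivar Replicate plants per cultivar.
#' @param n_weeks Observation weeks in the season.
#' @param receptacle_rate_per_week Mean new receptacles per plant per
#'   emergence week, one value per cultivar.
#' @param fruiting_prob Probability that a receptacle yields a harvested
#'   fruit, one value per cultivar.
#' @param fruiting_overdispersion Intra-plant correlation `rho` in `[0, 1)`
#'   of fruiting outcomes (beta-binomial across plants).
#' @param detection_prob Probability `theta` that a receptacle is captured
#'   and detected in the weekly image.
#' @param false_positive_rate Mean spurious detections per plant per week
#'   (additive Poisson noise, e.g. a bee mistaken for a receptacle).
#' @param fruit_lag Weeks from receptacle emergence to harvest.
#' @param seed Integer seed making the simulation reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cultivars = 5L,
                       cultivar_labels = c("A", "J", "K", "M", "S"),
                       n_plants_per_cultivar = 5L,
                       n_weeks = 15L,
                       receptacle_rate_per_week = c(3, 2.5, 3.5, 2, 3),
                       fruiting_prob = c(0.30, 0.45, 0.55, 0.65, 0.80),
                       fruiting_overdispersion = 0.05,
                       detection_prob = 0.686,
                       false_positive_rate = 0,
                       fruit_lag = 2L,
                       seed = 1L) {
  cfg <- structure(
    list(
      n_cultivars = check_count(n_cultivars, "n_cultivars"),
      cultivar_labels = as.character(cultivar_labels),
      n_plants_per_cultivar = check_count(n_plants_per_cultivar, "n_plants_per_cultivar"),
      n_weeks = check_count(n_weeks, "n_weeks"),
      receptacle_rate_per_week = receptacle_rate_per_week,
      fruiting_prob = fruiting_prob,
      fruiting_overdispersion = fruiting_overdispersion,
      detection_prob = detection_prob,
      false_positive_rate = false_positive_rate,
      fruit_lag = check_count(fruit_lag, "fruit_lag", min = 0L),
      seed = check_count(seed, "seed", min = 0L)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config A `sim_config` object.
#' @export
validate_sim_config <- function(config) {
  k <- config$n_cultivars
  if (length(config$cultivar_labels) != k || anyDuplicated(config$cultivar_labels)) {
    abort_field("cultivar_labels", sprintf("must be %d distinct labels", k))
  }
  check_nonneg(config$receptacle_rate_per_week, "receptacle_rate_per_week", len = k)
  check_prob(config$fruiting_prob, "fruiting_prob", len = k)
  check_prob(config$fruiting_overdispersion, "fruiting_overdispersion", len = 1L)
  if (config$fruiting_overdispersion >= 1) {
    abort_field("fruiting_overdispersion", "must be < 1")
  }
  check_prob(config$detection_prob, "detection_prob", len = 1L)
  check_nonneg(config$false_positive_rate, "false_positive_rate", len = 1L)
  if (config$fruit_lag >= config$n_weeks) {
    abort_field("fruit_lag", "must be smaller than n_weeks")
  }
  invisible(config)
}

# Plant-level fruiting probability: beta with mean pi and correlation rho.
plant_fruiting_probs <- function(n, pi, rho) {
  if (rho == 0 || pi == 0 || pi == 1) {
    return(rep(pi, n))
  }
  shape <- (1 - rho) / rho
  rbeta(n, pi * shape, (1 - pi) * shape)
}

#' Simulate a greenhouse trial
#'
#' Generates one row per plant per week with the true number of newly
#' emerged receptacles, the number of newly harvested fruits, and the
#' running cumulative fruit count. New receptacles are Poisson with the
#' cultivar's weekly rate during the emergence phase; each receptacle
#' independently becomes a fruit with the plant's fruiting probability and
#' is harvested `fruit_lag` weeks after emergence. Detected counts are
#' left `NA`; fill them with [simulate_detections()].
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `plant_id`, `cultivar`, `week`,
#'   `true_receptacles_new`, `detected_receptacles_new`, `fruits_new`,
#'   `cumulative_fruits`.
#' @export
simulate_trial <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  n_plants <- config$n_cultivars * config$n_plants_per_cultivar
  cultivar <- rep(config$cultivar_labels, each = config$n_plants_per_cultivar)
  plant_id <- sprintf("%s_%02d", cultivar,
                      rep(seq_len(config$n_plants_per_cultivar), times = config$n_cultivars))
  rate <- rep(config$receptacle_rate_per_week, each = config$n_plants_per_cultivar)
  pvec <- unlist(lapply(seq_len(config$n_cultivars), function(i) {
    plant_fruiting_probs(config$n_plants_per_cultivar,
                         config$fruiting_prob[i],
                         config$fruiting_overdispersion)
  }))

  n_weeks <- config$n_weeks
  emerge_weeks <- seq_len(n_weeks - config$fruit_lag)

  # plants x weeks matrices; receptacle cohorts resolve fruit_lag weeks later
  rec_new <- matrix(0L, n_plants, n_weeks)
  frt_new <- matrix(0L, n_plants, n_weeks)
  for (w in emerge_weeks) {
    new_r <- rpois(n_plants, rate)
    rec_new[, w] <- new_r
    frt_new[, w + config$fruit_lag] <- rbinom(n_plants, new_r, pvec)
  }

  tibble::tibble(
    plant_id = rep(plant_id, each = n_weeks),
    cultivar = rep(cultivar, each = n_weeks),
    week = rep(seq_len(n_weeks), times = n_plants),
    true_receptacles_new = as.integer(t(rec_new)),
    detected_receptacles_new = NA_integer_,
    fruits_new = as.integer(t(frt_new))
  ) |>
    dplyr::group_by(.data$plant_id) |>
    dplyr::mutate(cumulative_fruits = cumsum(.data$fruits_new)) |>
    dplyr::ungroup()
}

#' Overlay imperfect detection on a simulated trial
#'
#' Each week's detected count is a binomial thinning of the true count
#' with detection probability `detection_prob`, plus Poisson false
#' positives at rate `false_positive_rate` per plant-week.
#'
#' @param trial Tibble from [simulate_trial()] (or with the same columns).
#' @param detection_prob Probability a receptacle is detected.
#' @param false_positive_rate Mean spurious detections per plant-week.
#' @param seed Integer seed.
#' @return `trial` with `detected_receptacles_new` filled in.
#' @export
simulate_detections <- function(trial, detection_prob, false_positive_rate = 0,
                                seed = 1L) {
  check_columns(trial, "true_receptacles_new", "trial")
  check_prob(detection_prob, "detection_prob", len = 1L)
  check_nonneg(false_positive_rate, "false_positive_rate", len = 1L)
  set.seed(check_count(seed, "seed", min = 0L))
  n <- nrow(trial)
  detected <- rbinom(n, trial$true_receptacles_new, detection_prob)
  if (false_positive_rate > 0) {
    detected <- detected + rpois(n, false_positive_rate)
  }
  dplyr::mutate(trial, detected_receptacles_new = as.integer(detected))
}

#' Draw a calibration sample of fully hand-counted plants
#'
#' Emulates selecting a few plants per cultivar and counting, for each,
#' how many receptacles the detector observed (`n_obs`) and how many it
#' missed (`n_mis`). By default the counts come from a single observation
#' week (the week of peak emergence across the trial); `mode =
#' "cumulative"` pools all weeks instead. With false positives present,
#' detected can exceed true and `n_mis` is clipped at zero; the number of
#' clipped plants is attached as attribute `n_clipped`.
#'
#' @param trial Trial tibble with detected counts filled in.
#' @param plants_per_cultivar Plants sampled (without replacement) per cultivar.
#' @param seed Integer seed for the sampling.
#' @param mode `"single_week"` (default) or `"cumulative"`.
#' @param week Observation week for `mode = "single_week"`; defaults to
#'   the week with the largest total true receptacle count.
#' @return Tibble with columns `plant_id`, `cultivar`, `n_obs`, `n_mis`.
#' @export
make_calibration_sample <- function(trial, plants_per_cultivar = 4L, seed = 1L,
                                    mode = c("single_week", "cumulative"),
                                    week = NULL) {
  mode <- match.arg(mode)
  check_columns(trial, c("plant_id", "cultivar", "week",
                         "true_receptacles_new", "detected_receptacles_new"),
                "trial")
  if (anyNA(trial$detected_receptacles_new)) {
    abort("trial has no detected counts; run simulate_detections() first",
          class = "strawyield_validation_error")
  }
  plants_per_cultivar <- check_count(plants_per_cultivar, "plants_per_cultivar")

  if (mode == "single_week") {
    if (is.null(week)) {
      totals <- tapply(trial$true_receptacles_new, trial$week, sum)
      week <- as.integer(names(totals)[which.max(totals)])
    }
    obs <- dplyr::filter(trial, .data$week == !!week)
    if (nrow(obs) == 0L) abort_field("week", "not present in the trial")
    per_plant <- obs |>
      dplyr::group_by(.data$plant_id, .data$cultivar) |>
      dplyr::summarise(true = sum(.data$true_receptacles_new),
                       det = sum(.data$detected_receptacles_new),
                       .groups = "drop")
  } else {
    per_plant <- trial |>
      dplyr::group_by(.data$plant_id, .data$cultivar) |>
      dplyr::summarise(true = sum(.data$true_receptacles_new),
                       det = sum(.data$detected_receptacles_new),
                       .groups = "drop")
  }

  avail <- table(per_plant$cultivar)
  if (any(avail < plants_per_cultivar)) {
    abort(sprintf("plants_per_cultivar = %d exceeds available plants for cultivar(s): %s",
                  plants_per_cultivar,
                  paste(names(avail)[avail < plants_per_cultivar], collapse = ", ")),
          class = "strawyield_validation_error")
  }

  set.seed(check_count(seed, "seed", min = 0L))
  sampled <- per_plant |>
    dplyr::group_by(.data$cultivar) |>
    dplyr::slice_sample(n = plants_per_cultivar) |>
    dplyr::ungroup()

  n_clipped <- sum(sampled$det > sampled$true)
  if (n_clipped > 0L) {
    inform(sprintf("n_mis clipped at 0 for %d plant(s) where detections exceeded truth",
                   n_clipped))
  }
  out <- tibble::tibble(
    plant_id = sampled$plant_id,
    cultivar = sampled$cultivar,
    n_obs = as.integer(sampled$det),
    n_mis = as.integer(pmax(sampled$true - sampled$det, 0L))
  )
  attr(out, "n_clipped") <- n_clipped
  attr(out, "week") <- if (mode == "single_week") week else NA_integer_
  out
}

#' Simulate paired ground-truth and predicted bounding boxes
#'
#' Builds geometric fixtures for the detection metrics: ground-truth boxes
#' placed uniformly on a 1000 x 1000 canvas, and predictions that are
#' jittered copies carrying confidence scores, with a fraction deleted
#' (missed detections) and optional spurious boxes added per image.
#'
#' @param n_images Number of images.
#' @param boxes_per_image Ground-truth boxes per image.
#' @param jitter Standard deviation (pixels) of Gaussian noise added to
#'   each predicted box corner; 0 gives exact copies.
#' @param miss_rate Probability a ground-truth box has no prediction.
#' @param false_positive_rate Mean spurious predicted boxes per image.
#' @param seed Integer seed.
#' @return List with tibbles `ground_truth` (no `score`) and
#'   `predictions` (with `score`), columns `image_id`, `x_min`, `y_min`,
#'   `x_max`, `y_max`.
#' @export
simulate_box_pairs <- function(n_images, boxes_per_image, jitter = 0,
                               miss_rate = 0, false_positive_rate = 0,
                               seed = 1L) {
  n_images <- check_count(n_images, "n_images")
  boxes_per_image <- check_count(boxes_per_image, "boxes_per_image")
  check_nonneg(jitter, "jitter", len = 1L)
  check_prob(miss_rate, "miss_rate", len = 1L)
  check_nonneg(false_positive_rate, "false_positive_rate", len = 1L)
  set.seed(check_count(seed, "seed", min = 0L))

  canvas <- 1000
  n_gt <- n_images * boxes_per_image
  w <- runif(n_gt, 40, 120)
  h <- runif(n_gt, 40, 120)
  x <- runif(n_gt, 0, canvas - w)
  y <- runif(n_gt, 0, canvas - h)
  gt <- tibble::tibble(
    image_id = rep(seq_len(n_images), each = boxes_per_image),
    x_min = x, y_min = y, x_max = x + w, y_max = y + h
  )

  keep <- runif(n_gt) >= miss_rate
  pred <- gt[keep, , drop = FALSE]
  n_pred <- nrow(pred)
  if (n_pred > 0L && jitter > 0) {
    pred$x_min <- pred$x_min + rnorm(n_pred, 0, jitter)
    pred$y_min <- pred$y_min + rnorm(n_pred, 0, jitter)
    pred$x_max <- pmax(pred$x_max + rnorm(n_pred, 0, jitter), pred$x_min + 1)
    pred$y_max <- pmax(pred$y_max + rnorm(n_pred, 0, jitter), pred$y_min + 1)
  }
  pred$score <- if (n_pred > 0L) runif(n_pred, 0.5, 1) else numeric(0)

  if (false_positive_rate > 0) {
    n_fp_img <- rpois(n_images, false_positive_rate)
    n_fp <- sum(n_fp_img)
    if (n_fp > 0L) {
      wf <- runif(n_fp, 40, 120); hf <- runif(n_fp, 40, 120)
      xf <- runif(n_fp, 0, canvas - wf); yf <- runif(n_fp, 0, canvas - hf)
      fp <- tibble::tibble(
        image_id = rep(seq_len(n_images), times = n_fp_img),
        x_min = xf, y_min = yf, x_max = xf + wf, y_max = yf + hf,
        score = runif(n_fp, 0, 1)
      )
      pred <- dplyr::bind_rows(pred, fp)
    }
  }
  list(ground_truth = gt, predictions = tibble::as_tibble(pred))
}
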