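#' Configuration of the full analysis pipeline
#'
#' Bundles the trial simulation settings with the analysis settings the
#' field protocol fixes: 4 hand-counted plants per cultivar for the
#' detection calibration and a 4-week predictor window.
#'
#' @param simulation A [sim_config()].
#' @param calibration_plants_per_cultivar Plants hand-counted per cultivar.
#' @param window_weeks Initial weeks used to build `frt`/`rec`.
#' @param n_imputations Imputation rounds for the fruiting probabilities.
#' @param tolerance Tail tolerance of the count posterior predictive.
#' @param eval_boxes Also simulate box pairs and write a detection
#'   evaluation report.
#' @param seed Global integer seed, expanded into per-stage child seeds.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            calibration_plants_per_cultivar = 4L,
                            window_weeks = 4L,
                            n_imputations = 200L,
                            tolerance = 1e-8,
                            eval_boxes = FALSE,
                            seed = 1L) {
  structure(
    list(simulation = validate_sim_config(simulation),
         calibration_plants_per_cultivar =
           check_count(calibration_plants_per_cultivar, "calibration_plants_per_cultivar"),
         window_weeks = check_count(window_weeks, "window_weeks", min = 2L),
         n_imputations = check_count(n_imputations, "n_imputations"),
         tolerance = tolerance,
         eval_boxes = isTRUE(eval_boxes),
         seed = check_count(seed, "seed", min = 0L)),
    class = "pipeline_config"
  )
}

stage_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(2147483646L, 6L),
                  c("trial", "detections", "calibration", "fruiting",
                    "boxes", "spare"))
}

#' Run the yield-prediction pipeline end to end
#'
#' Simulate a trial, overlay imperfect detection, calibrate the detection
#' proportion on a hand-counted subsample, estimate per-cultivar fruiting
#' probabilities under receptacle-count imputation, build the regression
#' features from the early-season window, and compare the four yield
#' models. Every artifact is written to `outdir` as CSV/JSON together
#' with a manifest recording the configuration, the per-stage seeds and
#' md5 checksums, so an identical seed reproduces byte-identical files.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory artifacts: `trial`,
#'   `calibration`, `theta_posterior`, `fruiting`, `features`,
#'   `comparison`, optional `eval_report`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("strawyield_")) {
  if (!inherits(config, "pipeline_config")) {
    abort_field("config", "must be a pipeline_config object")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- stage_seeds(config$seed)
  paths <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "strawyield_pipeline_error")
    })
  }

  sim <- config$simulation
  sim$seed <- seeds[["trial"]]
  trial <- stage("simulate", {
    simulate_trial(sim) |>
      simulate_detections(sim$detection_prob, sim$false_positive_rate,
                          seed = seeds[["detections"]])
  })
  paths["trial"] <- file.path(outdir, "trial.csv")
  write_trial_csv(trial, paths["trial"])

  calibration <- stage("calibrate", {
    make_calibration_sample(trial, config$calibration_plants_per_cultivar,
                            seed = seeds[["calibration"]])
  })
  paths["calibration"] <- file.path(outdir, "calibration.csv")
  write_calibration_csv(calibration, paths["calibration"])

  theta_post <- fit_theta_posterior(calibration)
  ci <- theta_interval(theta_post)
  paths["theta"] <- file.path(outdir, "theta_posterior.json")
  jsonlite::write_json(
    list(alpha = theta_post$alpha, beta = theta_post$beta,
         mean = theta_post$alpha / (theta_post$alpha + theta_post$beta),
         ci95_lower = ci[["lower"]], ci95_upper = ci[["upper"]]),
    paths["theta"], auto_unbox = TRUE, digits = NA)

  fruiting <- stage("fruiting", {
    estimate_pi_per_cultivar(trial, theta_post,
                             n_imputations = config$n_imputations,
                             seed = seeds[["fruiting"]])
  })
  paths["fruiting"] <- file.path(outdir, "fruiting_estimates.csv")
  readr::write_csv(fruiting, paths["fruiting"])

  features <- stage("features", {
    build_feature_table(trial, fruiting, theta_posterior = theta_post,
                        window_weeks = config$window_weeks)
  })
  paths["features"] <- file.path(outdir, "feature_table.csv")
  readr::write_csv(features, paths["features"])

  comparison <- stage("regress", compare_models(features))
  paths["comparison"] <- file.path(outdir, "model_comparison.json")
  jsonlite::write_json(
    list(
      models = lapply(comparison$fits, function(f) {
        list(terms = f$terms, estimate = unname(f$coefficients),
             se = unname(f$standard_errors), t = unname(f$t_values),
             p_value = unname(f$p_values), aic = f$aic,
             adj_r2 = f$adj_r2,
             mse = comparison$comparison$loocv_mse[
               comparison$comparison$model == f$model_label])
      }),
      best_model = comparison$best_model
    ),
    paths["comparison"], auto_unbox = TRUE, digits = NA)

  eval_report <- NULL
  if (config$eval_boxes) {
    boxes <- stage("eval-boxes", {
      simulate_box_pairs(n_images = 50, boxes_per_image = 4, jitter = 8,
                         miss_rate = 0.15, false_positive_rate = 0.2,
                         seed = seeds[["boxes"]])
    })
    eval_report <- mean_average_precision(boxes$ground_truth, boxes$predictions)
    paths["eval"] <- file.path(outdir, "eval_report.json")
    jsonlite::write_json(
      list(ap_by_threshold = eval_report$ap_by_threshold,
           map_score = eval_report$map_score,
           mean_count_difference = eval_report$mean_count_difference,
           count_correlation = eval_report$count_correlation),
      paths["eval"], auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("strawyield")),
    seed = config$seed,
    stage_seeds = as.list(seeds),
    config = list(
      simulation = unclass(sim),
      calibration_plants_per_cultivar = config$calibration_plants_per_cultivar,
      window_weeks = config$window_weeks,
      n_imputations = config$n_imputations,
      tolerance = config$tolerance,
      eval_boxes = config$eval_boxes
    ),
    checksums = as.list(stats::setNames(tools::md5sum(unname(paths)),
                                        basename(unname(paths))))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(trial = trial, calibration = calibration,
                 theta_posterior = theta_post, fruiting = fruiting,
                 features = features, comparison = comparison,
                 eval_report = eval_report, manifest = manifest,
                 outdir = outdir))
}
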