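#' Read and write trial and calibration tables
#'
#' Trial CSVs carry one row per plant-week with columns `plant_id`,
#' `cultivar`, `week`, `true_receptacles_new`, `detected_receptacles_new`,
#' `fruits_new`, `cumulative_fruits` (real field data may leave
#' `true_receptacles_new` empty). Calibration CSVs carry `plant_id`,
#' `cultivar`, `n_obs`, `n_mis`.
#'
#' @param path File path.
#' @param trial,calibration Tibbles to write.
#' @return The tibble read, or the input invisibly for writers.
#' @name trial_io
NULL

#' @rdname trial_io
#' @export
read_trial_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    plant_id = readr::col_character(),
    cultivar = readr::col_character(),
    week = readr::col_integer(),
    true_receptacles_new = readr::col_integer(),
    detected_receptacles_new = readr::col_integer(),
    fruits_new = readr::col_integer(),
    cumulative_fruits = readr::col_integer()
  ))
}

#' @rdname trial_io
#' @export
write_trial_csv <- function(trial, path) {
  readr::write_csv(trial, path)
  invisible(trial)
}

#' @rdname trial_io
#' @export
read_calibration_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    plant_id = readr::col_character(),
    cultivar = readr::col_character(),
    n_obs = readr::col_integer(),
    n_mis = readr::col_integer()
  ))
}

#' @rdname trial_io
#' @export
write_calibration_csv <- function(calibration, path) {
  readr::write_csv(calibration, path)
  invisible(calibration)
}

#' Read a simulation configuration from YAML
#'
#' The YAML keys mirror the [sim_config()] arguments; absent keys take
#' the defaults.
#'
#' @param path YAML file path.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(sprintf("unknown simulation config field(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "strawyield_validation_error")
  }
  do.call(sim_config, vals)
}

#' Bounding-box sets as COCO-style JSON
#'
#' Boxes are stored with `bbox = [x, y, width, height]` under a single
#' `"receptacle"` category; predictions additionally carry `score`.
#' On read the boxes are converted to corner coordinates
#' (`x_min`, `y_min`, `x_max`, `y_max`).
#'
#' @param boxes Tibble of boxes (`image_id`, corner coordinates, optional
#'   `score`).
#' @param path JSON file path.
#' @return `read_coco_boxes()` returns the box tibble.
#' @name coco_io
NULL

#' @rdname coco_io
#' @export
write_coco_boxes <- function(boxes, path) {
  has_score <- "score" %in% names(boxes)
  ann <- lapply(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, ]
    a <- list(id = i, image_id = b$image_id, category_id = 1L,
              bbox = c(b$x_min, b$y_min, b$x_max - b$x_min, b$y_max - b$y_min))
    if (has_score) a$score <- b$score
    a
  })
  obj <- list(
    images = lapply(unique(boxes$image_id), function(i) list(id = i)),
    annotations = ann,
    categories = list(list(id = 1L, name = "receptacle"))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(boxes)
}

#' @rdname coco_io
#' @export
read_coco_boxes <- function(path) {
  obj <- jsonlite::read_json(path)
  ann <- obj$annotations
  if (length(ann) == 0L) {
    return(tibble::tibble(image_id = integer(0), x_min = numeric(0),
                          y_min = numeric(0), x_max = numeric(0),
                          y_max = numeric(0)))
  }
  out <- tibble::tibble(
    image_id = vapply(ann, function(a) a$image_id, c(ann[[1]]$image_id)),
    x_min = vapply(ann, function(a) a$bbox[[1]], numeric(1)),
    y_min = vapply(ann, function(a) a$bbox[[2]], numeric(1)),
    x_max = vapply(ann, function(a) a$bbox[[1]] + a$bbox[[3]], numeric(1)),
    y_max = vapply(ann, function(a) a$bbox[[2]] + a$bbox[[4]], numeric(1))
  )
  if (!is.null(ann[[1]]$score)) {
    out$score <- vapply(ann, function(a) a$score, numeric(1))
  }
  out
}
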