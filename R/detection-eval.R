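#' Intersection over union of two bounding boxes
#'
#' Boxes use continuous corner coordinates; area is
#' `(x_max - x_min) * (y_max - y_min)`. Disjoint boxes score 0,
#' identical boxes 1. Degenerate (zero-area) boxes are rejected.
#'
#' @param a,b One-row data frames (or named lists/vectors) with `x_min`,
#'   `y_min`, `x_max`, `y_max`.
#' @return IoU in `[0, 1]`.
#' @examples
#' iou(c(x_min = 0, y_min = 0, x_max = 10, y_max = 10),
#'     c(x_min = 5, y_min = 5, x_max = 15, y_max = 15))  # 1/7
#' @export
iou <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  for (box in list(a, b)) {
    if (box$x_max <= box$x_min || box$y_max <= box$y_min) {
      abort("degenerate bounding box: x_max must exceed x_min and y_max must exceed y_min",
            class = "strawyield_validation_error")
    }
  }
  iw <- min(a$x_max, b$x_max) - max(a$x_min, b$x_min)
  ih <- min(a$y_max, b$y_max) - max(a$y_min, b$y_min)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a$x_max - a$x_min) * (a$y_max - a$y_min) +
    (b$x_max - b$x_min) * (b$y_max - b$y_min) - inter
  inter / union
}

# Vectorised IoU matrix: rows = gt boxes, cols = predicted boxes.
iou_matrix <- function(gt, pred) {
  if (nrow(gt) == 0L || nrow(pred) == 0L) {
    return(matrix(0, nrow(gt), nrow(pred)))
  }
  ix_min <- outer(gt$x_min, pred$x_min, pmax)
  iy_min <- outer(gt$y_min, pred$y_min, pmax)
  ix_max <- outer(gt$x_max, pred$x_max, pmin)
  iy_max <- outer(gt$y_max, pred$y_max, pmin)
  iw <- pmax(ix_max - ix_min, 0)
  ih <- pmax(iy_max - iy_min, 0)
  inter <- iw * ih
  area_gt <- (gt$x_max - gt$x_min) * (gt$y_max - gt$y_min)
  area_pr <- (pred$x_max - pred$x_min) * (pred$y_max - pred$y_min)
  inter / (outer(area_gt, area_pr, `+`) - inter)
}

check_boxes <- function(boxes, what, need_score = FALSE) {
  check_columns(boxes, c("image_id", "x_min", "y_min", "x_max", "y_max"), what)
  if (nrow(boxes) > 0L &&
      (any(boxes$x_max <= boxes$x_min) || any(boxes$y_max <= boxes$y_min))) {
    abort(sprintf("%s contains degenerate (zero-area) boxes", what),
          class = "strawyield_validation_error")
  }
  if (need_score) {
    if (!"score" %in% names(boxes) || (nrow(boxes) > 0L && anyNA(boxes$score))) {
      abort(sprintf("%s must carry a confidence `score` on every box", what),
            class = "strawyield_validation_error")
    }
  }
  invisible(boxes)
}

#' Greedily match predictions to ground-truth boxes
#'
#' Within each image, predictions are processed in decreasing confidence
#' order (ties broken by stable input order) and each is matched to the
#' not-yet-matched ground-truth box of highest IoU, provided that IoU is
#' at least `iou_threshold` (the usual COCO convention for "above the
#' threshold"). Each ground-truth box is matched at most once.
#'
#' @param gt Ground-truth boxes (no scores required).
#' @param predictions Predicted boxes with a `score` column.
#' @param iou_threshold Minimum IoU for a successful detection.
#' @return A tibble, one row per prediction in global descending-score
#'   order, with `image_id`, `pred_id`, `score`, `gt_id` (`NA` when
#'   unmatched) and the matched `iou`.
#' @export
match_detections <- function(gt, predictions, iou_threshold) {
  check_boxes(gt, "gt")
  check_boxes(predictions, "predictions", need_score = TRUE)
  check_prob(iou_threshold, "iou_threshold", len = 1L)

  gt <- dplyr::mutate(gt, gt_id = dplyr::row_number())
  predictions <- dplyr::mutate(predictions, pred_id = dplyr::row_number())

  out <- vector("list", length(unique(predictions$image_id)))
  imgs <- unique(predictions$image_id)
  for (k in seq_along(imgs)) {
    p <- predictions[predictions$image_id == imgs[k], , drop = FALSE]
    g <- gt[gt$image_id == imgs[k], , drop = FALSE]
    ord <- order(-p$score)  # stable: ties keep input order
    p <- p[ord, , drop = FALSE]
    iom <- iou_matrix(g, p)
    taken <- rep(FALSE, nrow(g))
    gt_id <- rep(NA_integer_, nrow(p))
    best_iou <- rep(NA_real_, nrow(p))
    for (j in seq_len(nrow(p))) {
      cand <- which(!taken & iom[, j] >= iou_threshold)
      if (length(cand)) {
        i <- cand[which.max(iom[cand, j])]
        taken[i] <- TRUE
        gt_id[j] <- g$gt_id[i]
        best_iou[j] <- iom[i, j]
      }
    }
    out[[k]] <- tibble::tibble(image_id = p$image_id, pred_id = p$pred_id,
                               score = p$score, gt_id = gt_id, iou = best_iou)
  }
  res <- dplyr::bind_rows(out)
  res <- res[order(res$pred_id), , drop = FALSE]  # restore input order
  res[order(-res$score), , drop = FALSE]          # stable: ties keep input order
}

#' Average precision at one IoU threshold
#'
#' Ranks all predictions by confidence across images, marks each as true
#' or false positive by the one-to-one greedy matching of
#' [match_detections()], and summarises the precision-recall curve. The
#' default is the COCO 101-point rule: the interpolated precision
#' envelope evaluated at recalls 0, 0.01, ..., 1 and averaged;
#' `interpolation = "all_points"` integrates the envelope over the exact
#' recall steps instead.
#'
#' @inheritParams match_detections
#' @param interpolation `"coco101"` (default) or `"all_points"`.
#' @return AP in `[0, 1]`. Zero when there are no predictions (and
#'   ground truth is non-empty) or no ground truth (and predictions
#'   exist); an error when both sets are empty, since the metric is then
#'   undefined.
#' @export
average_precision <- function(gt, predictions, iou_threshold,
                              interpolation = c("coco101", "all_points")) {
  interpolation <- match.arg(interpolation)
  check_boxes(gt, "gt")
  check_boxes(predictions, "predictions", need_score = TRUE)
  if (nrow(gt) == 0L && nrow(predictions) == 0L) {
    abort("average precision is undefined when both box sets are empty",
          class = "strawyield_validation_error")
  }
  if (nrow(predictions) == 0L || nrow(gt) == 0L) return(0)

  m <- match_detections(gt, predictions, iou_threshold)
  tp <- cumsum(!is.na(m$gt_id))
  fp <- cumsum(is.na(m$gt_id))
  recall <- tp / nrow(gt)
  precision <- tp / (tp + fp)
  # interpolated envelope: best precision at any recall >= r
  envelope <- rev(cummax(rev(precision)))
  if (interpolation == "coco101") {
    grid <- seq(0, 1, by = 0.01)
    idx <- findInterval(grid, recall, left.open = TRUE) + 1L
    p_at <- ifelse(idx <= length(envelope), envelope[pmin(idx, length(envelope))], 0)
    mean(p_at)
  } else {
    r_prev <- c(0, head(recall, -1))
    sum((recall - r_prev) * envelope)
  }
}

#' Mean average precision over the COCO threshold sweep
#'
#' Computes AP at IoU thresholds 0.50, 0.55, ..., 0.95 and reports their
#' arithmetic mean, together with per-image ground-truth vs predicted
#' counts and the summary statistics used to compare AI and human counts
#' (mean difference and Pearson correlation).
#'
#' @inheritParams average_precision
#' @return A `detection_eval` object: list with `ap_by_threshold`
#'   (tibble of `iou_threshold`, `ap`), `map_score`, `per_image_counts`,
#'   `mean_count_difference`, `count_correlation`.
#' @export
mean_average_precision <- function(gt, predictions,
                                   interpolation = c("coco101", "all_points")) {
  interpolation <- match.arg(interpolation)
  thresholds <- seq(0.50, 0.95, by = 0.05)
  ap <- vapply(thresholds, function(t) {
    average_precision(gt, predictions, t, interpolation)
  }, numeric(1))

  imgs <- sort(unique(c(gt$image_id, predictions$image_id)))
  counts <- tibble::tibble(
    image_id = imgs,
    human_count = vapply(imgs, function(i) sum(gt$image_id == i), numeric(1)),
    ai_count = vapply(imgs, function(i) sum(predictions$image_id == i), numeric(1))
  )
  cmp <- compare_counts(counts$human_count, counts$ai_count, quiet = TRUE)

  structure(
    list(
      ap_by_threshold = tibble::tibble(iou_threshold = thresholds, ap = ap),
      map_score = mean(ap),
      per_image_counts = counts,
      mean_count_difference = cmp$mean_difference,
      count_correlation = cmp$correlation
    ),
    class = "detection_eval"
  )
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf("Detection evaluation over %d image(s)\n", nrow(x$per_image_counts)))
  cat(sprintf("  mAP (IoU 0.50:0.95): %.4f\n", x$map_score))
  cat(sprintf("  AI - human count, mean difference: %+.3f; Pearson r: %s\n",
              x$mean_count_difference,
              ifelse(is.na(x$count_correlation), "undefined",
                     sprintf("%.3f", x$count_correlation))))
  invisible(x)
}

#' Compare per-image AI counts with human counts
#'
#' @param human_counts,ai_counts Equal-length numeric vectors of counts
#'   per image.
#' @param quiet Suppress the zero-variance warning.
#' @return One-row tibble with `mean_difference` (`mean(ai - human)`),
#'   Pearson `correlation` (`NA` and flagged when either series has zero
#'   variance or fewer than 3 pairs), and `n`.
#' @export
compare_counts <- function(human_counts, ai_counts, quiet = FALSE) {
  if (length(human_counts) != length(ai_counts)) {
    abort("count series must have equal length", class = "strawyield_validation_error")
  }
  n <- length(human_counts)
  r <- NA_real_
  if (n >= 3L) {
    if (sd(human_counts) == 0 || sd(ai_counts) == 0) {
      if (!quiet) warn("correlation undefined: a count series has zero variance")
    } else {
      r <- cor(human_counts, ai_counts)
    }
  }
  tibble::tibble(mean_difference = mean(ai_counts - human_counts),
                 correlation = r, n = n)
}

#' @rdname mean_average_precision
#' @param object A `detection_eval` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.detection_eval <- function(object, ...) {
  ggplot2::ggplot(object$ap_by_threshold,
                  ggplot2::aes(x = .data$iou_threshold, y = .data$ap)) +
    ggplot2::geom_col(fill = "#c0392b", width = 0.035) +
    ggplot2::geom_hline(yintercept = object$map_score, linetype = 2) +
    ggplot2::annotate("text", x = 0.5, y = object$map_score,
                      label = sprintf("mAP = %.3f", object$map_score),
                      vjust = -0.5, hjust = 0) +
    ggplot2::labs(x = "IoU threshold", y = "Average precision") +
    ggplot2::ylim(0, 1)
}
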