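box <- function(x1, y1, x2, y2, image_id = 1, score = NULL) {
  b <- tibble::tibble(image_id = image_id, x_min = x1, y_min = y1,
                      x_max = x2, y_max = y2)
  if (!is.null(score)) b$score <- score
  b
}

test_that("iou handles identity, disjoint, partial overlap and degeneracy", {
  a <- box(0, 0, 10, 10)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, box(20, 20, 30, 30)), 0)
  expect_equal(iou(a, box(5, 5, 15, 15)), 25 / 175)  # = 1/7 by hand
  expect_error(iou(a, box(5, 5, 5, 15)), "degenerate")
})

test_that("greedy matching is one-to-one and threshold-sensitive", {
  gt <- box(0, 0, 10, 10)
  pred <- box(2.3457, 0, 12.3457, 10, score = 0.9)  # IoU ~ 0.62
  m_lo <- match_detections(gt, pred, 0.5)
  expect_false(is.na(m_lo$gt_id))
  m_hi <- match_detections(gt, pred, 0.65)
  expect_true(is.na(m_hi$gt_id))

  # two predictions over one gt: only the higher-scored one matches
  preds2 <- dplyr::bind_rows(box(1, 0, 11, 10, score = 0.9),
                             box(0.5, 0, 10.5, 10, score = 0.8))
  m2 <- match_detections(gt, preds2, 0.5)
  expect_equal(sum(!is.na(m2$gt_id)), 1)
  expect_equal(m2$score[!is.na(m2$gt_id)], 0.9)

  expect_error(match_detections(gt, box(1, 0, 11, 10), 0.5), "score")
})

test_that("average precision covers perfect, empty and enumerated cases", {
  gt <- dplyr::bind_rows(box(0, 0, 10, 10), box(50, 50, 60, 60))
  perfect <- dplyr::mutate(gt, score = c(0.9, 0.8))
  expect_equal(average_precision(gt, perfect, 0.5), 1)

  none <- perfect[0, ]
  expect_equal(average_precision(gt, none, 0.5), 0)
  expect_error(average_precision(gt[0, ], none, 0.5), "undefined")
  expect_equal(average_precision(gt[0, ], perfect, 0.5), 0)

  # ranks (TP, FP): TP at rank 1 -> precision 1 up to recall 0.5, 0 beyond
  tp_fp <- dplyr::bind_rows(box(0, 0, 10, 10, score = 0.9),
                            box(200, 200, 210, 210, score = 0.8))
  got <- average_precision(gt, tp_fp, 0.5)
  expect_equal(got, oracle_ap(gt, tp_fp, 0.5))
  expect_equal(got, 51 / 101)  # grid points 0,0.01,...,0.5 at precision 1
})

test_that("single-box sweep yields the step mAP of 0.30 at IoU 0.62", {
  gt <- box(0, 0, 10, 10)
  pred <- box(2.3457, 0, 12.3457, 10, score = 0.9)
  ev <- mean_average_precision(gt, pred)
  expect_equal(ev$ap_by_threshold$iou_threshold, seq(0.50, 0.95, by = 0.05))
  expect_equal(ev$ap_by_threshold$ap, c(1, 1, 1, rep(0, 7)))
  expect_equal(ev$map_score, 0.30)
  expect_equal(ev$map_score, mean(ev$ap_by_threshold$ap))
})

test_that("perfect predictions give mAP 1 with every AP 1", {
  pairs <- simulate_box_pairs(4, 3, jitter = 0, miss_rate = 0, seed = 31)
  ev <- mean_average_precision(pairs$ground_truth, pairs$predictions)
  expect_equal(ev$ap_by_threshold$ap, rep(1, 10))
  expect_equal(ev$map_score, 1)
  expect_equal(ev$mean_count_difference, 0)
})

test_that("mAP agrees with the brute-force oracle and AP is threshold-monotone", {
  set.seed(77)
  for (rep in 1:25) {
    fx <- random_box_fixture()
    ap <- vapply(seq(0.5, 0.95, by = 0.05), function(t) {
      average_precision(fx$gt, fx$pred, t)
    }, numeric(1))
    expect_true(all(diff(ap) <= 1e-12))
    expect_true(all(ap >= 0 & ap <= 1))
    ev <- mean_average_precision(fx$gt, fx$pred)
    expect_equal(ev$map_score, oracle_map(fx$gt, fx$pred), tolerance = 1e-9)
  }
})

test_that("count comparison reproduces hand-computed statistics", {
  same <- compare_counts(c(3, 5, 7), c(3, 5, 7))
  expect_equal(same$mean_difference, 0)
  expect_equal(same$correlation, 1)

  shifted <- compare_counts(c(3, 5, 7, 9), c(5, 7, 9, 11))
  expect_equal(shifted$mean_difference, 2)
  expect_equal(shifted$correlation, 1)

  hand <- compare_counts(c(3, 5, 7, 9), c(4, 4, 8, 10))
  expect_equal(hand$mean_difference, 0.5)
  # textbook Pearson formula, computed by hand from the centred series
  h <- c(3, 5, 7, 9) - 6; a <- c(4, 4, 8, 10) - 6.5
  expect_equal(hand$correlation, sum(h * a) / sqrt(sum(h^2) * sum(a^2)))

  expect_warning(flat <- compare_counts(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_true(is.na(flat$correlation))
  expect_error(compare_counts(1:3, 1:4), "equal length")
})

test_that("COCO JSON round-trips both ground truth and scored predictions", {
  pairs <- simulate_box_pairs(3, 2, jitter = 3, miss_rate = 0.2,
                              false_positive_rate = 0.5, seed = 12)
  gt_path <- withr::local_tempfile(fileext = ".json")
  pr_path <- withr::local_tempfile(fileext = ".json")
  write_coco_boxes(pairs$ground_truth, gt_path)
  write_coco_boxes(pairs$predictions, pr_path)
  gt2 <- read_coco_boxes(gt_path)
  pr2 <- read_coco_boxes(pr_path)
  expect_equal(as.data.frame(gt2), as.data.frame(pairs$ground_truth))
  expect_equal(as.data.frame(pr2), as.data.frame(pairs$predictions))
  expect_false("score" %in% names(gt2))
  expect_true("score" %in% names(pr2))
})
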