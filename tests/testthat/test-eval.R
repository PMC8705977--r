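test_that("greedy matching follows the single-match protocol", {
  gt <- data.frame(image_id = 1L, category_id = 1L, x = 10, y = 10, w = 20, h = 20)
  perfect <- data.frame(image_id = 1L, category_id = 1L, x = 10, y = 10,
                        w = 20, h = 20, score = 0.9)
  m <- match_detections(perfect, gt)
  expect_identical(sum(m$per_class[["1"]]$tp), 1L)

  # two overlapping predictions of one object: only the better scores a TP
  two <- rbind(perfect, transform(perfect, score = 0.7))
  m2 <- match_detections(two, gt)
  expect_identical(m2$per_class[["1"]]$tp, c(TRUE, FALSE))

  # no predictions: everything is a false negative
  m3 <- match_detections(perfect[0, ], rbind(gt, gt, gt))
  e <- m3$per_class[["1"]]
  expect_identical(e$n_gt, 3L)
  expect_length(e$scores, 0)
})

test_that("bookkeeping identities hold on random evaluation runs", {
  set.seed(17)
  for (rep in 1:10) {
    gt <- data.frame(image_id = sample(1:3, 15, TRUE), category_id = sample(1:3, 15, TRUE),
                     x = runif(15, 0, 80), y = runif(15, 0, 80),
                     w = runif(15, 5, 20), h = runif(15, 5, 20))
    pr <- data.frame(image_id = sample(1:3, 25, TRUE), category_id = sample(1:3, 25, TRUE),
                     x = runif(25, 0, 80), y = runif(25, 0, 80),
                     w = runif(25, 5, 20), h = runif(25, 5, 20),
                     score = runif(25))
    m <- match_detections(pr, gt)
    for (cl in names(m$per_class)) {
      e <- m$per_class[[cl]]
      tp <- sum(e$tp)
      fp <- sum(!e$tp)
      expect_identical(tp + fp, length(e$scores))          # TP + FP = predictions
      expect_lte(tp, e$n_gt)                               # TP + FN = ground truth
      expect_identical(length(e$scores),
                       sum(pr$category_id == as.integer(cl)))
    }
  }
})

test_that("precision and recall follow their defining ratios", {
  m <- structure(list(classes = 1L, per_class = list(
    "1" = list(scores = seq(1, 0.1, length.out = 10),
               tp = c(rep(TRUE, 9), FALSE), n_gt = 12L)),
    iou_threshold = 0.5), class = "match_result")
  pr <- precision_recall(m)[["1"]]
  expect_equal(pr$precision[10], 9 / 10)   # TP = 9, FP = 1
  expect_equal(pr$recall[10], 9 / 12)      # TP = 9, FN = 3
  # all correct and complete: the curve ends at (1, 1)
  m2 <- structure(list(classes = 1L, per_class = list(
    "1" = list(scores = c(0.9, 0.8), tp = c(TRUE, TRUE), n_gt = 2L)),
    iou_threshold = 0.5), class = "match_result")
  pr2 <- precision_recall(m2)[["1"]]
  expect_equal(pr2$precision[2], 1)
  expect_equal(pr2$recall[2], 1)
  # zero ground truth: warn and skip
  m3 <- structure(list(classes = 1L, per_class = list(
    "1" = list(scores = 0.5, tp = FALSE, n_gt = 0L)),
    iou_threshold = 0.5), class = "match_result")
  expect_warning(out <- precision_recall(m3), "undefined")
  expect_length(out, 0)
})

test_that("average precision handles the canonical endpoint cases", {
  expect_equal(average_precision(data.frame(precision = 1, recall = 1)), 1.0)
  # a false positive outranking the only true positive halves the AP
  pr <- data.frame(precision = c(0, 0.5), recall = c(0, 1))
  expect_equal(average_precision(pr), 0.5, tolerance = 1e-9)
  expect_equal(average_precision(data.frame(precision = numeric(),
                                            recall = numeric())), 0)
  pr0 <- data.frame(precision = c(0, 0), recall = c(0, 0))
  expect_equal(average_precision(pr0), 0)
})

test_that("101-point AP tracks the exact integrator within its grid error", {
  set.seed(19)
  for (rep in 1:100) {
    n <- sample(3:60, 1)
    n_gt <- sample(1:30, 1)
    scores <- runif(n)
    tp <- runif(n) < 0.5
    if (sum(tp) > n_gt) tp[which(tp)[seq_len(sum(tp) - n_gt)]] <- FALSE
    o <- order(-scores)
    ctp <- cumsum(tp[o])
    cfp <- cumsum(!tp[o])
    pr <- data.frame(precision = ctp / (ctp + cfp), recall = ctp / n_gt)
    expect_lt(abs(average_precision(pr) - ap_exact(scores, tp, n_gt)), 0.01)
  }
})

test_that("mean AP is the plain average over classes", {
  expect_equal(mean_ap(rep(1, 5)), 1.0)
  expect_equal(mean_ap(c(0.8, 0.6)), 0.7)
  expect_equal(mean_ap(c(0.4, 0.4, 0.4)), 0.4)
  expect_error(mean_ap(numeric()), "no classes")
})

test_that("ROC sweeps match the confusion arithmetic and AUC conventions", {
  # perfectly separating scores
  m <- structure(list(classes = 1L, per_class = list(
    "1" = list(scores = c(0.9, 0.85, 0.8), tp = rep(TRUE, 3), n_gt = 3L)),
    iou_threshold = 0.5), class = "match_result")
  roc <- roc_curve(m, negatives = c(0.1, 0.2, 0.3))
  expect_equal(attr(roc[["1"]], "auc"), 1.0)

  # single threshold with TP = 9, FN = 3, FP = 1, TN = 7
  m2 <- structure(list(classes = 1L, per_class = list(
    "1" = list(scores = seq(0.9, 0.5, length.out = 9), tp = rep(TRUE, 9),
               n_gt = 12L)), iou_threshold = 0.5), class = "match_result")
  neg <- c(0.55, rep(0.1, 7))   # one negative above the 0.5 cut
  roc2 <- roc_curve(m2, neg)[["1"]]
  i <- which(abs(roc2$threshold - 0.5) < 1e-9)
  expect_equal(roc2$tpr[i], 0.75)
  expect_equal(roc2$fpr[i], 0.125)

  # scores independent of labels: AUC concentrates near 1/2
  set.seed(23)
  mr <- structure(list(classes = 1L, per_class = list(
    "1" = list(scores = runif(5000), tp = runif(5000) < 0.5, n_gt = 2500L)),
    iou_threshold = 0.5), class = "match_result")
  rocr <- roc_curve(mr, negatives = runif(5000))[["1"]]
  expect_lt(abs(attr(rocr, "auc") - 0.5), 0.05)
  expect_error(roc_curve(m, negatives = numeric()), "negative pool")
})

test_that("negative pool collects only background predictions", {
  gt <- data.frame(image_id = 1L, category_id = 1L, x = 10, y = 10, w = 20, h = 20)
  pr <- data.frame(image_id = 1L, category_id = c(1L, 1L),
                   x = c(10, 70), y = c(10, 70), w = 20, h = 20,
                   score = c(0.9, 0.4))
  np <- negative_pool(pr, gt)
  expect_equal(np[["1"]], 0.4)
})

test_that("posture proportions implement the lying dichotomy", {
  det <- data.frame(timestamp = rep(0, 10),
                    category_id = c(rep(3L, 5), rep(2L, 3), rep(1L, 2)))
  pp <- posture_proportions(det)
  expect_equal(pp$lying_frac, 0.8)      # (5 LOS + 3 LOB) / 10
  expect_equal(pp$notlying_frac, 0.2)
  expect_identical(pp$n_standing, 2L)

  det2 <- data.frame(timestamp = 0, category_id = c(5L, 4L, 1L))
  expect_equal(posture_proportions(det2)$lying_frac, 0)

  # a frame with no detections reports missing fractions, not zeros
  pp3 <- posture_proportions(det2, timestamps = c(0, 1))
  empty <- pp3[pp3$timestamp == 1, ]
  expect_identical(empty$n_total, 0L)
  expect_true(is.na(empty$lying_frac))
  expect_true(is.na(empty$notlying_frac))
})

test_that("posture series aggregate and serialise to plain text", {
  det <- data.frame(timestamp = c(0, 60, 3600, 3660),
                    category_id = c(2L, 2L, 1L, 1L))
  hourly <- posture_proportions(det, window = 3600)
  expect_equal(hourly$lying_frac, c(1, 0))
  f <- tempfile(fileext = ".txt")
  write_posture_txt(hourly, f)
  back <- utils::read.table(f, header = TRUE)
  expect_equal(back$lying_frac, hourly$lying_frac)
  unlink(f)
})

test_that("profiler closed forms match single-layer arithmetic", {
  lc <- shuffledet:::new_layer_conv(16, 32, k = 1, bn = FALSE, act = "none")
  expect_identical(shuffledet:::layer_param_count(lc), 512L)
  dw <- shuffledet:::new_layer_conv(48, 48, k = 5, groups = 48, bn = FALSE,
                                    act = "none")
  expect_identical(shuffledet:::layer_param_count(dw), 1200L)
})

test_that("profile totals equal the per-layer breakdown and the weight census", {
  cfg <- default_model_config()
  pr <- profile_model(cfg)
  expect_equal(pr$total_params, sum(pr$layers$params))
  expect_equal(pr$total_macs, sum(pr$layers$macs))
  expect_equal(pr$gflops_double, 2 * pr$gflops)
  m <- build_detector(cfg, init_seed = 1)
  expect_identical(count_parameters(m), as.integer(pr$total_params))
  # MACs scale with the input area
  pr320 <- profile_model(cfg, input_size = 320)
  expect_equal(pr320$total_params, pr$total_params)
  expect_lt(pr320$total_macs, pr$total_macs)
})
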