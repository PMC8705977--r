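# Independent reference implementations and small fixture builders used
# across the suite.

# exact area under the precision-envelope-recall curve by stepwise
# integration over every recall breakpoint (no 101-point grid)
ap_exact <- function(scores, tp, n_gt) {
  if (!length(scores) || n_gt == 0L) return(0)
  o <- order(-scores, seq_along(scores))
  tp <- tp[o]
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  prec <- ctp / (ctp + cfp)
  rec <- ctp / n_gt
  # envelope: running max of precision from the right
  env <- rev(cummax(rev(prec)))
  r_prev <- 0
  area <- 0
  for (i in seq_along(rec)) {
    if (rec[i] > r_prev) {
      area <- area + (rec[i] - r_prev) * env[i]
      r_prev <- rec[i]
    }
  }
  area
}

# O(n^2) reference non-maximum suppression with the same ordering and
# tie-break contract, written against a precomputed pairwise IoU matrix
nms_reference <- function(det, iou_threshold) {
  n <- nrow(det)
  if (!n) return(det)
  corners <- cbind(det$x - det$w / 2, det$y - det$h / 2,
                   det$x + det$w / 2, det$y + det$h / 2)
  iou <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    xx1 <- max(corners[i, 1], corners[j, 1])
    yy1 <- max(corners[i, 2], corners[j, 2])
    xx2 <- min(corners[i, 3], corners[j, 3])
    yy2 <- min(corners[i, 4], corners[j, 4])
    inter <- max(xx2 - xx1, 0) * max(yy2 - yy1, 0)
    a1 <- (corners[i, 3] - corners[i, 1]) * (corners[i, 4] - corners[i, 2])
    a2 <- (corners[j, 3] - corners[j, 1]) * (corners[j, 4] - corners[j, 2])
    u <- a1 + a2 - inter
    iou[i, j] <- if (u > 0) inter / u else 0
  }
  ord <- order(-det$score, seq_len(n))
  removed <- logical(n)
  kept <- integer()
  for (i in ord) {
    if (removed[i]) next
    kept <- c(kept, i)
    for (j in ord) {
      if (!removed[j] && j != i && det$class_id[j] == det$class_id[i] &&
          iou[i, j] > iou_threshold) {
        removed[j] <- TRUE
      }
    }
    removed[i] <- TRUE
  }
  out <- det[kept, , drop = FALSE]
  out[order(-out$score), , drop = FALSE]
}

random_detections <- function(n, classes = 3L, span = 100) {
  data.frame(
    x = runif(n, 10, span - 10), y = runif(n, 10, span - 10),
    w = runif(n, 4, 30), h = runif(n, 4, 30),
    conf = runif(n), class_id = sample.int(classes, n, replace = TRUE),
    class_prob = runif(n), score = round(runif(n), 3))
}

# small desk-scale scene configuration used by the training experiments
desk_scene_config <- function(seed) {
  scene_config(width = 96L, height = 96L, n_range = c(2L, 5L),
               size_range = c(28, 48), occlusion_prob = 0.1,
               brightness_range = c(0.8, 1.0), seed = seed)
}

desk_samples <- function(n, seed, split = NULL) {
  cfg <- desk_scene_config(seed)
  if (is.null(split)) {
    ds <- generate_dataset(cfg, n)
    shuffledet:::samples_from_dataset(ds)
  } else {
    ds <- generate_dataset(cfg, n, split_fractions = split)
    sm <- shuffledet:::samples_from_dataset(ds)
    split(sm, ds$index$split)
  }
}

# minimal valid annotation set
tiny_aset <- function() {
  annotation_set(
    images = data.frame(id = 1L, file_name = "a.png", width = 100L, height = 80L),
    annotations = data.frame(id = 1L, image_id = 1L, category_id = 2L,
                             x = 10, y = 20, w = 30, h = 15))
}
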