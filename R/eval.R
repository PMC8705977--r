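# Detection evaluation: greedy matching, precision/recall, 101-point
# interpolated average precision, mAP over IoU thresholds, per-class ROC
# against an explicit negative pool, and posture-proportion time series.

#' Match predictions to ground truth
#'
#' Greedy protocol: within each class, predictions are visited in
#' descending score order (ties broken by row order); each matches the
#' highest-IoU unmatched ground-truth box of the same class in the same
#' image provided IoU >= threshold (a true positive), else it is a false
#' positive. Ground truths matched at most once; leftovers are false
#' negatives.
#'
#' @param pred data frame of predictions: `image_id`, `category_id`, `x`,
#'   `y`, `w`, `h` (top-left convention), `score`.
#' @param gt an [annotation_set()] or a data frame with `image_id`,
#'   `category_id`, `x`, `y`, `w`, `h`.
#' @param iou_threshold match threshold (default 0.5).
#' @return A `match_result`: per class, the score-ordered TP flags plus
#'   the ground-truth count.
#' @export
match_detections <- function(pred, gt, iou_threshold = 0.5) {
  if (inherits(gt, "annotation_set")) gt <- gt$annotations
  classes <- sort(unique(c(pred$category_id, gt$category_id)))
  per <- list()
  for (cl in classes) {
    p <- pred[pred$category_id == cl, , drop = FALSE]
    g <- gt[gt$category_id == cl, , drop = FALSE]
    if (nrow(p)) {
      p <- p[order(-p$score, seq_len(nrow(p))), , drop = FALSE]
      tp <- logical(nrow(p))
      gt_used <- logical(nrow(g))
      pc <- cbind(p$x, p$y, p$x + p$w, p$y + p$h)
      gc <- cbind(g$x, g$y, g$x + g$w, g$y + g$h)
      for (i in seq_len(nrow(p))) {
        cand <- which(!gt_used & g$image_id == p$image_id[i])
        if (!length(cand)) next
        ious <- box_iou(pc[i, , drop = FALSE], gc[cand, , drop = FALSE])
        j <- which.max(ious)
        if (ious[j] >= iou_threshold) {
          tp[i] <- TRUE
          gt_used[cand[j]] <- TRUE
        }
      }
      per[[as.character(cl)]] <- list(scores = p$score, tp = tp, n_gt = nrow(g))
    } else {
      per[[as.character(cl)]] <- list(scores = numeric(), tp = logical(),
                                      n_gt = nrow(g))
    }
  }
  structure(list(classes = classes, per_class = per,
                 iou_threshold = iou_threshold), class = "match_result")
}

#' Cumulative precision-recall curves
#'
#' Precision `TP/(TP+FP)` and recall `TP/(TP+FN)` at every score cut of a
#' [match_detections()] result. Classes without ground truth have
#' undefined recall and are skipped with a warning.
#'
#' @param m a `match_result`.
#' @return A named list of per-class data frames (`score`, `precision`,
#'   `recall`).
#' @export
precision_recall <- function(m) {
  out <- list()
  for (cl in names(m$per_class)) {
    e <- m$per_class[[cl]]
    if (e$n_gt == 0L) {
      warning("class ", cl, " has no ground truth; recall undefined, skipped")
      next
    }
    if (!length(e$scores)) {
      out[[cl]] <- data.frame(score = numeric(), precision = numeric(),
                              recall = numeric())
      next
    }
    ctp <- cumsum(e$tp)
    cfp <- cumsum(!e$tp)
    out[[cl]] <- data.frame(score = e$scores,
                            precision = ctp / (ctp + cfp),
                            recall = ctp / e$n_gt)
  }
  out
}

#' 101-point interpolated average precision
#'
#' Area under the precision-envelope-versus-recall curve, evaluated on the
#' standard 101-point recall grid `0, 0.01, ..., 1`: at each grid recall
#' the envelope takes the maximum precision achieved at any recall at
#' least that large.
#'
#' @param pr a single class's precision-recall data frame from
#'   [precision_recall()] (columns `precision`, `recall`).
#' @return AP in `[0, 1]`; an empty curve gives 0.
#' @export
average_precision <- function(pr) {
  if (!NROW(pr)) return(0)
  rec <- pr$recall
  prec <- pr$precision
  grid <- seq(0, 1, by = 0.01)
  env <- vapply(grid, function(r) {
    ok <- rec >= r - 1e-12
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1))
  mean(env)
}

#' Mean average precision
#'
#' The arithmetic mean of per-class AP values over the `n` classes.
#'
#' @param per_class_ap numeric vector of per-class APs.
#' @return mAP in `[0, 1]`.
#' @examples
#' mean_ap(c(0.977, 0.952, 0.957, 0.875, 0.841))  # 0.9204
#' @export
mean_ap <- function(per_class_ap) {
  if (!length(per_class_ap)) stop("invalid-input: no classes with defined AP")
  mean(per_class_ap)
}

#' Evaluate detections against ground truth
#'
#' Runs matching at one or more IoU thresholds and aggregates per-class AP
#' and mAP. With the default threshold ladder `0.50:0.05:0.95`, both
#' mAP@0.5 and mAP@0.5:0.95 are reported.
#'
#' @inheritParams match_detections
#' @param iou_thresholds vector of matching thresholds.
#' @return An `eval_report`: `ap` (class x threshold matrix), `map50`,
#'   `map50_95`, `pr` (PR curves at the first threshold), `n_classes`.
#' @export
evaluate_detections <- function(pred, gt,
                                iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (inherits(gt, "annotation_set")) gt <- gt$annotations
  classes <- sort(unique(gt$category_id))
  ap <- matrix(NA_real_, length(classes), length(iou_thresholds),
               dimnames = list(as.character(classes),
                               sprintf("%.2f", iou_thresholds)))
  pr_first <- NULL
  for (ti in seq_along(iou_thresholds)) {
    m <- match_detections(pred, gt, iou_thresholds[ti])
    pr <- suppressWarnings(precision_recall(m))
    if (ti == 1L) pr_first <- pr
    for (cl in as.character(classes)) {
      ap[cl, ti] <- if (!is.null(pr[[cl]])) average_precision(pr[[cl]]) else NA_real_
    }
  }
  maps <- colMeans(ap, na.rm = TRUE)
  structure(list(ap = ap, per_class_ap50 = ap[, 1],
                 map50 = unname(maps[1]),
                 map50_95 = if (length(maps) > 1) mean(maps) else unname(maps[1]),
                 map_per_threshold = maps, pr = pr_first,
                 n_classes = length(classes)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %d classes, mAP@0.5 = %.4f, mAP@0.5:0.95 = %.4f>\n",
              x$n_classes, x$map50, x$map50_95))
  invisible(x)
}

#' Per-class ROC curves for a detector
#'
#' Pure detection has no natural true negatives; the negative pool is
#' therefore explicit: candidate boxes that overlap no ground truth (IoU
#' below `iou_max` against every ground-truth box; see
#' [negative_pool()]). For each class, the score axis is swept and TPR =
#' TP/(TP+FN) is plotted against FPR = FP/(FP+TN), where positives come
#' from the match result and negatives from the pool.
#'
#' @param m a `match_result` from [match_detections()].
#' @param negatives numeric vector of negative-candidate scores, or a
#'   named list of such vectors per class.
#' @return A named list per class: data frame (`threshold`, `tpr`, `fpr`)
#'   plus attribute `auc` (trapezoidal area).
#' @export
roc_curve <- function(m, negatives) {
  if (!is.list(negatives)) {
    negatives <- stats::setNames(rep(list(negatives), length(m$classes)),
                                 as.character(m$classes))
  }
  out <- list()
  for (cl in names(m$per_class)) {
    e <- m$per_class[[cl]]
    neg <- negatives[[cl]]
    if (is.null(neg) || !length(neg)) {
      stop("invalid-input: empty negative pool for class ", cl)
    }
    pos <- e$scores[e$tp]
    thr <- sort(unique(c(0, e$scores, neg, 1)), decreasing = TRUE)
    tpr <- vapply(thr, function(t) sum(pos >= t) / max(e$n_gt, 1L), numeric(1))
    fpr <- vapply(thr, function(t) sum(neg >= t) / length(neg), numeric(1))
    o <- order(fpr, tpr)
    auc <- sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(o)]) / 2)
    df <- data.frame(threshold = thr, tpr = tpr, fpr = fpr)
    attr(df, "auc") <- auc
    out[[cl]] <- df
  }
  out
}

#' Negative candidate pool for ROC analysis
#'
#' Returns the scores of predictions that overlap no ground-truth box
#' (maximum IoU below `iou_max` in their image), grouped by predicted
#' class.
#'
#' @inheritParams match_detections
#' @param iou_max overlap ceiling defining "background" (default 0.1).
#' @return Named list of score vectors per class.
#' @export
negative_pool <- function(pred, gt, iou_max = 0.1) {
  if (inherits(gt, "annotation_set")) gt <- gt$annotations
  pc <- cbind(pred$x, pred$y, pred$x + pred$w, pred$y + pred$h)
  isneg <- logical(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    g <- gt[gt$image_id == pred$image_id[i], , drop = FALSE]
    if (!nrow(g)) {
      isneg[i] <- TRUE
      next
    }
    gc <- cbind(g$x, g$y, g$x + g$w, g$y + g$h)
    isneg[i] <- max(box_iou(pc[i, , drop = FALSE], gc)) < iou_max
  }
  split(pred$score[isneg], as.character(pred$category_id[isneg]))
}

#' Posture-proportion time series
#'
#' Aggregates per-frame detections into the lying / not-lying dichotomy
#' used for day-scale activity monitoring: lying = lying-on-belly +
#' lying-on-side (categories 2 and 3); everything else (standing, sitting,
#' mounting) counts as not lying. Frames with no detections yield missing
#' fractions rather than zeros.
#'
#' @param det data frame of per-frame detections with columns `timestamp`
#'   (seconds or any numeric time) and `category_id`.
#' @param timestamps optional vector of all frame timestamps, including
#'   frames in which nothing was detected; defaults to the timestamps
#'   present in `det`.
#' @param window optional aggregation window in the same time units
#'   (e.g. 3600 for hourly means); `NULL` gives per-frame rows.
#' @param lying_classes category ids counted as lying (default `c(2, 3)` =
#'   LOB, LOS).
#' @param standing_class category id counted for the standing series
#'   (default 1).
#' @return A data frame `timestamp, n_total, lying_frac, notlying_frac,
#'   n_standing`; with a window, `timestamp` is the window start and
#'   fractions are means over frames that had detections.
#' @export
posture_proportions <- function(det, timestamps = NULL, window = NULL,
                                lying_classes = c(2L, 3L),
                                standing_class = 1L) {
  ts <- if (is.null(timestamps)) sort(unique(det$timestamp)) else
    sort(unique(timestamps))
  rows <- lapply(ts, function(t) {
    d <- det[det$timestamp == t, , drop = FALSE]
    n <- nrow(d)
    lying <- sum(d$category_id %in% lying_classes)
    data.frame(timestamp = t, n_total = n,
               lying_frac = if (n) lying / n else NA_real_,
               notlying_frac = if (n) 1 - lying / n else NA_real_,
               n_standing = sum(d$category_id == standing_class))
  })
  perframe <- do.call(rbind, rows)
  if (is.null(window)) return(perframe)
  bin <- floor(perframe$timestamp / window) * window
  agg <- lapply(split(perframe, bin), function(d) {
    ok <- !is.na(d$lying_frac)
    data.frame(timestamp = d$timestamp[1] - d$timestamp[1] %% window,
               n_total = sum(d$n_total),
               lying_frac = if (any(ok)) mean(d$lying_frac[ok]) else NA_real_,
               notlying_frac = if (any(ok)) mean(d$notlying_frac[ok]) else NA_real_,
               n_standing = mean(d$n_standing))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Write a posture time series as a plain-text table
#'
#' Whitespace-delimited columns `timestamp n_total lying_frac
#' notlying_frac n_standing`; missing fractions are written as `NA`.
#'
#' @param series data frame from [posture_proportions()].
#' @param path output `.txt` path.
#' @export
write_posture_txt <- function(series, path) {
  utils::write.table(series, path, quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}
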