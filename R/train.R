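# Training: anchor/cell target assignment, the composite detection loss
# (CIoU box term + binary cross-entropy objectness and class terms) with
# analytic gradients, an SGD-with-momentum loop (linear warmup + cosine
# decay), light augmentation, and genetic-algorithm hyperparameter
# evolution scored by the weighted mAP fitness.

#' Training hyperparameters
#'
#' @param lr0 initial learning rate.
#' @param lrf final learning rate as a fraction of `lr0` (cosine decay
#'   target).
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty on convolution weights.
#' @param warmup_epochs epochs of linear learning-rate warmup.
#' @param box,obj,cls loss-balance gains for the box, objectness and
#'   class terms.
#' @param hsv_v brightness-jitter gain (log-normal sigma).
#' @param fliplr horizontal flip probability.
#' @param rot90 probability of rotating a (square) sample by a random
#'   quarter turn; poses are rotation-invariant in top-view imagery, so
#'   this multiplies the effective orientation coverage for free.
#' @param mosaic probability of composing a 4-scene mosaic sample.
#' @param anchor_t anchor-matching ratio threshold: a ground-truth box is
#'   assigned to anchors whose width and height ratios are both within
#'   this factor.
#' @return A `hyperparameters` list, serialisable to/from YAML.
#' @export
hyperparameters <- function(lr0 = 0.01, lrf = 0.1, momentum = 0.937,
                            weight_decay = 5e-4, warmup_epochs = 3,
                            box = 5.0, obj = 1.0, cls = 5.0,
                            hsv_v = 0.2, fliplr = 0.5, rot90 = 0.75,
                            mosaic = 0.0, anchor_t = 4.0) {
  structure(list(lr0 = lr0, lrf = lrf, momentum = momentum,
                 weight_decay = weight_decay, warmup_epochs = warmup_epochs,
                 box = box, obj = obj, cls = cls, hsv_v = hsv_v,
                 fliplr = fliplr, rot90 = rot90, mosaic = mosaic,
                 anchor_t = anchor_t),
            class = "hyperparameters")
}

#' Read / write hyperparameters as YAML
#'
#' @param hyp a [hyperparameters()] object.
#' @param path YAML file path.
#' @export
write_hyperparameters <- function(hyp, path) {
  yaml::write_yaml(unclass(hyp), path)
  invisible(path)
}

#' @rdname write_hyperparameters
#' @export
read_hyperparameters <- function(path) {
  do.call(hyperparameters, yaml::read_yaml(path))
}

#' Fit anchors by k-means over box dimensions
#'
#' Clusters the `(w, h)` pairs of a box collection into `k` anchors
#' (seeded k-means), sorts them by area and splits them evenly across the
#' three detection scales, smallest anchors to the finest stride.
#'
#' @param wh two-column matrix or data frame of box widths and heights in
#'   input pixels.
#' @param k number of anchors (default 9 = 3 scales x 3 anchors).
#' @param seed RNG seed for the k-means initialisation.
#' @return List of three `(k/3) x 2` anchor matrices.
#' @export
anchor_kmeans <- function(wh, k = 9L, seed = 1L) {
  wh <- as.matrix(wh)[, 1:2, drop = FALSE]
  if (nrow(wh) < k) stop("invalid-input: need at least ", k, " boxes")
  km <- with_seed(seed, stats::kmeans(wh, centers = k, nstart = 10L,
                                      iter.max = 100L))
  cent <- km$centers[order(km$centers[, 1] * km$centers[, 2]), , drop = FALSE]
  per <- k %/% 3L
  lapply(0:2, function(s) {
    m <- cent[(s * per + 1L):((s + 1L) * per), , drop = FALSE]
    dimnames(m) <- NULL
    m
  })
}

# ---- target assignment --------------------------------------------------

#' Assign ground-truth boxes to anchors and grid cells
#'
#' Each box is matched, at every scale, to the anchors whose width and
#' height ratios both lie within `anchor_t`; targets are placed at the
#' cell containing the box centre plus the nearest horizontal and
#' vertical neighbour cells (the centre-offset decode spans `[-0.5, 1.5]`
#' cells, so those cells can also reach the box). Objectness targets are
#' 1 at assigned slots, 0 elsewhere. When two boxes claim the same
#' (cell, anchor) slot the first in annotation order wins, so a slot
#' never carries two classes.
#'
#' @param boxes data frame with `cx`, `cy`, `w`, `h` (centre format,
#'   input pixels) and `class_id`.
#' @param cfg model config (anchors, strides, classes).
#' @param input_hw input canvas `c(height, width)`.
#' @param anchor_t anchor ratio threshold.
#' @return A list with one data frame per scale: `row` (grid row index),
#'   `anchor`, `class_id`, `gx`, `gy` (0-based cell), `bx, by, bw, bh`
#'   (target box, pixels).
#' @export
assign_targets <- function(boxes, cfg, input_hw, anchor_t = 4.0) {
  K <- cfg$head$anchors_per_scale
  empty <- data.frame(row = integer(), anchor = integer(),
                      class_id = integer(), gx = numeric(), gy = numeric(),
                      bx = numeric(), by = numeric(), bw = numeric(),
                      bh = numeric())
  out <- vector("list", length(cfg$head$strides))
  if (nrow(boxes)) {
    bad <- boxes$w <= 0 | boxes$h <= 0
    outside <- !bad & (boxes$cx < 0 | boxes$cy < 0 |
                         boxes$cx > input_hw[2] | boxes$cy > input_hw[1])
    if (any(outside)) warning("box centre outside image skipped")
    boxes <- boxes[!bad & !outside, , drop = FALSE]
  }
  for (s in seq_along(cfg$head$strides)) {
    stride <- cfg$head$strides[s]
    Sh <- input_hw[1] %/% stride
    Sw <- input_hw[2] %/% stride
    anchors <- cfg$head$anchors[[s]]
    if (!nrow(boxes)) {
      out[[s]] <- empty
      next
    }
    rw <- outer(boxes$w, anchors[, 1], "/")
    rh <- outer(boxes$h, anchors[, 2], "/")
    ok <- pmax(rw, 1 / rw) < anchor_t & pmax(rh, 1 / rh) < anchor_t
    hit <- which(ok, arr.ind = TRUE)
    if (!nrow(hit)) {
      out[[s]] <- empty
      next
    }
    i <- hit[, 1]
    a <- hit[, 2]
    cx <- boxes$cx[i] / stride
    cy <- boxes$cy[i] / stride
    gx0 <- pmin(pmax(floor(cx), 0), Sw - 1)
    gy0 <- pmin(pmax(floor(cy), 0), Sh - 1)
    gx1 <- ifelse(cx - gx0 < 0.5, gx0 - 1, gx0 + 1)
    gy1 <- ifelse(cy - gy0 < 0.5, gy0 - 1, gy0 + 1)
    okx <- gx1 >= 0 & gx1 < Sw
    oky <- gy1 >= 0 & gy1 < Sh
    cand <- rbind(cbind(i, a, gx0, gy0),
                  cbind(i, a, gx1, gy0)[okx, , drop = FALSE],
                  cbind(i, a, gx0, gy1)[oky, , drop = FALSE])
    ii <- cand[, 1]
    tg <- data.frame(row = as.integer(cand[, 3] * Sh + cand[, 4] + 1),
                     anchor = as.integer(cand[, 2]),
                     class_id = boxes$class_id[ii],
                     gx = cand[, 3], gy = cand[, 4],
                     bx = boxes$cx[ii], by = boxes$cy[ii],
                     bw = boxes$w[ii], bh = boxes$h[ii])
    out[[s]] <- tg[!duplicated(tg[, c("row", "anchor")]), , drop = FALSE]
  }
  out
}

# ---- loss ---------------------------------------------------------------

bce_logits <- function(z, t) {
  pmax(z, 0) - z * t + log1p(exp(-abs(z)))
}

# complete IoU between centre-format boxes (vectorised)
ciou <- function(px, py, pw, ph, bx, by, bw, bh) {
  eps <- 1e-9
  px1 <- px - pw / 2; px2 <- px + pw / 2
  py1 <- py - ph / 2; py2 <- py + ph / 2
  bx1 <- bx - bw / 2; bx2 <- bx + bw / 2
  by1 <- by - bh / 2; by2 <- by + bh / 2
  iw <- pmax(pmin(px2, bx2) - pmax(px1, bx1), 0)
  ih <- pmax(pmin(py2, by2) - pmax(py1, by1), 0)
  inter <- iw * ih
  un <- pw * ph + bw * bh - inter + eps
  iou <- inter / un
  cw <- pmax(px2, bx2) - pmin(px1, bx1)
  ch <- pmax(py2, by2) - pmin(py1, by1)
  c2 <- cw^2 + ch^2 + eps
  rho2 <- (bx - px)^2 + (by - py)^2
  v <- (4 / pi^2) * (atan(bw / bh) - atan(pw / ph))^2
  alpha <- v / (1 - iou + v + eps)
  iou - rho2 / c2 - alpha * v
}

decode_slots <- function(tx, ty, tw, th, gx, gy, stride, aw, ah) {
  list(px = (2 * sigmoid(tx) - 0.5 + gx) * stride,
       py = (2 * sigmoid(ty) - 0.5 + gy) * stride,
       pw = (2 * sigmoid(tw))^2 * aw,
       ph = (2 * sigmoid(th))^2 * ah)
}

ciou_of_raw <- function(raw, gx, gy, bx, by, bw, bh, stride, aw, ah) {
  d <- decode_slots(raw[, 1], raw[, 2], raw[, 3], raw[, 4],
                    gx, gy, stride, aw, ah)
  ciou(d$px, d$py, d$pw, d$ph, bx, by, bw, bh)
}

#' Composite detection loss
#'
#' `loss = box_gain * mean(1 - CIoU)` over assigned slots `+ obj_gain *`
#' per-scale-balanced BCE over all objectness logits `+ cls_gain *` BCE
#' over class logits at assigned slots. Returns the components and, when
#' `grad = TRUE`, the gradient with respect to every raw grid value (box
#' gradients by central differences through the decode + CIoU chain;
#' everything else analytic).
#'
#' @param grids list of raw prediction grids (internal tmap form).
#' @param targets output of [assign_targets()].
#' @param cfg model config.
#' @param hyp [hyperparameters()].
#' @param grad compute gradients.
#' @return List: `total`, `box`, `obj`, `cls`, `n_assigned`, and `dgrids`
#'   when requested.
#' @export
compute_loss <- function(grids, targets, cfg, hyp, grad = TRUE) {
  nc <- cfg$num_classes
  K <- cfg$head$anchors_per_scale
  per <- 5L + nc
  balance <- c(4.0, 1.0, 0.4)
  n_assigned <- sum(vapply(targets, nrow, 1L))
  box_sum <- 0
  cls_sum <- 0
  obj_loss <- 0
  dgrids <- if (grad) lapply(grids, function(t) matrix(0, nrow(t$x), ncol(t$x)))
  for (s in seq_along(grids)) {
    t <- grids[[s]]
    n <- nrow(t$x)
    stride <- cfg$head$strides[s]
    tg <- targets[[s]]
    obj_cols <- (seq_len(K) - 1L) * per + 5L
    tobj <- matrix(0, n, K)
    if (nrow(tg)) tobj[cbind(tg$row, tg$anchor)] <- 1
    z <- t$x[, obj_cols, drop = FALSE]
    obj_loss <- obj_loss + balance[s] * mean(bce_logits(z, tobj))
    if (grad) {
      dgrids[[s]][, obj_cols] <- hyp$obj * balance[s] *
        (sigmoid(z) - tobj) / (n * K)
    }
    if (nrow(tg)) {
      trow <- tg$row
      tanchor <- tg$anchor
      tcls <- tg$class_id
      gx <- tg$gx; gy <- tg$gy
      bx <- tg$bx; by <- tg$by; bw <- tg$bw; bh <- tg$bh
      base <- (tanchor - 1L) * per
      aw <- cfg$head$anchors[[s]][tanchor, 1]
      ah <- cfg$head$anchors[[s]][tanchor, 2]
      raw <- cbind(t$x[cbind(trow, base + 1L)], t$x[cbind(trow, base + 2L)],
                   t$x[cbind(trow, base + 3L)], t$x[cbind(trow, base + 4L)])
      ci <- ciou_of_raw(raw, gx, gy, bx, by, bw, bh, stride, aw, ah)
      box_sum <- box_sum + sum(1 - ci)
      if (grad) {
        h <- 1e-3
        for (j in 1:4) {
          rp <- raw; rp[, j] <- rp[, j] + h
          rm <- raw; rm[, j] <- rm[, j] - h
          dci <- (ciou_of_raw(rp, gx, gy, bx, by, bw, bh, stride, aw, ah) -
                    ciou_of_raw(rm, gx, gy, bx, by, bw, bh, stride, aw, ah)) / (2 * h)
          idx <- cbind(trow, base + j)
          dgrids[[s]][idx] <- dgrids[[s]][idx] - hyp$box * dci
        }
      }
      for (cc in seq_len(nc)) {
        zc <- t$x[cbind(trow, base + 5L + cc)]
        tc <- as.numeric(tcls == cc)
        cls_sum <- cls_sum + sum(bce_logits(zc, tc))
        if (grad) {
          idx <- cbind(trow, base + 5L + cc)
          dgrids[[s]][idx] <- dgrids[[s]][idx] + hyp$cls * (sigmoid(zc) - tc)
        }
      }
    }
  }
  box_loss <- if (n_assigned) box_sum / n_assigned else 0
  cls_loss <- if (n_assigned) cls_sum / (n_assigned * nc) else 0
  if (grad && n_assigned) {
    for (s in seq_along(dgrids)) {
      tg <- targets[[s]]
      if (!nrow(tg)) next
      base <- (tg$anchor - 1L) * per
      for (j in 1:4) {
        idx <- cbind(tg$row, base + j)
        dgrids[[s]][idx] <- dgrids[[s]][idx] / n_assigned
      }
      for (cc in seq_len(nc)) {
        idx <- cbind(tg$row, base + 5L + cc)
        dgrids[[s]][idx] <- dgrids[[s]][idx] / (n_assigned * nc)
      }
    }
  }
  total <- hyp$box * box_loss + hyp$obj * obj_loss + hyp$cls * cls_loss
  if (!is.finite(total)) {
    stop("training-divergence: non-finite loss (box=", box_loss,
         ", obj=", obj_loss, ", cls=", cls_loss, ")")
  }
  out <- list(total = total, box = box_loss, obj = obj_loss, cls = cls_loss,
              n_assigned = n_assigned)
  if (grad) out$dgrids <- dgrids
  out
}

# ---- optimiser ----------------------------------------------------------

sgd_step <- function(layers, lr, hyp, scale = 1) {
  for (ly in layers) {
    upd <- function(p, g, v, decay = 0) {
      grad <- ly[[g]] * scale
      if (decay > 0) grad <- grad + decay * ly[[p]]
      vel <- if (is.null(ly[[v]])) grad else hyp$momentum * ly[[v]] + grad
      ly[[v]] <- vel
      ly[[p]] <- ly[[p]] - lr * vel
    }
    if (ly$kind == "conv") {
      upd("W", "gW", "vW", hyp$weight_decay)
      if (ly$has_bias) upd("b", "gb", "vb")
      if (ly$has_bn) {
        upd("gamma", "ggamma", "vgamma")
        upd("beta", "gbeta", "vbeta")
      }
    } else if (ly$kind == "eca") {
      upd("kernel", "gkernel", "vkernel")
    }
    zero_grads(ly)
  }
}

lr_schedule <- function(epoch, total, hyp) {
  wu <- hyp$warmup_epochs
  if (wu > 0 && epoch <= wu) return(hyp$lr0 * epoch / wu)
  p <- (epoch - wu) / max(total - wu, 1)
  hyp$lr0 * (hyp$lrf + (1 - hyp$lrf) * (1 + cos(pi * p)) / 2)
}

# ---- augmentation -------------------------------------------------------

augment_sample <- function(sample, hyp, pool = NULL) {
  img <- sample$image
  boxes <- sample$boxes
  if (!is.null(pool) && length(pool) >= 4L && stats::runif(1) < hyp$mosaic) {
    picks <- pool[sample.int(length(pool), 3L)]
    tiles <- c(list(sample), picks)
    d <- dim(img)
    H <- d[1]; W <- d[2]
    h2 <- H %/% 2L; w2 <- W %/% 2L
    canvas <- matrix(0.3, H, W)
    parts <- list()
    offs <- list(c(0, 0), c(0, w2), c(h2, 0), c(h2, w2))
    for (q in 1:4) {
      ti <- tiles[[q]]$image
      if (length(dim(ti)) == 3L) ti <- ti[, , 1]
      canvas[offs[[q]][1] + seq_len(h2), offs[[q]][2] + seq_len(w2)] <-
        resize_bilinear(ti, h2, w2)
      b <- tiles[[q]]$boxes
      if (nrow(b)) {
        b$cx <- b$cx / 2 + offs[[q]][2]
        b$cy <- b$cy / 2 + offs[[q]][1]
        b$w <- b$w / 2
        b$h <- b$h / 2
        parts[[q]] <- b[b$w >= 4 & b$h >= 4, , drop = FALSE]
      }
    }
    img <- canvas
    boxes <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
    if (is.null(boxes)) boxes <- sample$boxes[0, , drop = FALSE]
  }
  if ((hyp$rot90 %||% 0) > 0 && dim(img)[1] == dim(img)[2] &&
      stats::runif(1) < hyp$rot90) {
    k <- sample(0:3, 1L)
    S <- dim(img)[1]
    for (q in seq_len(k)) {
      img <- if (length(dim(img)) == 3L) {
        ar <- array(0, dim(img))
        for (cch in seq_len(dim(img)[3])) ar[, , cch] <- t(img[, , cch])[, S:1]
        ar
      } else t(img)[, S:1]
      if (nrow(boxes)) {
        newcx <- S - boxes$cy
        boxes$cy <- boxes$cx
        boxes$cx <- newcx
        tmpw <- boxes$w
        boxes$w <- boxes$h
        boxes$h <- tmpw
      }
    }
  }
  if (stats::runif(1) < hyp$fliplr) {
    W <- dim(img)[2]
    img <- if (length(dim(img)) == 3L) img[, W:1, , drop = FALSE] else img[, W:1]
    if (nrow(boxes)) boxes$cx <- W - boxes$cx
  }
  if (hyp$hsv_v > 0) {
    img <- pmin(pmax(img * exp(stats::rnorm(1, 0, hyp$hsv_v / 2)), 0), 1)
  }
  list(image = img, boxes = boxes, image_id = sample$image_id)
}

# ---- training loop ------------------------------------------------------

#' Train the detector
#'
#' SGD with momentum, linear warmup then cosine learning-rate decay.
#' Samples are visited one at a time with gradients accumulated over
#' `batch_size` images per step. When validation samples are supplied,
#' mAP@0.5 and mAP@0.5:0.95 are computed every `val_every` epochs and the
#' checkpoint with the best fitness (see [fitness()]) is retained.
#'
#' @param samples list of training samples, each `list(image, boxes,
#'   image_id)` with centre-format boxes (see the synthetic generator's
#'   `samples_from_dataset` layout); images must already be at the
#'   network input size.
#' @param cfg model config; its `input_size` must match the sample
#'   images.
#' @param hyp [hyperparameters()].
#' @param epochs training epochs; 0 returns the freshly initialised
#'   model.
#' @param seed seed controlling initialisation, anchor fitting, sample
#'   order and augmentation.
#' @param batch_size gradient accumulation length.
#' @param val_samples optional held-out samples for mAP tracking.
#' @param val_every validation cadence in epochs.
#' @param fit_anchors refit anchors to the training boxes by k-means
#'   before building the model (the default; pass `FALSE` to keep
#'   `cfg$head$anchors`).
#' @param verbose print per-epoch progress.
#' @return List: `model` (best checkpoint if validated, else final),
#'   `history` (per-epoch data frame), `best_fitness`, `cfg`.
#' @export
train_detector <- function(samples, cfg = NULL, hyp = hyperparameters(),
                           epochs = 30L, seed = 1L, batch_size = 8L,
                           val_samples = NULL, val_every = 5L,
                           fit_anchors = TRUE, verbose = FALSE) {
  if (!length(samples)) stop("invalid-input: empty dataset")
  d <- dim(samples[[1]]$image)
  if (is.null(cfg)) cfg <- default_model_config(input_size = d[1])
  if (d[1] != cfg$input_size || d[2] != cfg$input_size) {
    stop("invalid-input: sample images must match cfg$input_size (letterbox first)")
  }
  if (fit_anchors) {
    wh <- do.call(rbind, lapply(samples, function(s) {
      as.matrix(s$boxes[, c("w", "h"), drop = FALSE])
    }))
    if (nrow(wh) >= 9L) cfg$head$anchors <- anchor_kmeans(wh, 9L, seed)
  }
  model <- build_detector(cfg, init_seed = seed)
  history <- list()
  best_fit <- -Inf
  best_state <- NULL
  layers <- model_layers(model)
  if (epochs > 0) with_seed(seed + 1L, {
    n <- length(samples)
    for (epoch in seq_len(epochs)) {
      lr <- lr_schedule(epoch, epochs, hyp)
      ord <- sample.int(n)
      sums <- c(total = 0, box = 0, obj = 0, cls = 0)
      nacc <- 0L
      for (i in ord) {
        sm <- augment_sample(samples[[i]], hyp, pool = samples)
        hg <- head_grids(model, sm$image, train = TRUE, grad = TRUE)
        tgt <- assign_targets(sm$boxes, cfg, dim(sm$image)[1:2], hyp$anchor_t)
        ls <- compute_loss(hg$grids, tgt, cfg, hyp, grad = TRUE)
        dout <- stats::setNames(
          lapply(seq_along(ls$dgrids), function(s) ls$dgrids[[s]]),
          model$outputs)
        backward_graph(model, hg$fwd, dout)
        sums <- sums + c(ls$total, ls$box, ls$obj, ls$cls)
        nacc <- nacc + 1L
        if (nacc == batch_size) {
          sgd_step(layers, lr, hyp, scale = 1 / nacc)
          nacc <- 0L
        }
      }
      if (nacc > 0L) sgd_step(layers, lr, hyp, scale = 1 / nacc)
      row <- data.frame(epoch = epoch, lr = lr,
                        loss = sums[1] / n, box = sums[2] / n,
                        obj = sums[3] / n, cls = sums[4] / n,
                        map50 = NA_real_, map50_95 = NA_real_,
                        fitness = NA_real_)
      if (!is.null(val_samples) &&
          (epoch %% val_every == 0L || epoch == epochs)) {
        rep <- evaluate_model(model, val_samples, cfg)
        fit <- fitness(rep$map50, rep$map50_95)
        row$map50 <- rep$map50
        row$map50_95 <- rep$map50_95
        row$fitness <- fit
        if (fit >= best_fit) {
          best_fit <- fit
          best_state <- model_state(model)
        }
      }
      history[[epoch]] <- row
      if (verbose) {
        message(sprintf("epoch %3d lr %.4g loss %.4f box %.4f obj %.4f cls %.4f%s",
                        epoch, lr, row$loss, row$box, row$obj, row$cls,
                        if (!is.na(row$map50))
                          sprintf(" mAP50 %.3f fit %.3f", row$map50, row$fitness)
                        else ""))
      }
    }
  })
  if (!is.null(best_state)) load_state(model, best_state)
  list(model = model, cfg = cfg,
       history = if (length(history)) do.call(rbind, history) else
         data.frame(),
       best_fitness = if (is.finite(best_fit)) best_fit else NA_real_)
}

#' Evaluate a model on a sample set
#'
#' Runs inference (evaluation-mode normalisation, low confidence floor,
#' NMS) over the samples and scores the detections against their boxes.
#'
#' @param model trained `sdet_model`.
#' @param samples list of samples as in [train_detector()].
#' @param cfg model config.
#' @param conf_threshold decoding score floor (default the config's
#'   evaluation threshold, 0.001).
#' @param iou_thresholds AP matching thresholds.
#' @return An `eval_report`, see [evaluate_detections()].
#' @export
evaluate_model <- function(model, samples, cfg = model$cfg,
                           conf_threshold = cfg$eval_conf_threshold,
                           iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  preds <- list()
  gts <- list()
  for (sm in samples) {
    hg <- head_grids(model, sm$image)
    det <- decode_predictions(hg$grids, cfg, conf_threshold)
    det <- nms(det, cfg$nms_iou)
    preds[[length(preds) + 1L]] <- detections_to_results(det, sm$image_id)
    b <- sm$boxes
    if (nrow(b)) {
      gts[[length(gts) + 1L]] <- data.frame(
        image_id = sm$image_id, category_id = b$class_id,
        x = b$cx - b$w / 2, y = b$cy - b$h / 2, w = b$w, h = b$h)
    }
  }
  evaluate_detections(do.call(rbind, preds), do.call(rbind, gts),
                      iou_thresholds)
}

# ---- fitness and hyperparameter evolution -------------------------------

#' Fitness weights
#'
#' The selection metric weights mAP@0.5 at 10% and mAP@0.5:0.95 at 90%;
#' precision and recall do not enter.
#'
#' @param w_map50,w_map50_95 non-negative weights summing to 1.
#' @return A `fitness_weights` list.
#' @export
fitness_weights <- function(w_map50 = 0.1, w_map50_95 = 0.9) {
  if (w_map50 < 0 || w_map50_95 < 0 || abs(w_map50 + w_map50_95 - 1) > 1e-9) {
    stop("invalid-config: fitness weights must be non-negative and sum to 1")
  }
  structure(list(w_map50 = w_map50, w_map50_95 = w_map50_95),
            class = "fitness_weights")
}

#' Weighted mAP fitness
#'
#' @param map50 mAP at IoU 0.5, in `[0, 1]`.
#' @param map50_95 mAP averaged over IoU 0.50-0.95, in `[0, 1]`.
#' @param w a [fitness_weights()] object.
#' @return `w_map50 * map50 + w_map50_95 * map50_95`.
#' @examples
#' fitness(0.8, 0.6)  # 0.62
#' @export
fitness <- function(map50, map50_95, w = fitness_weights()) {
  w$w_map50 * map50 + w$w_map50_95 * map50_95
}

default_hyp_bounds <- function() {
  list(lr0 = c(1e-5, 0.1), lrf = c(0.01, 1), momentum = c(0.6, 0.98),
       weight_decay = c(0, 0.001), warmup_epochs = c(0, 5),
       box = c(0.5, 20), obj = c(0.2, 4), cls = c(0.5, 20),
       hsv_v = c(0, 0.9), fliplr = c(0, 1), rot90 = c(0, 1), mosaic = c(0, 1),
       anchor_t = c(2, 8))
}

#' Genetic-algorithm hyperparameter evolution
#'
#' Elitist (1+1) evolution: each generation mutates the best-so-far
#' parent with per-field log-normal multiplicative noise, evaluates the
#' child's fitness, and keeps the better of the two. The best-ever
#' fitness trace is therefore non-decreasing by construction.
#'
#' @param base starting [hyperparameters()].
#' @param generations number of generations (>= 1).
#' @param fitness_fn function `hyperparameters -> numeric` scoring a
#'   candidate; see [make_train_fitness()] for the training-backed one.
#' @param mutate_prob per-field mutation probability.
#' @param sigma log-normal mutation scale.
#' @param seed RNG seed.
#' @param bounds named list of `c(lo, hi)` clamps per field.
#' @return List: `best` (hyperparameters), `fitness`, `trace`
#'   (best-ever fitness per generation).
#' @export
evolve_hyperparameters <- function(base = hyperparameters(), generations = 20L,
                                   fitness_fn, mutate_prob = 0.9, sigma = 0.2,
                                   seed = 1L, bounds = default_hyp_bounds()) {
  if (generations < 1L) stop("invalid-config: generations must be >= 1")
  with_seed(seed, {
    best <- base
    best_fit <- fitness_fn(base)
    trace <- numeric(generations)
    for (g in seq_len(generations)) {
      child <- best
      for (f in names(bounds)) {
        if (stats::runif(1) < mutate_prob) {
          child[[f]] <- min(max(child[[f]] * exp(stats::rnorm(1, 0, sigma)),
                                bounds[[f]][1]), bounds[[f]][2])
        }
      }
      fit <- fitness_fn(child)
      if (fit > best_fit) {
        best <- child
        best_fit <- fit
      }
      trace[g] <- best_fit
    }
    list(best = best, fitness = best_fit, trace = trace)
  })
}

#' Training-backed fitness function for evolution
#'
#' Wraps a short training run: each candidate trains for
#' `epochs_budget` epochs on the given samples and is scored by
#' [fitness()] on the validation set.
#'
#' @param samples,val_samples training and validation samples.
#' @param cfg model config.
#' @param epochs_budget training epochs per candidate (> 0).
#' @param seed seed shared across candidates so fitness differences come
#'   from the hyperparameters.
#' @return A function `hyperparameters -> numeric`.
#' @export
make_train_fitness <- function(samples, val_samples, cfg, epochs_budget,
                               seed = 1L) {
  if (epochs_budget <= 0) stop("invalid-config: training budget must be positive")
  function(hyp) {
    res <- train_detector(samples, cfg, hyp, epochs = epochs_budget,
                          seed = seed, val_samples = val_samples,
                          val_every = epochs_budget)
    res$best_fitness
  }
}
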