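# Detector assembly: stem + three compression-block stages with ECA, a
# path-aggregation neck, and three 1x1 anchor-based prediction heads. The
# network is represented as a flat DAG of primitive nodes (conv, slice,
# concat, shuffle, pool, upsample, eca) so one generic forward/backward
# walker serves training, inference and the analytic profiler.

#' Default detector configuration
#'
#' The reference architecture: a 3x3 stride-2 stem convolution to 24
#' channels followed by a 2x2 max pool; three backbone stages of
#' `[48, 96, 192]` channels with `[3, 7, 3]` basic compression-block
#' repeats (each stage opened by a symmetric downsampling unit and closed
#' by ECA attention); a path-aggregation neck at a unified width of 48
#' channels whose stride-8 fusion carries a five-deep stack of dense 3x3
#' convolutions; and three 1x1 heads predicting 3 anchors over 5 posture
#' classes per grid cell. The fusion depths are calibrated so the full
#' model lands on a 0.358 M parameter / 1.2 GFLOP budget (see
#' [profile_model()]).
#'
#' @param input_size network input resolution (square, divisible by 32).
#' @param num_classes number of object classes.
#' @param class_names character vector of category names, in category-id
#'   order.
#' @param anchors optional list of three `K x 2` matrices of anchor
#'   `(w, h)` pairs in input pixels, one per stride `8/16/32`, each sorted
#'   ascending by area; defaults to anchors fitted by k-means to the
#'   synthetic pen-scene generator's box distribution at 640 px.
#' @return A config list understood by [build_detector()] and
#'   [profile_model()].
#' @export
default_model_config <- function(input_size = 640L, num_classes = 5L,
                                 class_names = c("STD", "LOB", "LOS", "SIT", "MOT"),
                                 anchors = NULL) {
  if (input_size %% 32L != 0L) {
    stop("invalid-input: input_size must be divisible by 32 (letterbox first)")
  }
  if (is.null(anchors)) anchors <- default_anchors(input_size)
  list(
    input_size = as.integer(input_size),
    num_classes = as.integer(num_classes),
    class_names = class_names,
    stem_channels = 24L,
    stage_channels = c(48L, 96L, 192L),
    stage_repeats = c(3L, 7L, 3L),
    dw_kernel = 5L,
    eca_after_stage = c(TRUE, TRUE, TRUE),
    eca_gamma = 2,
    eca_b = 1,
    neck = list(width = 48L, depth_n3 = 5L, depth_td4 = 0L,
                depth_n4 = 0L, depth_n5 = 0L, bottom_up = TRUE,
                eca_after_fusion = FALSE),
    head = list(anchors_per_scale = 3L, strides = c(8L, 16L, 32L),
                anchors = anchors),
    conf_threshold = 0.25,
    eval_conf_threshold = 0.001,
    nms_iou = 0.45
  )
}

# anchors fitted once by seeded k-means (k = 9) to the box dimensions of
# the default synthetic pen-scene generator at 640 px, grouped 3 per scale
# ascending by area (see anchor_kmeans()); scaled linearly for other input
# sizes
default_anchors <- function(input_size = 640L) {
  base <- list(
    matrix(c(45.7, 66.9, 64.9, 49.1, 65.2, 69.5), ncol = 2, byrow = TRUE),
    matrix(c(82.3, 55.2, 58.6, 92.1, 85.2, 78.5), ncol = 2, byrow = TRUE),
    matrix(c(102.3, 66.6, 78.6, 103.8, 99.8, 97.2), ncol = 2, byrow = TRUE)
  )
  lapply(base, function(m) m * input_size / 640)
}

# ---- graph construction -------------------------------------------------

new_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g
}

g_add <- function(g, name, kind, inputs = character(), layer = NULL,
                  extra = list()) {
  if (name %in% names(g$nodes)) stop("duplicate node name: ", name)
  g$nodes[[name]] <- list(name = name, kind = kind, inputs = inputs,
                          layer = layer, extra = extra)
  name
}

add_conv <- function(g, name, input, cin, cout, k = 1L, stride = 1L,
                     groups = 1L, bn = TRUE, act = "relu", bias = FALSE) {
  g_add(g, name, "conv", input,
        new_layer_conv(cin, cout, k, stride, groups, bn, act, bias))
}

# basic compression unit as primitive nodes; returns output node name
emit_basic <- function(g, input, C, dwk, prefix) {
  cb <- C %/% 2L
  l <- g_add(g, paste0(prefix, "_l"), "slice", input,
             extra = list(from = 1L, to = cb, cin = C))
  r <- g_add(g, paste0(prefix, "_r"), "slice", input,
             extra = list(from = cb + 1L, to = C, cin = C))
  r1 <- add_conv(g, paste0(prefix, "_pre"), r, cb, cb, 1L)
  r2 <- add_conv(g, paste0(prefix, "_dw"), r1, cb, cb, dwk, 1L, groups = cb,
                 act = "none")
  r3 <- add_conv(g, paste0(prefix, "_post"), r2, cb, cb, 1L)
  cc <- g_add(g, paste0(prefix, "_cat"), "concat", c(l, r3))
  g_add(g, paste0(prefix, "_shuf"), "shuffle", cc,
        extra = list(perm = shuffle_permutation(C, 2L)))
}

# symmetric downsampling unit: both branches see all input channels
emit_down <- function(g, input, cin, dwk, prefix) {
  branch <- function(tag) {
    a <- add_conv(g, paste0(prefix, tag, "_pre"), input, cin, cin, 1L)
    b <- add_conv(g, paste0(prefix, tag, "_dw"), a, cin, cin, dwk, 2L,
                  groups = cin, act = "none")
    add_conv(g, paste0(prefix, tag, "_post"), b, cin, cin, 1L)
  }
  b1 <- branch("_a")
  b2 <- branch("_b")
  cc <- g_add(g, paste0(prefix, "_cat"), "concat", c(b1, b2))
  g_add(g, paste0(prefix, "_shuf"), "shuffle", cc,
        extra = list(perm = shuffle_permutation(2L * cin, 2L)))
}

emit_fusion <- function(g, inputs, cin_total, width, depth, prefix,
                        eca_cfg = NULL) {
  cc <- g_add(g, paste0(prefix, "_cat"), "concat", inputs)
  cur <- add_conv(g, paste0(prefix, "_red"), cc, cin_total, width, 1L)
  for (i in seq_len(depth)) {
    cur <- add_conv(g, paste0(prefix, "_c", i), cur, width, width, 3L)
  }
  if (!is.null(eca_cfg)) {
    cur <- g_add(g, paste0(prefix, "_eca"), "eca", cur,
                 layer = new_layer_eca(width, eca_cfg$gamma, eca_cfg$b))
  }
  cur
}

#' Build the detector
#'
#' Instantiates the full network graph from a configuration list. Weights
#' are Kaiming-initialised when a seed is given, zero otherwise; head
#' biases start at a low-objectness prior so early training is not flooded
#' with false positives.
#'
#' @param cfg a configuration list, see [default_model_config()].
#' @param init_seed integer seed for weight initialisation, or `NULL` to
#'   leave all weights zero.
#' @return An object of class `sdet_model`.
#' @export
build_detector <- function(cfg = default_model_config(), init_seed = NULL) {
  g <- new_graph()
  g_add(g, "in", "input")
  cur <- add_conv(g, "stem_conv", "in", 3L, cfg$stem_channels, 3L, 2L)
  cur <- g_add(g, "stem_pool", "maxpool", cur)
  taps <- character(3)
  cin <- cfg$stem_channels
  for (i in 1:3) {
    C <- cfg$stage_channels[i]
    stopifnot(C == 2L * cin)
    cur <- emit_down(g, cur, cin, cfg$dw_kernel, sprintf("s%dd", i))
    for (r in seq_len(cfg$stage_repeats[i])) {
      cur <- emit_basic(g, cur, C, cfg$dw_kernel, sprintf("s%db%d", i, r))
    }
    if (cfg$eca_after_stage[i]) {
      cur <- g_add(g, sprintf("s%d_eca", i), "eca", cur,
                   layer = new_layer_eca(C, cfg$eca_gamma, cfg$eca_b))
    }
    taps[i] <- cur
    cin <- C
  }
  nk <- cfg$neck
  W <- nk$width
  ecafuse <- if (isTRUE(nk$eca_after_fusion)) {
    list(gamma = cfg$eca_gamma, b = cfg$eca_b)
  } else NULL
  lat3 <- add_conv(g, "lat3", taps[1], cfg$stage_channels[1], W, 1L)
  lat4 <- add_conv(g, "lat4", taps[2], cfg$stage_channels[2], W, 1L)
  lat5 <- add_conv(g, "lat5", taps[3], cfg$stage_channels[3], W, 1L)
  up5 <- g_add(g, "up5", "upsample", lat5)
  td4 <- emit_fusion(g, c(lat4, up5), 2L * W, W, nk$depth_td4, "td4", ecafuse)
  up4 <- g_add(g, "up4", "upsample", td4)
  n3 <- emit_fusion(g, c(lat3, up4), 2L * W, W, nk$depth_n3, "n3", ecafuse)
  if (isTRUE(nk$bottom_up)) {
    d3 <- add_conv(g, "bu_d3", n3, W, W, 3L, 2L)
    n4 <- emit_fusion(g, c(d3, td4), 2L * W, W, nk$depth_n4, "n4", ecafuse)
    d4 <- add_conv(g, "bu_d4", n4, W, W, 3L, 2L)
    n5 <- emit_fusion(g, c(d4, lat5), 2L * W, W, nk$depth_n5, "n5", ecafuse)
  } else {
    n4 <- td4
    n5 <- lat5
  }
  K <- cfg$head$anchors_per_scale
  per <- K * (5L + cfg$num_classes)
  add_conv(g, "p3", n3, W, per, 1L, bn = FALSE, act = "none", bias = TRUE)
  add_conv(g, "p4", n4, W, per, 1L, bn = FALSE, act = "none", bias = TRUE)
  add_conv(g, "p5", n5, W, per, 1L, bn = FALSE, act = "none", bias = TRUE)
  model <- structure(list(cfg = cfg, nodes = g$nodes,
                          outputs = c("p3", "p4", "p5"),
                          taps = taps, neck_outputs = c(n3, n4, n5)),
                     class = "sdet_model")
  if (!is.null(init_seed)) init_detector_weights(model, init_seed)
  model
}

init_detector_weights <- function(model, seed) {
  with_seed(seed, {
    for (nd in model$nodes) if (!is.null(nd$layer)) init_layer(nd$layer)
  })
  # low-objectness prior on head biases: sigmoid(-4.6) ~= 0.01
  nc <- model$cfg$num_classes
  K <- model$cfg$head$anchors_per_scale
  for (out in model$outputs) {
    ly <- model$nodes[[out]]$layer
    b <- ly$b
    for (k in seq_len(K)) {
      off <- (k - 1L) * (5L + nc)
      b[off + 5L] <- -4.6
      b[off + 5L + seq_len(nc)] <- log(0.6 / (nc - 0.6))
    }
    ly$b <- b
  }
  invisible(model)
}

model_layers <- function(model) {
  out <- list()
  for (nd in model$nodes) if (!is.null(nd$layer)) out[[nd$name]] <- nd$layer
  out
}

#' @export
print.sdet_model <- function(x, ...) {
  pr <- profile_model(x$cfg)
  cat(sprintf("<sdet_model: %d nodes, %s parameters, %.3f GFLOPs @ %d px>\n",
              length(x$nodes), format(pr$total_params, big.mark = ","),
              pr$gflops, x$cfg$input_size))
  invisible(x)
}

# ---- graph execution ----------------------------------------------------

forward_graph <- function(model, x, train = FALSE, grad = FALSE) {
  acts <- new.env(parent = emptyenv())
  caches <- if (grad) new.env(parent = emptyenv()) else NULL
  for (nd in model$nodes) {
    out <- switch(nd$kind,
      input = list(out = x, cache = NULL),
      conv = layer_forward(nd$layer, acts[[nd$inputs]], train, grad),
      eca = layer_forward(nd$layer, acts[[nd$inputs]], train, grad),
      maxpool = {
        mp <- maxpool2_fwd(acts[[nd$inputs]])
        list(out = mp$out, cache = if (grad) mp else NULL)
      },
      upsample = {
        up <- upsample2_fwd(acts[[nd$inputs]])
        list(out = up$out, cache = if (grad) up else NULL)
      },
      concat = {
        ins <- lapply(nd$inputs, function(nm) acts[[nm]])
        widths <- vapply(ins, function(t) ncol(t$x), 1L)
        list(out = tm(do.call(cbind, lapply(ins, `[[`, "x")),
                      ins[[1]]$h, ins[[1]]$w),
             cache = if (grad) list(widths = widths) else NULL)
      },
      slice = {
        t <- acts[[nd$inputs]]
        list(out = tm(t$x[, nd$extra$from:nd$extra$to, drop = FALSE], t$h, t$w),
             cache = NULL)
      },
      shuffle = {
        t <- acts[[nd$inputs]]
        list(out = tm(t$x[, nd$extra$perm, drop = FALSE], t$h, t$w),
             cache = NULL)
      },
      stop("unknown node kind: ", nd$kind))
    acts[[nd$name]] <- out$out
    if (grad && !is.null(out$cache)) caches[[nd$name]] <- out$cache
  }
  list(acts = acts, caches = caches)
}

backward_graph <- function(model, fwd, dout) {
  dacc <- new.env(parent = emptyenv())
  for (nm in names(dout)) dacc[[nm]] <- dout[[nm]]
  addg <- function(nm, dx) {
    cur <- dacc[[nm]]
    dacc[[nm]] <- if (is.null(cur)) dx else cur + dx
  }
  for (nd in rev(model$nodes)) {
    dy <- dacc[[nd$name]]
    if (is.null(dy) || nd$kind == "input") next
    switch(nd$kind,
      conv = addg(nd$inputs, layer_backward(nd$layer, fwd$caches[[nd$name]], dy)),
      eca = addg(nd$inputs, layer_backward(nd$layer, fwd$caches[[nd$name]], dy)),
      maxpool = addg(nd$inputs, maxpool2_bwd(dy, fwd$caches[[nd$name]])),
      upsample = addg(nd$inputs, upsample2_bwd(dy, fwd$caches[[nd$name]])),
      concat = {
        widths <- fwd$caches[[nd$name]]$widths
        off <- 0L
        for (i in seq_along(nd$inputs)) {
          addg(nd$inputs[i], dy[, (off + 1L):(off + widths[i]), drop = FALSE])
          off <- off + widths[i]
        }
      },
      slice = {
        dx <- matrix(0, nrow(dy), nd$extra$cin)
        dx[, nd$extra$from:nd$extra$to] <- dy
        addg(nd$inputs, dx)
      },
      shuffle = {
        inv <- order(nd$extra$perm)
        addg(nd$inputs, dy[, inv, drop = FALSE])
      })
    dacc[[nd$name]] <- NULL  # release
  }
  invisible(NULL)
}

# forward pass on an H x W x 3 image array in [0, 1]
detector_forward <- function(model, image, train = FALSE, grad = FALSE) {
  d <- dim(image)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop("invalid-input: image dimensions must be divisible by 32 (letterbox first)")
  }
  if (length(d) == 2L || d[3] == 1L) {
    image <- array(rep(as.numeric(image), 3), c(d[1], d[2], 3L))
  }
  forward_graph(model, tm_from_array(image), train = train, grad = grad)
}

#' Backbone feature pyramid
#'
#' Runs the stem and the three compression-block stages and returns the
#' three pyramid taps at strides 8, 16 and 32.
#'
#' @param model an `sdet_model` from [build_detector()].
#' @param image an `H x W x 3` (or grayscale) numeric array in `[0, 1]`
#'   with dimensions divisible by 32.
#' @return A list of three [feature_map()]s `P3`, `P4`, `P5`.
#' @export
backbone_pyramid <- function(model, image) {
  fwd <- detector_forward(model, image)
  out <- list()
  for (i in 1:3) {
    t <- fwd$acts[[model$taps[i]]]
    out[[paste0("P", i + 2L)]] <- feature_map(tm_to_array(t), c(8L, 16L, 32L)[i])
  }
  out
}

#' Fused neck feature maps
#'
#' Returns the path-aggregation outputs `N3`, `N4`, `N5` (strides 8/16/32)
#' at the unified neck width.
#'
#' @inheritParams backbone_pyramid
#' @return A list of three [feature_map()]s.
#' @export
neck_features <- function(model, image) {
  fwd <- detector_forward(model, image)
  out <- list()
  for (i in 1:3) {
    t <- fwd$acts[[model$neck_outputs[i]]]
    out[[paste0("N", i + 2L)]] <- feature_map(tm_to_array(t), c(8L, 16L, 32L)[i])
  }
  out
}

# raw prediction grids as tmaps, one per scale
head_grids <- function(model, image, train = FALSE, grad = FALSE) {
  fwd <- detector_forward(model, image, train = train, grad = grad)
  list(grids = lapply(model$outputs, function(nm) fwd$acts[[nm]]), fwd = fwd)
}

# ---- decoding, IoU, NMS -------------------------------------------------

# grid geometry for a tmap of S_h x S_w cells: row r maps to 0-based cell
# (gy, gx) with gy = (r-1) %% S_h, gx = (r-1) %/% S_h
grid_xy <- function(h, w) {
  r <- seq_len(h * w) - 1L
  list(gy = r %% h, gx = r %/% h)
}

#' Decode raw head grids into detections
#'
#' Applies the sigmoid box parameterisation: the box centre is
#' `(2*sigmoid(t_xy) - 0.5 + cell)*stride` and the size is
#' `anchor*(2*sigmoid(t_wh))^2`; objectness and class logits pass through a
#' sigmoid, and the detection score is the product of objectness confidence
#' and the best class probability. At zero logits a cell decodes to its
#' centre with the anchor's size.
#'
#' @param grids list of three raw prediction grids (as returned internally
#'   by the heads), one per stride.
#' @param cfg the model configuration that produced them.
#' @param conf_threshold drop detections whose score falls below this.
#' @return A data frame of class `sdet_detections` with columns `x, y, w,
#'   h` (box centre and size, input pixels), `conf`, `class_id`,
#'   `class_prob`, `score`.
#' @export
decode_predictions <- function(grids, cfg, conf_threshold = cfg$conf_threshold) {
  nc <- cfg$num_classes
  K <- cfg$head$anchors_per_scale
  out <- vector("list", length(grids) * K)
  ii <- 0L
  for (s in seq_along(grids)) {
    t <- grids[[s]]
    stride <- cfg$head$strides[s]
    gxy <- grid_xy(t$h, t$w)
    anchors <- cfg$head$anchors[[s]]
    for (k in seq_len(K)) {
      off <- (k - 1L) * (5L + nc)
      tx <- sigmoid(t$x[, off + 1L])
      ty <- sigmoid(t$x[, off + 2L])
      tw <- sigmoid(t$x[, off + 3L])
      th <- sigmoid(t$x[, off + 4L])
      conf <- sigmoid(t$x[, off + 5L])
      cls <- sigmoid(t$x[, off + 5L + seq_len(nc), drop = FALSE])
      cbest <- max.col(cls, ties.method = "first")
      cprob <- cls[cbind(seq_len(nrow(cls)), cbest)]
      score <- conf * cprob
      keep <- which(score >= conf_threshold)
      if (!length(keep)) next
      ii <- ii + 1L
      out[[ii]] <- data.frame(
        x = (2 * tx[keep] - 0.5 + gxy$gx[keep]) * stride,
        y = (2 * ty[keep] - 0.5 + gxy$gy[keep]) * stride,
        w = (2 * tw[keep])^2 * anchors[k, 1L],
        h = (2 * th[keep])^2 * anchors[k, 2L],
        conf = conf[keep],
        class_id = cbest[keep],
        class_prob = cprob[keep],
        score = score[keep])
    }
  }
  det <- if (ii) do.call(rbind, out[seq_len(ii)]) else
    data.frame(x = numeric(), y = numeric(), w = numeric(), h = numeric(),
               conf = numeric(), class_id = integer(), class_prob = numeric(),
               score = numeric())
  # clip boxes to the input canvas
  if (nrow(det)) {
    W <- max(vapply(seq_along(grids), function(s)
      grids[[s]]$w * cfg$head$strides[s], 1L))
    H <- max(vapply(seq_along(grids), function(s)
      grids[[s]]$h * cfg$head$strides[s], 1L))
    x1 <- pmax(det$x - det$w / 2, 0)
    y1 <- pmax(det$y - det$h / 2, 0)
    x2 <- pmin(det$x + det$w / 2, W)
    y2 <- pmin(det$y + det$h / 2, H)
    det$x <- (x1 + x2) / 2
    det$y <- (y1 + y2) / 2
    det$w <- pmax(x2 - x1, 1e-6)
    det$h <- pmax(y2 - y1, 1e-6)
  }
  class(det) <- c("sdet_detections", "data.frame")
  det
}

#' Intersection over union of axis-aligned boxes
#'
#' Boxes are corner format `(x1, y1, x2, y2)`. Degenerate (zero-area)
#' boxes have IoU 0 by convention.
#'
#' @param a,b numeric length-4 vectors or `n x 4` / `m x 4` matrices.
#' @return If both are single boxes, a scalar; otherwise the `n x m`
#'   pairwise IoU matrix.
#' @examples
#' box_iou(c(0, 0, 10, 10), c(0, 2, 10, 12))  # 80 / 120
#' @export
box_iou <- function(a, b) {
  a <- matrix(a, ncol = 4)
  b <- matrix(b, ncol = 4)
  ix1 <- outer(a[, 1], b[, 1], pmax)
  iy1 <- outer(a[, 2], b[, 2], pmax)
  ix2 <- outer(a[, 3], b[, 3], pmin)
  iy2 <- outer(a[, 4], b[, 4], pmin)
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  areaa <- pmax(a[, 3] - a[, 1], 0) * pmax(a[, 4] - a[, 2], 0)
  areab <- pmax(b[, 3] - b[, 1], 0) * pmax(b[, 4] - b[, 2], 0)
  un <- outer(areaa, areab, "+") - inter
  iou <- ifelse(un > 0, inter / un, 0)
  if (length(iou) == 1L) iou[1, 1] else iou
}

cxcywh_to_corners <- function(d) {
  cbind(d$x - d$w / 2, d$y - d$h / 2, d$x + d$w / 2, d$y + d$h / 2)
}

#' Greedy per-class non-maximum suppression
#'
#' Detections are visited in descending score order (ties broken by lower
#' row index, so the result is deterministic); each kept box suppresses
#' remaining same-class boxes whose IoU with it exceeds the threshold.
#'
#' @param detections an `sdet_detections` data frame (columns `x, y, w, h`,
#'   `score`, `class_id`).
#' @param iou_threshold suppression threshold (default 0.45).
#' @return The surviving subset, ordered by descending score.
#' @export
nms <- function(detections, iou_threshold = 0.45) {
  n <- nrow(detections)
  if (!n) return(detections)
  corners <- cxcywh_to_corners(detections)
  ord <- order(-detections$score, seq_len(n))
  keep <- logical(n)
  alive <- rep(TRUE, n)
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    same <- which(alive & detections$class_id == detections$class_id[i])
    if (length(same)) {
      ious <- box_iou(corners[i, , drop = FALSE], corners[same, , drop = FALSE])
      alive[same[ious > iou_threshold]] <- FALSE
    }
  }
  out <- detections[keep, , drop = FALSE]
  out[order(-out$score), , drop = FALSE]
}

#' Detect objects in an image
#'
#' Letterboxes the image to the model's input size, runs the network,
#' decodes the prediction grids, applies non-maximum suppression and maps
#' the surviving boxes back to source-image coordinates.
#'
#' @param model an initialised or trained `sdet_model`.
#' @param image `H x W x {1,3}` numeric array in `[0, 1]`.
#' @param conf_threshold score threshold (defaults to the config value).
#' @param iou_threshold NMS threshold (defaults to the config value).
#' @return An `sdet_detections` data frame in source-image pixel
#'   coordinates.
#' @export
detect <- function(model, image, conf_threshold = model$cfg$conf_threshold,
                   iou_threshold = model$cfg$nms_iou) {
  lb <- letterbox(image, model$cfg$input_size)
  hg <- head_grids(model, lb$image)
  det <- decode_predictions(hg$grids, model$cfg, conf_threshold)
  det <- nms(det, iou_threshold)
  unletterbox_detections(det, lb$transform, dim(image)[1:2])
}

# ---- checkpoints --------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the model configuration (with
#' class names) and every trainable parameter and normalisation statistic.
#'
#' @param model an `sdet_model`.
#' @param path file path.
#' @return `load_checkpoint()` returns the restored `sdet_model`.
#' @export
save_checkpoint <- function(model, path) {
  st <- lapply(model_layers(model), layer_params_flat)
  saveRDS(list(cfg = model$cfg, state = st, format = 1L), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_detector(ck$cfg)
  load_state(model, ck$state)
  model
}

model_state <- function(model) lapply(model_layers(model), layer_params_flat)

load_state <- function(model, state) {
  lys <- model_layers(model)
  for (nm in names(state)) layer_params_load(lys[[nm]], state[[nm]])
  invisible(model)
}

#' Read / write a model configuration as YAML
#'
#' @param cfg a model configuration list.
#' @param path YAML file path.
#' @return `read_model_config()` returns the configuration list.
#' @export
write_model_config <- function(cfg, path) {
  out <- cfg
  out$head$anchors <- lapply(cfg$head$anchors, function(m) {
    lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$head$anchors <- lapply(cfg$head$anchors, function(rows) {
    do.call(rbind, lapply(rows, as.numeric))
  })
  for (f in c("input_size", "num_classes", "stem_channels", "dw_kernel")) {
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  cfg$stage_channels <- as.integer(cfg$stage_channels)
  cfg$stage_repeats <- as.integer(cfg$stage_repeats)
  cfg$head$strides <- as.integer(cfg$head$strides)
  cfg
}
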