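# Seeded synthetic pen-scene generator. Emulates top-view (infrared-style)
# footage of group-housed pigs: a textured floor, variable illumination,
# and 5-50 animal silhouettes drawn from five posture classes whose
# recipes key on the anatomical cue that defines each posture (folded vs
# visible legs, raised forequarters, body-on-body contact for mounting).
# Everything is a deterministic function of (config, seed).

#' Synthetic pen-scene configuration
#'
#' @param width,height canvas size in pixels. The default 640 x 640
#'   matches the network input; `farm_preset()` switches to the 2304 x
#'   1296 geometry of raw barn footage.
#' @param n_range inclusive range of instances per scene.
#' @param class_weights sampling probabilities of the five postures (STD,
#'   LOB, LOS, SIT, MOT); must sum to 1.
#' @param size_range body length range in pixels.
#' @param brightness_range per-scene global illumination multiplier range.
#' @param grayscale render single-channel infrared-like scenes (`TRUE`) or
#'   RGB.
#' @param occlusion_prob probability that an instance is deliberately
#'   placed overlapping an earlier one, and that dark rails are drawn
#'   across the pen.
#' @param seed integer seed; together with the config it fully determines
#'   the scene (R's default Mersenne-Twister generator is used
#'   throughout).
#' @return A `scene_config` list.
#' @export
scene_config <- function(width = 640L, height = 640L, n_range = c(5L, 20L),
                         class_weights = rep(0.2, 5),
                         size_range = c(64, 120),
                         brightness_range = c(0.65, 1.0),
                         grayscale = TRUE, occlusion_prob = 0.15,
                         seed = 1L) {
  stopifnot(length(class_weights) == 5L, n_range[1] <= n_range[2])
  if (abs(sum(class_weights) - 1) > 1e-8) {
    stop("invalid-config: class_weights must sum to 1")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_range = as.integer(n_range), class_weights = class_weights,
                 size_range = size_range, brightness_range = brightness_range,
                 grayscale = isTRUE(grayscale),
                 occlusion_prob = occlusion_prob, seed = as.integer(seed)),
            class = "scene_config")
}

#' @rdname scene_config
#' @export
farm_preset <- function(seed = 1L) {
  scene_config(width = 2304L, height = 1296L, n_range = c(9L, 50L),
               size_range = c(110, 200), seed = seed)
}

#' Class-imbalanced configuration preset
#'
#' Skews the class weights so sitting and mounting are rare minority
#' classes, mirroring the imbalance of real pen footage where pigs spend
#' most of the day lying.
#'
#' @param cfg a [scene_config()].
#' @return The config with weights `(0.35, 0.30, 0.25, 0.05, 0.05)`.
#' @export
imbalance_preset <- function(cfg = scene_config()) {
  cfg$class_weights <- c(0.35, 0.30, 0.25, 0.05, 0.05)
  cfg
}

#' Render a single posture silhouette
#'
#' Produces the binary silhouette mask of one instance on a local window,
#' plus an "accent" mask (the mounted animal in MOT scenes, drawn slightly
#' brighter). Recipes: STD is a narrow 3.2:1 ellipse with four detached
#' leg dots; LOB a plain wide ellipse (legs folded under the body); LOS an
#' ellipse with four leg strokes extending from one flank; SIT a wedge
#' tapering from wide hindquarters to a narrow front; MOT a body ellipse
#' crossed by a second, roughly perpendicular animal.
#'
#' @param class_id posture class 1-5 (STD, LOB, LOS, SIT, MOT).
#' @param length_px body length in pixels.
#' @param orientation body axis angle in radians.
#' @param aspect_jitter multiplicative jitter on the recipe's aspect
#'   ratio (default 1 = none).
#' @param cross_angle for MOT, angle of the mounted animal relative to the
#'   carrier (default 1.48 rad, roughly perpendicular).
#' @return A list with logical matrices `mask` and `accent` and the
#'   window's `half` size.
#' @export
render_silhouette <- function(class_id, length_px, orientation,
                              aspect_jitter = 1, cross_angle = 1.48) {
  L <- length_px
  half <- ceiling(L * 0.95)
  s <- 2L * half + 1L
  xs <- matrix(rep(seq_len(s) - half - 1L, each = s), s, s)   # x = col offset
  ys <- matrix(rep(seq_len(s) - half - 1L, times = s), s, s)  # y = row offset
  co <- cos(orientation); si <- sin(orientation)
  u <- xs * co + ys * si
  v <- -xs * si + ys * co
  ell <- function(uc, vc, a, b, uu = u, vv = v) {
    ((uu - uc) / a)^2 + ((vv - vc) / b)^2 <= 1
  }
  accent <- matrix(FALSE, s, s)
  if (class_id == 1L) {            # STD: narrow body + 4 detached leg dots
    b <- (L / 6.4) * aspect_jitter
    mask <- ell(0, 0, L / 2, b)
    r <- max(2.2, L / 11)
    gap <- max(2.2, L / 20)
    for (uu0 in c(-0.32, 0.32) * L) {
      for (sv in c(-1, 1)) {
        mask <- mask | ell(uu0, sv * (b + gap + r), r, r)
      }
    }
  } else if (class_id == 2L) {     # LOB: plain wide ellipse, legs hidden
    mask <- ell(0, 0, L / 2, (L / 3.6) * aspect_jitter)
  } else if (class_id == 3L) {     # LOS: slim body + 4 stout lateral legs
    b <- (L / 5.2) * aspect_jitter
    mask <- ell(0, 0, L / 2, b)
    wleg <- max(2.2, L / 9)
    for (uu0 in c(-0.55, -0.18, 0.18, 0.55) * (L / 2)) {
      leg <- abs(u - uu0) <= wleg / 2 & v >= 0.4 * b & v <= b + 0.24 * L
      mask <- mask | leg
    }
  } else if (class_id == 4L) {     # SIT: wedge, narrow front, wide rear
    a2 <- 0.42 * L
    wf <- L / 26
    wr <- (L / 3.7) * aspect_jitter
    frac <- pmax((u + a2) / (2 * a2), 0)
    width_u <- wf + (wr - wf) * frac^1.6   # convex taper: arrow-like wedge
    mask <- abs(u) <= a2 & abs(v) <= width_u
  } else if (class_id == 5L) {     # MOT: carrier + crossing mounted animal
    b <- L / 4.2
    mask <- ell(0, 0, L / 2, b)
    co2 <- cos(cross_angle); si2 <- sin(cross_angle)
    u2 <- (u - 0.08 * L) * co2 + (v - 0.18 * L) * si2
    v2 <- -(u - 0.08 * L) * si2 + (v - 0.18 * L) * co2
    top <- (u2 / (0.44 * L))^2 + (v2 / (0.16 * L * aspect_jitter))^2 <= 1
    accent <- top
    mask <- mask | top
  } else {
    stop("invalid-config: class_id must be 1..5")
  }
  list(mask = mask, accent = accent, half = half)
}

#' Generate one synthetic pen scene
#'
#' @param cfg a [scene_config()].
#' @return A list with `image` (numeric `H x W` matrix, or `H x W x 3` if
#'   `grayscale = FALSE`, values in `[0, 1]`), `annotations` (data frame
#'   `id, category_id, x, y, w, h, area, iscrowd`; boxes tight around each
#'   silhouette, top-left origin, clipped to canvas) and the scene
#'   dimensions.
#' @export
generate_scene <- function(cfg = scene_config()) {
  stopifnot(inherits(cfg, "scene_config"))
  H <- cfg$height; W <- cfg$width
  if (min(H, W) < cfg$size_range[1] * 0.6) {
    stop("invalid-config: canvas too small for the minimum silhouette")
  }
  with_seed(cfg$seed, {
    # floor: coarse blotches + fine grain
    coarse <- matrix(stats::rnorm(64, 0, 1), 8, 8)
    base <- 0.30 + 0.05 * resize_bilinear(coarse, H, W) +
      matrix(stats::rnorm(H * W, 0, 0.015), H, W)
    img <- base
    nopts <- seq(cfg$n_range[1], cfg$n_range[2])
    n <- nopts[sample.int(length(nopts), 1L)]
    if (cfg$n_range[2] == 0L) n <- 0L
    anns <- vector("list", n)
    centers <- matrix(0, 0, 2)
    kept <- 0L
    for (i in seq_len(n)) {
      cls <- sample.int(5L, 1L, prob = cfg$class_weights)
      L <- stats::runif(1, cfg$size_range[1], cfg$size_range[2])
      theta <- stats::runif(1, 0, 2 * pi)
      jit <- exp(stats::rnorm(1, 0, 0.06))
      cross <- stats::runif(1, 1.22, 1.92)
      margin <- 0.3 * L
      if (nrow(centers) > 0 && stats::runif(1) < cfg$occlusion_prob) {
        j <- sample.int(nrow(centers), 1L)
        ang <- stats::runif(1, 0, 2 * pi)
        cx <- centers[j, 1] + 0.6 * L * cos(ang)
        cy <- centers[j, 2] + 0.6 * L * sin(ang)
        cx <- min(max(cx, margin), W - margin)
        cy <- min(max(cy, margin), H - margin)
      } else {
        cx <- stats::runif(1, margin, W - margin)
        cy <- stats::runif(1, margin, H - margin)
      }
      sil <- render_silhouette(cls, L, theta, jit, cross)
      half <- sil$half
      rows <- (round(cy) - half):(round(cy) + half)
      cols <- (round(cx) - half):(round(cx) + half)
      inr <- rows >= 1 & rows <= H
      inc <- cols >= 1 & cols <= W
      m <- sil$mask[inr, inc, drop = FALSE]
      if (sum(m) < 25) next
      acc <- sil$accent[inr, inc, drop = FALSE]
      body_int <- stats::runif(1, 0.68, 0.92)
      patch <- img[rows[inr], cols[inc], drop = FALSE]
      patch[m] <- body_int + stats::rnorm(sum(m), 0, 0.02)
      patch[acc] <- patch[acc] + 0.12
      img[rows[inr], cols[inc]] <- patch
      rr <- range(which(rowSums(m) > 0))
      cr <- range(which(colSums(m) > 0))
      y1 <- rows[inr][rr[1]] - 1L   # 0-based COCO origin
      x1 <- cols[inc][cr[1]] - 1L
      hh <- rr[2] - rr[1] + 1L
      ww <- cr[2] - cr[1] + 1L
      kept <- kept + 1L
      anns[[kept]] <- data.frame(id = kept, category_id = cls,
                                 x = x1, y = y1, w = ww, h = hh,
                                 area = ww * hh, iscrowd = 0L)
      centers <- rbind(centers, c(cx, cy))
    }
    if (stats::runif(1) < cfg$occlusion_prob) {
      nb <- sample.int(2L, 1L)
      for (b in seq_len(nb)) {
        yb <- sample.int(H, 1L)
        hb <- max(3L, round(H / 80))
        rows <- yb:min(yb + hb, H)
        img[rows, ] <- 0.18 + stats::rnorm(length(rows) * W, 0, 0.01)
      }
    }
    bright <- stats::runif(1, cfg$brightness_range[1], cfg$brightness_range[2])
    img <- pmin(pmax(img * bright, 0), 1)
    if (!cfg$grayscale) {
      img <- array(rep(img, 3), c(H, W, 3L)) *
        array(rep(c(1, 0.97, 0.92), each = H * W), c(H, W, 3L))
    }
    ann <- if (kept) do.call(rbind, anns[seq_len(kept)]) else
      data.frame(id = integer(), category_id = integer(), x = numeric(),
                 y = numeric(), w = numeric(), h = numeric(),
                 area = numeric(), iscrowd = integer())
    list(image = img, annotations = ann, width = W, height = H,
         seed = cfg$seed)
  })
}

scene_subseed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(idx) * 7919) %% 2147483647)
}

#' Generate a dataset of scenes with COCO annotations
#'
#' Renders `n_images` scenes under per-image sub-seeds derived from the
#' config seed (a splittable counter scheme, so any image can be
#' regenerated independently), assigns them to splits, and optionally
#' writes PNG images plus one COCO JSON per split.
#'
#' @param cfg a [scene_config()].
#' @param n_images number of scenes.
#' @param split_fractions named numeric vector summing to 1, e.g.
#'   `c(train = 0.8, val = 0.2)`.
#' @param dir output directory; when `NULL` nothing is written.
#' @param keep_images keep the rendered arrays in the returned object
#'   (turn off for annotation-only studies of many large scenes).
#' @return A list with `scenes` (if kept: image, annotations, image_id),
#'   `splits` (one [annotation_set()] per split) and `index` (data frame
#'   `image_id, file_name, split`).
#' @export
generate_dataset <- function(cfg = scene_config(), n_images,
                             split_fractions = c(train = 1),
                             dir = NULL, keep_images = TRUE) {
  if (abs(sum(split_fractions) - 1) > 1e-8) {
    stop("invalid-config: split fractions must sum to 1")
  }
  counts <- floor(split_fractions * n_images)
  rem <- n_images - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  split_of <- rep(names(split_fractions), counts)
  scenes <- vector("list", n_images)
  images_df <- data.frame(id = seq_len(n_images),
                          file_name = sprintf("scene_%05d.png", seq_len(n_images)),
                          width = cfg$width, height = cfg$height)
  all_ann <- vector("list", n_images)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_len(n_images)) {
    ci <- cfg
    ci$seed <- scene_subseed(cfg$seed, i)
    sc <- generate_scene(ci)
    ann <- sc$annotations
    if (nrow(ann)) ann$image_id <- i
    all_ann[[i]] <- ann
    if (!is.null(dir)) {
      write_image(sc$image, file.path(dir, "images", images_df$file_name[i]))
    }
    if (keep_images) {
      scenes[[i]] <- list(image = sc$image, annotations = ann, image_id = i)
    }
  }
  ann_all <- do.call(rbind, all_ann)
  splits <- list()
  for (sp in unique(split_of)) {
    ids <- images_df$id[split_of == sp]
    ann_sp <- ann_all[ann_all$image_id %in% ids, , drop = FALSE]
    if (nrow(ann_sp)) ann_sp$id <- seq_len(nrow(ann_sp))
    aset <- annotation_set(images_df[images_df$id %in% ids, , drop = FALSE],
                           ann_sp)
    splits[[sp]] <- aset
    if (!is.null(dir)) {
      write_coco(aset, file.path(dir, paste0("annotations_", sp, ".json")))
    }
  }
  list(scenes = if (keep_images) scenes else NULL, splits = splits,
       index = data.frame(image_id = images_df$id,
                          file_name = images_df$file_name, split = split_of))
}

# training samples (image + centre-format boxes) from an in-memory dataset
samples_from_dataset <- function(ds) {
  lapply(ds$scenes, function(sc) {
    a <- sc$annotations
    boxes <- data.frame(cx = a$x + a$w / 2, cy = a$y + a$h / 2,
                        w = a$w, h = a$h, class_id = a$category_id)
    list(image = sc$image, boxes = boxes, image_id = sc$image_id)
  })
}

#' Hand-coded geometric posture classifier
#'
#' A deterministic reference classifier that assigns a posture class to a
#' clean silhouette mask from geometry alone: connected-component count
#' (standing legs), width-to-length ratio (mounting pairs), lateral mass
#' skewness (side-lying legs), width-taper correlation (sitting wedge)
#' and elongation (standing vs belly-lying). It certifies that the five
#' synthetic classes are separable, i.e. the detection task is learnable.
#'
#' @param mask logical matrix silhouette.
#' @return Integer class id 1-5.
#' @export
classify_silhouette <- function(mask) {
  if (count_components(mask) >= 4L) return(1L)
  pts <- which(mask, arr.ind = TRUE)
  y <- pts[, 1] - mean(pts[, 1])
  x <- pts[, 2] - mean(pts[, 2])
  cv <- stats::cov(cbind(x, y))
  ev <- eigen(cv, symmetric = TRUE)
  ax <- ev$vectors[, 1]
  u <- x * ax[1] + y * ax[2]
  v <- -x * ax[2] + y * ax[1]
  len <- diff(range(u))
  wid <- diff(range(v))
  if (wid / len > 0.72) return(5L)
  skv <- mean(v^3) / (stats::sd(v)^3 + 1e-9)
  if (abs(skv) > 0.30) return(3L)
  if (abs(stats::cor(u, abs(v))) > 0.30) return(4L)
  if (len / wid > 2.6) 1L else 2L
}

# 8-connected component count via iterative flood fill
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- 0L
  todo <- which(mask & lab == 0L)
  for (start in todo) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% nr + 1L
      cc <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; ccc <- cc + dc
        if (rr >= 1 && rr <= nr && ccc >= 1 && ccc <= nc) {
          q <- (ccc - 1L) * nr + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- comp
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  comp
}
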