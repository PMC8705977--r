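test_that("backbone emits the stride-8/16/32 pyramid with stated widths", {
  cfg <- default_model_config(320)
  m <- build_detector(cfg, init_seed = 1)
  img <- array(runif(320 * 320 * 3), c(320, 320, 3))
  pyr <- backbone_pyramid(m, img)
  expect_identical(dim(pyr$P3), c(40L, 40L, 48L))
  expect_identical(dim(pyr$P4), c(20L, 20L, 96L))
  expect_identical(dim(pyr$P5), c(10L, 10L, 192L))
  expect_identical(attr(pyr$P3, "stride"), 8L)
  expect_identical(attr(pyr$P5, "stride"), 32L)
  expect_error(backbone_pyramid(m, array(0, c(100, 100, 3))), "divisible by 32")
})

test_that("stages contain one downsampling unit plus 3/7/3 basic units", {
  m <- build_detector(default_model_config(), init_seed = NULL)
  nm <- names(m$nodes)
  for (i in 1:3) {
    expect_true(any(grepl(sprintf("^s%dd_", i), nm)))
    reps <- c(3L, 7L, 3L)[i]
    expect_true(any(grepl(sprintf("^s%db%d_", i, reps), nm)))
    expect_false(any(grepl(sprintf("^s%db%d_", i, reps + 1L), nm)))
    expect_true(sprintf("s%d_eca", i) %in% nm)
  }
})

test_that("neck outputs three fused maps at unified width and matching strides", {
  cfg <- default_model_config(320)
  m <- build_detector(cfg, init_seed = 2)
  img <- array(runif(320 * 320 * 3), c(320, 320, 3))
  nf <- neck_features(m, img)
  expect_identical(dim(nf$N3), c(40L, 40L, 48L))
  expect_identical(dim(nf$N4), c(20L, 20L, 48L))
  expect_identical(dim(nf$N5), c(10L, 10L, 48L))
})

test_that("disabling the bottom-up path reduces the neck to its top-down result", {
  cfg <- default_model_config(128)
  m <- build_detector(cfg, init_seed = 3)
  cfg2 <- cfg
  cfg2$neck$bottom_up <- FALSE
  m2 <- build_detector(cfg2, init_seed = 99)
  # share weights on the common (stem/stage/lateral/top-down) layers
  st <- shuffledet:::model_state(m)
  common <- intersect(names(st), names(shuffledet:::model_layers(m2)))
  shuffledet:::load_state(m2, st[common])
  img <- array(runif(128 * 128 * 3), c(128, 128, 3))
  fwd <- shuffledet:::detector_forward(m, img)
  nf2 <- neck_features(m2, img)
  td4 <- fwd$acts[[m$nodes[["n4_cat"]]$inputs[2]]]  # top-down N4 intermediate
  expect_equal(as.numeric(nf2$N4), as.numeric(td4$x), tolerance = 1e-12)
  n3 <- fwd$acts[[m$neck_outputs[1]]]
  expect_equal(as.numeric(nf2$N3), as.numeric(n3$x), tolerance = 1e-12)
})

test_that("upsampled coarse maps align with the next pyramid level", {
  x <- shuffledet:::tm(matrix(rnorm(5 * 5 * 2), 25, 2), 5L, 5L)
  up <- shuffledet:::upsample2_fwd(x)
  expect_identical(c(up$out$h, up$out$w), c(10L, 10L))
  a <- array(x$x, c(5, 5, 2))
  b <- array(up$out$x, c(10, 10, 2))
  expect_equal(b[2 * (1:5), 2 * (1:5), ], a)
})

test_that("heads emit K x (5 + C) channels and the full candidate count", {
  cfg <- default_model_config(320)
  m <- build_detector(cfg, init_seed = 4)
  img <- array(runif(320 * 320 * 3), c(320, 320, 3))
  hg <- shuffledet:::head_grids(m, img)
  expect_identical(ncol(hg$grids[[1]]$x), 3L * (5L + 5L))
  expect_identical(nrow(hg$grids[[3]]$x), 100L)  # 10 x 10 cells
  det <- decode_predictions(hg$grids, cfg, conf_threshold = 0)
  expect_equal(nrow(det), (40^2 + 20^2 + 10^2) * 3)
  # Detection contract: score is exactly confidence times best class prob
  expect_equal(det$score, det$conf * det$class_prob, tolerance = 1e-12)
  expect_true(all(det$score <= det$conf + 1e-12))
})

test_that("end-to-end shape contract holds at 320, 416 and 640 inputs", {
  for (sz in c(320L, 416L, 640L)) {
    cfg <- default_model_config(sz)
    m <- build_detector(cfg, init_seed = 5)
    hg <- shuffledet:::head_grids(m, array(0.5, c(sz, sz, 3)))
    for (s in 1:3) {
      S <- sz %/% cfg$head$strides[s]
      expect_identical(c(hg$grids[[s]]$h, hg$grids[[s]]$w), c(S, S))
    }
  }
})

test_that("decode applies the sigmoid parameterisation and score product", {
  cfg <- default_model_config(64)
  per <- 10L
  # all-zero logits: every cell decodes to its centre with the anchor size
  grids <- lapply(1:3, function(s) {
    S <- 64L %/% cfg$head$strides[s]
    shuffledet:::tm(matrix(0, S * S, 3L * per), S, S)
  })
  det <- decode_predictions(grids, cfg, conf_threshold = 0)
  expect_equal(unique(det$conf), 0.5)
  expect_equal(unique(det$score), 0.25)   # 0.5 confidence x 0.5 class prob
  d8 <- det[abs(det$w - cfg$head$anchors[[1]][1, 1]) < 1e-9, ]
  expect_true(all(abs((d8$x / 8) %% 1 - 0.5) < 1e-9))  # cell centres

  # explicit confidence / class probability product
  g <- grids
  g[[3]]$x[1, 5] <- qlogis(0.8)
  g[[3]]$x[1, 6] <- qlogis(0.5)
  g[[3]]$x[1, 7:10] <- -20
  det2 <- decode_predictions(g, cfg, conf_threshold = 0)
  r <- det2[det2$conf > 0.79 & det2$conf < 0.81, ]
  expect_equal(r$score[1], 0.8 * 0.5, tolerance = 1e-9)
  # zero confidence gives zero score regardless of class probabilities
  g[[3]]$x[2, 5] <- -40
  g[[3]]$x[2, 6] <- 40
  det3 <- decode_predictions(g, cfg, conf_threshold = -1)
  expect_lt(det3$score[det3$conf < 1e-15][1], 1e-15)
})

test_that("encoding a box to its anchor targets and decoding recovers it", {
  cfg <- default_model_config(128)
  set.seed(7)
  for (rep in 1:20) {
    s <- sample(1:3, 1)
    stride <- cfg$head$strides[s]
    S <- 128L %/% stride
    a <- sample(1:3, 1)
    anc <- cfg$head$anchors[[s]][a, ]
    w <- anc[1] * runif(1, 0.3, 3.9)
    h <- anc[2] * runif(1, 0.3, 3.9)
    cx <- runif(1, 0.3, S - 0.3) * stride
    cy <- runif(1, 0.3, S - 0.3) * stride
    gx <- floor(cx / stride)
    gy <- floor(cy / stride)
    tx <- qlogis((cx / stride - gx + 0.5) / 2)
    ty <- qlogis((cy / stride - gy + 0.5) / 2)
    tw <- qlogis(sqrt(w / anc[1]) / 2)
    th <- qlogis(sqrt(h / anc[2]) / 2)
    d <- shuffledet:::decode_slots(tx, ty, tw, th, gx, gy, stride, anc[1], anc[2])
    expect_equal(c(d$px, d$py, d$pw, d$ph), c(cx, cy, w, h), tolerance = 1e-4)
  }
})

test_that("box IoU matches rectangle arithmetic and conventions", {
  expect_equal(box_iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1.0)
  expect_equal(box_iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0.0)
  expect_equal(box_iou(c(0, 0, 10, 10), c(0, 2, 10, 12)), 80 / 120)
  expect_equal(box_iou(c(0, 0, 0, 10), c(0, 0, 10, 10)), 0)  # zero area
  m <- box_iou(rbind(c(0, 0, 10, 10), c(5, 5, 15, 15)), rbind(c(0, 0, 10, 10)))
  expect_identical(dim(m), c(2L, 1L))
})

test_that("greedy NMS suppresses per class with stable tie-breaks", {
  d <- data.frame(x = c(5, 5), y = c(5, 5), w = c(10, 10), h = c(10, 10),
                  conf = 1, class_id = 1L, class_prob = 1,
                  score = c(0.9, 0.8))
  expect_identical(nrow(nms(d, 0.5)), 1L)
  expect_equal(nms(d, 0.5)$score, 0.9)
  d2 <- d
  d2$x <- c(5, 50)
  expect_identical(nrow(nms(d2, 0.5)), 2L)
  # IoU 2/3 pair: suppressed at 0.5, kept at 0.7
  d3 <- data.frame(x = c(5, 5), y = c(5, 7), w = 10, h = 10, conf = 1,
                   class_id = 1L, class_prob = 1, score = c(0.9, 0.8))
  expect_identical(nrow(nms(d3, 0.5)), 1L)
  expect_identical(nrow(nms(d3, 0.7)), 2L)
  # different classes never suppress each other
  d3$class_id <- c(1L, 2L)
  expect_identical(nrow(nms(d3, 0.5)), 2L)
  expect_identical(nrow(nms(d[0, ], 0.5)), 0L)
})

test_that("NMS agrees with the quadratic reference on random detection sets", {
  set.seed(11)
  for (rep in 1:200) {
    d <- random_detections(sample(1:50, 1))
    thr <- runif(1, 0.2, 0.7)
    a <- nms(d, thr)
    b <- nms_reference(d, thr)
    expect_identical(rownames(a), rownames(b))
  }
})

test_that("checkpoints round-trip the configuration and all weights", {
  cfg <- default_model_config(64)
  m <- build_detector(cfg, init_seed = 12)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  g1 <- shuffledet:::head_grids(m, img)$grids
  g2 <- shuffledet:::head_grids(m2, img)$grids
  for (s in 1:3) expect_identical(g1[[s]]$x, g2[[s]]$x)
  unlink(f)
})

test_that("model configs survive a YAML round trip", {
  cfg <- default_model_config()
  f <- tempfile(fileext = ".yaml")
  write_model_config(cfg, f)
  cfg2 <- read_model_config(f)
  expect_equal(cfg2$head$anchors, cfg$head$anchors)
  expect_identical(cfg2$stage_repeats, cfg$stage_repeats)
  expect_identical(cfg2$input_size, cfg$input_size)
  unlink(f)
})
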