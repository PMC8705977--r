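test_that("target assignment places centred boxes and respects the ratio gate", {
  cfg <- default_model_config(128)
  # a centred 64 x 64 box lands in at least one scale's centre cell
  b <- data.frame(cx = 64, cy = 64, w = 64, h = 64, class_id = 2L)
  tg <- assign_targets(b, cfg, c(128, 128))
  n_per_scale <- vapply(tg, nrow, 1L)
  expect_gt(sum(n_per_scale), 0)
  hit <- FALSE
  for (s in seq_along(tg)) {
    if (!nrow(tg[[s]])) next
    S <- 128 %/% cfg$head$strides[s]
    hit <- hit || any(tg[[s]]$gx == 64 %/% cfg$head$strides[s] &
                        tg[[s]]$gy == 64 %/% cfg$head$strides[s])
  }
  expect_true(hit)

  # empty annotations: nothing assigned anywhere
  e <- assign_targets(b[0, ], cfg, c(128, 128))
  expect_identical(sum(vapply(e, nrow, 1L)), 0L)

  # a box exactly equal to an anchor passes its ratio test (ratio 1)
  anc <- cfg$head$anchors[[2]][2, ]
  b2 <- data.frame(cx = 60, cy = 60, w = anc[1], h = anc[2], class_id = 1L)
  tg2 <- assign_targets(b2, cfg, c(128, 128))
  expect_true(any(tg2[[2]]$anchor == 2L))
})

test_that("no anchor slot ever carries two classes", {
  cfg <- default_model_config(96)
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    b <- data.frame(cx = runif(n, 10, 86), cy = runif(n, 10, 86),
                    w = runif(n, 8, 40), h = runif(n, 8, 40),
                    class_id = sample.int(5L, n, replace = TRUE))
    tg <- assign_targets(b, cfg, c(96, 96))
    for (s in seq_along(tg)) {
      key <- paste(tg[[s]]$row, tg[[s]]$anchor)
      expect_false(anyDuplicated(key) > 0)
    }
  }
})

test_that("loss vanishes for saturated-correct predictions and degrades gracefully", {
  cfg <- default_model_config(64)
  hyp <- hyperparameters()
  per <- 10L
  grids <- lapply(1:3, function(s) {
    S <- 64L %/% cfg$head$strides[s]
    shuffledet:::tm(matrix(-30, S * S, 3L * per), S, S)  # confident background
  })
  anc <- cfg$head$anchors[[3]][2, ]
  b <- data.frame(cx = 34, cy = 30, w = anc[1], h = anc[2], class_id = 3L)
  tg <- assign_targets(b, cfg, c(64, 64))
  # write saturated-correct values at every assigned slot
  for (s in seq_along(tg)) {
    t <- tg[[s]]
    if (!nrow(t)) next
    stride <- cfg$head$strides[s]
    for (i in seq_len(nrow(t))) {
      base <- (t$anchor[i] - 1L) * per
      a <- cfg$head$anchors[[s]][t$anchor[i], ]
      grids[[s]]$x[t$row[i], base + 1L] <- qlogis((t$bx[i] / stride - t$gx[i] + 0.5) / 2)
      grids[[s]]$x[t$row[i], base + 2L] <- qlogis((t$by[i] / stride - t$gy[i] + 0.5) / 2)
      grids[[s]]$x[t$row[i], base + 3L] <- qlogis(sqrt(t$bw[i] / a[1]) / 2)
      grids[[s]]$x[t$row[i], base + 4L] <- qlogis(sqrt(t$bh[i] / a[2]) / 2)
      grids[[s]]$x[t$row[i], base + 5L] <- 30
      grids[[s]]$x[t$row[i], base + 5L + t$class_id[i]] <- 30
      grids[[s]]$x[t$row[i], base + 5L + setdiff(1:5, t$class_id[i])] <- -30
    }
  }
  ls <- compute_loss(grids, tg, cfg, hyp, grad = FALSE)
  expect_lt(ls$box, 1e-4)
  expect_lt(ls$obj, 1e-6)
  expect_lt(ls$cls, 1e-6)

  # empty targets: only the negative-objectness term remains
  empty <- assign_targets(b[0, ], cfg, c(64, 64))
  zero_grids <- lapply(1:3, function(s) {
    S <- 64L %/% cfg$head$strides[s]
    shuffledet:::tm(matrix(0, S * S, 3L * per), S, S)
  })
  ls0 <- compute_loss(zero_grids, empty, cfg, hyp, grad = FALSE)
  expect_identical(ls0$box, 0)
  expect_identical(ls0$cls, 0)
  expect_equal(ls0$obj, sum(c(4, 1, 0.4) * log(1 + exp(0))), tolerance = 1e-9)
})

test_that("gradient steps on one fixed batch drive the loss down", {
  sd <- asNamespace("shuffledet")
  set.seed(9)
  cfg <- default_model_config(64)
  cfg$head$anchors <- lapply(default_model_config(640)$head$anchors,
                             function(a) a / 10)
  m <- build_detector(cfg, init_seed = 2)
  lys <- sd$model_layers(m)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  boxes <- data.frame(cx = c(20, 44), cy = c(30, 14), w = c(14, 10),
                      h = c(11, 12), class_id = c(1L, 4L))
  tgt <- assign_targets(boxes, cfg, c(64, 64))
  hyp <- hyperparameters()
  losses <- numeric(50)
  for (step in 1:50) {
    hg <- sd$head_grids(m, img, train = TRUE, grad = TRUE)
    ls <- compute_loss(hg$grids, tgt, cfg, hyp, grad = TRUE)
    sd$backward_graph(m, hg$fwd, stats::setNames(ls$dgrids, m$outputs))
    sd$sgd_step(lys, 0.01, hyp, 1)
    losses[step] <- ls$total
  }
  expect_lt(mean(losses[41:50]), 0.5 * mean(losses[1:5]))
  expect_lt(stats::coef(stats::lm(losses ~ seq_along(losses)))[2], 0)
})

test_that("training is a seeded deterministic function of its inputs", {
  sm <- desk_samples(4, seed = 31)
  cfg <- default_model_config(96)
  r1 <- train_detector(sm, cfg, hyperparameters(), epochs = 2, seed = 5,
                       batch_size = 2)
  r2 <- train_detector(sm, cfg, hyperparameters(), epochs = 2, seed = 5,
                       batch_size = 2)
  expect_equal(r1$history$loss, r2$history$loss, tolerance = 1e-12)
  # epochs = 0 returns the freshly initialised model unchanged
  r0 <- train_detector(sm, cfg, hyperparameters(), epochs = 0, seed = 5,
                       fit_anchors = FALSE)
  m0 <- build_detector(cfg, init_seed = 5)
  expect_equal(shuffledet:::model_state(r0$model),
               shuffledet:::model_state(m0), tolerance = 1e-12)
  expect_error(train_detector(list(), cfg), "empty")
})

test_that("anchor k-means produces three ascending-area scales", {
  set.seed(13)
  wh <- cbind(runif(200, 5, 120), runif(200, 5, 120))
  an <- anchor_kmeans(wh, 9, seed = 2)
  expect_length(an, 3)
  expect_true(max(an[[1]][, 1] * an[[1]][, 2]) <=
                min(an[[3]][, 1] * an[[3]][, 2]))
  expect_error(anchor_kmeans(wh[1:5, ]), "at least")
})

test_that("fitness is the stated weighted combination", {
  expect_equal(fitness(1, 1), 1)
  expect_identical(fitness(0.8, 0.6), 0.1 * 0.8 + 0.9 * 0.6)
  for (x in c(0, 0.3, 0.77, 1)) expect_equal(fitness(x, x), x)
  expect_error(fitness_weights(0.5, 0.6), "sum to 1")
})

test_that("hyperparameter evolution is elitist and finds a mock optimum", {
  base <- hyperparameters()
  # mutation probability zero: the base set comes back untouched
  ev0 <- evolve_hyperparameters(base, 1, function(h) 0.5, mutate_prob = 0,
                                seed = 3)
  expect_equal(unclass(ev0$best), unclass(base))
  # analytic mock: negative quadratic in log-learning-rate, optimum 0.003
  mock <- function(h) -(log(h$lr0) - log(0.003))^2
  ev <- evolve_hyperparameters(base, 30, mock, seed = 7)
  expect_true(all(diff(ev$trace) >= 0))
  expect_lt(abs(log(ev$best$lr0) - log(0.003)),
            abs(log(base$lr0) - log(0.003)))
  expect_error(evolve_hyperparameters(base, 0, mock), "generations")
  expect_error(make_train_fitness(list(), list(), NULL, 0), "budget")
})

test_that("hyperparameters survive a YAML round trip", {
  h <- hyperparameters(lr0 = 0.004, box = 3.3)
  f <- tempfile(fileext = ".yaml")
  write_hyperparameters(h, f)
  expect_equal(unclass(read_hyperparameters(f)), unclass(h))
  unlink(f)
})
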