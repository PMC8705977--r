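test_that("channel_split halves channels and concatenation restores the input", {
  set.seed(1)
  x <- feature_map(array(rnorm(6 * 6 * 4), c(6, 6, 4)))
  sp <- channel_split(x)
  expect_equal(dim(sp$first)[3], 2L)
  expect_equal(dim(sp$second)[3], 2L)
  expect_identical(as.numeric(sp$first), as.numeric(x[, , 1:2]))
  expect_identical(as.numeric(sp$second), as.numeric(x[, , 3:4]))
  back <- channel_concat(sp$first, sp$second)
  expect_identical(as.numeric(back), as.numeric(x))

  x2 <- feature_map(array(rnorm(4 * 4 * 2), c(4, 4, 2)))
  sp2 <- channel_split(x2)
  expect_equal(dim(sp2$first)[3], 1L)
  expect_error(channel_split(feature_map(array(0, c(2, 2, 3)))), "even")
})

test_that("channel_shuffle realises the reshape-transpose permutation", {
  expect_identical(shuffle_permutation(4, 2), c(1L, 3L, 2L, 4L))
  set.seed(2)
  x <- feature_map(array(rnorm(3 * 3 * 4), c(3, 3, 4)))
  y <- channel_shuffle(x, 2)
  expect_identical(as.numeric(y[, , 2]), as.numeric(x[, , 3]))
  # groups = 1 is the identity
  expect_identical(as.numeric(channel_shuffle(x, 1)), as.numeric(x))
  # applying the 2-group shuffle twice on 4 channels is the identity
  expect_identical(as.numeric(channel_shuffle(y, 2)), as.numeric(x))
  expect_error(channel_shuffle(feature_map(array(0, c(2, 2, 6))), 4),
               "divisible")
})

test_that("channel_shuffle is a bijection for all tested widths and groups", {
  for (C in c(2L, 4L, 6L, 8L, 16L)) {
    for (g in c(1L, 2L)) {
      p <- shuffle_permutation(C, g)
      expect_identical(sort(p), seq_len(C))
      x <- feature_map(array(rnorm(2 * 2 * C), c(2, 2, C)))
      y <- channel_shuffle(x, g)
      inv <- order(p)
      expect_identical(as.numeric(y[, , inv, drop = FALSE]), as.numeric(x))
    }
  }
})

test_that("eca_kernel_size follows the adaptive mapping with odd clamp", {
  expect_identical(eca_kernel_size(48), 3L)
  expect_identical(eca_kernel_size(192), 5L)
  expect_identical(eca_kernel_size(2), 3L)   # formula gives 1, clamped
  ks <- vapply(1:512, eca_kernel_size, 1L)
  expect_true(all(diff(ks) >= 0))            # non-decreasing in C
  expect_true(all(ks %% 2L == 1L))
  expect_error(eca_kernel_size(0), "invalid-config")
})

test_that("eca_apply rescales channels by sigmoid weights in (0, 1)", {
  # zero kernel: every weight is sigmoid(0) = 0.5; zero input stays zero
  z <- feature_map(array(0, c(4, 4, 8)))
  mod <- eca_module(8)
  expect_equal(eca_weights(z, mod), rep(0.5, 8))
  expect_true(all(eca_apply(z, mod) == 0))

  set.seed(3)
  x <- feature_map(array(rnorm(5 * 7 * 16), c(5, 7, 16)))
  mod16 <- eca_module(16, kernel = rnorm(3))
  y <- eca_apply(x, mod16)
  expect_identical(dim(y), dim(x))
  w <- eca_weights(x, mod16)
  expect_true(all(w > 0 & w < 1))
  expect_lte(sqrt(sum(y^2)), sqrt(sum(x^2)))  # contraction
  # scaling is exactly channel-wise multiplication
  expect_equal(as.numeric(y[, , 5]), as.numeric(x[, , 5]) * w[5])

  # hand-computed 3-tap convolution on a 4-channel constant input
  xc <- feature_map(array(2, c(2, 2, 4)))
  k <- c(0.5, 1, -0.25)
  mod4 <- eca_module(4, kernel = k)
  g <- rep(2, 4)
  gp <- c(0, g, 0)
  s <- vapply(1:4, function(i) sum(k * gp[i:(i + 2)]), numeric(1))
  expect_equal(eca_weights(xc, mod4), 1 / (1 + exp(-s)))
  expect_error(eca_apply(x, mod4), "invalid-config")
})

test_that("basic compression unit preserves shape and passes the left half through", {
  blk <- compression_block(48, mode = "basic")
  expect_identical(block_parameter_count(blk, include_norm = FALSE), 1752L)
  set.seed(4)
  x <- feature_map(array(rnorm(10 * 10 * 48), c(10, 10, 48)), stride = 8L)
  y <- block_forward(blk, x)
  expect_identical(dim(y), dim(x))
  expect_identical(attr(y, "stride"), 8L)
  # zero weights: the conv branch emits zeros, the passthrough half
  # reappears (shuffled) untouched
  p <- shuffle_permutation(48, 2)
  for (i in seq_len(48)) {
    src <- p[i]
    if (src <= 24) {
      expect_equal(as.numeric(y[, , i]), as.numeric(x[, , src]))
    } else {
      expect_true(all(y[, , i] == 0))
    }
  }
  expect_error(block_forward(blk, feature_map(array(0, c(4, 4, 24)))),
               "invalid-config")
  expect_error(compression_block(47, mode = "basic"), "even")
})

test_that("downsample unit doubles channels and halves spatial dims", {
  blk <- compression_block(24, mode = "downsample", init_seed = 1)
  expect_identical(block_parameter_count(blk, include_norm = FALSE), 3504L)
  x <- feature_map(array(rnorm(32 * 32 * 24), c(32, 32, 24)), stride = 4L)
  y <- block_forward(blk, x)
  expect_identical(dim(y), c(16L, 16L, 48L))
  expect_identical(attr(y, "stride"), 8L)
  # ceiling division on odd spatial dims
  xo <- feature_map(array(rnorm(9 * 9 * 24), c(9, 9, 24)))
  expect_identical(dim(block_forward(blk, xo))[1:2], c(5L, 5L))
  expect_error(compression_block(24, out_channels = 24, mode = "downsample"),
               "invalid-config")
})

test_that("stage shape contracts hold for every backbone configuration", {
  cfg <- default_model_config()
  cin <- cfg$stem_channels
  h <- 20L
  for (i in seq_along(cfg$stage_channels)) {
    C <- cfg$stage_channels[i]
    down <- compression_block(cin, mode = "downsample", init_seed = i)
    x <- feature_map(array(rnorm(h * h * cin), c(h, h, cin)))
    y <- block_forward(down, x)
    ho <- as.integer(ceiling(h / 2))
    expect_identical(dim(y), c(ho, ho, C))
    basic <- compression_block(C, mode = "basic", init_seed = i)
    z <- block_forward(basic, y)
    expect_identical(dim(z), dim(y))
    cin <- C
    h <- ho
  }
})
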