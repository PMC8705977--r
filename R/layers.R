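# Trainable layer objects. Layers are environments (reference semantics) so
# that batch-norm running statistics and accumulated gradients update in
# place during training.

new_layer_conv <- function(cin, cout, k = 1L, stride = 1L, groups = 1L,
                           bn = TRUE, act = c("relu", "none"), bias = FALSE) {
  act <- match.arg(act)
  if (groups != 1L && !(groups == cin && cout == cin)) {
    stop("invalid-config: only depthwise grouping (groups = in = out channels) is supported")
  }
  ly <- new.env(parent = emptyenv())
  ly$kind <- "conv"
  ly$cin <- as.integer(cin)
  ly$cout <- as.integer(cout)
  ly$k <- as.integer(k)
  ly$stride <- as.integer(stride)
  ly$pad <- (as.integer(k) - 1L) %/% 2L
  ly$groups <- as.integer(groups)
  ly$act <- act
  ly$has_bn <- isTRUE(bn)
  ly$has_bias <- isTRUE(bias)
  if (groups == 1L) {
    ly$W <- matrix(0, k * k * cin, cout)
  } else {
    ly$W <- matrix(0, k * k, cout)  # depthwise: one k^2 filter per channel
  }
  if (ly$has_bias) ly$b <- numeric(cout)
  if (ly$has_bn) {
    ly$gamma <- rep(1, cout)
    ly$beta <- numeric(cout)
    ly$buf <- new.env(parent = emptyenv())
    ly$buf$rmean <- numeric(cout)
    ly$buf$rvar <- rep(1, cout)
  }
  zero_grads(ly)
  ly
}

new_layer_eca <- function(channels, gamma = 2, b = 1) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- "eca"
  ly$cin <- ly$cout <- as.integer(channels)
  ly$kk <- eca_kernel_size(channels, gamma, b)
  ly$kernel <- numeric(ly$kk)
  zero_grads(ly)
  ly
}

zero_grads <- function(ly) {
  if (ly$kind == "conv") {
    ly$gW <- 0 * ly$W
    if (ly$has_bias) ly$gb <- numeric(ly$cout)
    if (ly$has_bn) {
      ly$ggamma <- numeric(ly$cout)
      ly$gbeta <- numeric(ly$cout)
    }
  } else if (ly$kind == "eca") {
    ly$gkernel <- numeric(ly$kk)
  }
  invisible(ly)
}

init_layer <- function(ly) {
  if (ly$kind == "conv") {
    fan_in <- ly$k * ly$k * ly$cin / ly$groups
    ly$W[] <- stats::rnorm(length(ly$W), 0, sqrt(2 / fan_in))
    if (ly$has_bias) ly$b[] <- 0
    if (ly$has_bn) {
      ly$gamma[] <- 1
      ly$beta[] <- 0
      ly$buf$rmean[] <- 0
      ly$buf$rvar[] <- 1
    }
  } else if (ly$kind == "eca") {
    ly$kernel[] <- stats::rnorm(ly$kk, 0, 1 / sqrt(ly$kk))
  }
  invisible(ly)
}

layer_forward <- function(ly, t, train = FALSE, grad = FALSE) {
  if (ly$kind == "eca") return(eca_forward(ly, t, grad))
  if (ncol(t$x) != ly$cin) {
    stop(sprintf("invalid-config: layer expects %d channels, got %d", ly$cin, ncol(t$x)))
  }
  if (ly$groups == 1L) {
    cv <- conv_dense_fwd(t, ly$W, ly$k, ly$stride, ly$pad, keep_col = grad)
  } else {
    cv <- conv_dw_fwd(t, ly$W, ly$k, ly$stride, ly$pad)
    if (!grad) cv$xp <- NULL
  }
  ho <- cv$out$h
  wo <- cv$out$w
  y <- cv$out$x
  cv$out <- NULL
  if (ly$has_bias) y <- y + rep(ly$b, each = nrow(y))
  bncache <- NULL
  if (ly$has_bn) {
    # per-sample spatial statistics in training AND inference: with one
    # image per step there is no batch axis, and using the same
    # normalisation in both modes keeps them consistent
    bn <- bn_fwd(y, ly$gamma, ly$beta, ly$buf, train = TRUE)
    y <- bn$y
    bn$y <- NULL
    bncache <- bn
  }
  mask <- NULL
  if (ly$act == "relu") {
    mask <- y > 0
    y <- y * mask
  }
  list(out = tm(y, ho, wo), cache = list(cv = cv, bn = bncache, mask = mask))
}

layer_backward <- function(ly, cache, dy) {
  if (ly$kind == "eca") return(eca_backward(ly, cache, dy))
  if (!is.null(cache$mask)) dy <- dy * cache$mask
  if (ly$has_bn) {
    bb <- bn_bwd(dy, cache$bn, ly$gamma)
    ly$ggamma <- ly$ggamma + bb$dgamma
    ly$gbeta <- ly$gbeta + bb$dbeta
    dy <- bb$dx
  }
  if (ly$has_bias) ly$gb <- ly$gb + colSums(dy)
  if (ly$groups == 1L) {
    bw <- conv_dense_bwd(dy, cache$cv, ly$W)
  } else {
    bw <- conv_dw_bwd(dy, cache$cv, ly$W)
  }
  ly$gW <- ly$gW + bw$dW
  bw$dx
}

eca_forward <- function(ly, t, grad = FALSE) {
  C <- ncol(t$x)
  if (C != ly$cin) {
    stop(sprintf("invalid-config: ECA expects %d channels, got %d", ly$cin, C))
  }
  g <- colMeans(t$x)
  p <- (ly$kk - 1L) %/% 2L
  gp <- c(numeric(p), g, numeric(p))
  s <- numeric(C)
  for (tap in seq_len(ly$kk)) s <- s + ly$kernel[tap] * gp[tap:(tap + C - 1L)]
  w <- sigmoid(s)
  n <- nrow(t$x)
  list(out = tm(t$x * rep(w, each = n), t$h, t$w),
       cache = list(x = if (grad) t$x else NULL, g = g, w = w, n = n))
}

eca_backward <- function(ly, cache, dy) {
  C <- ly$cin
  n <- cache$n
  w <- cache$w
  dwvec <- colSums(dy * cache$x)
  dx <- dy * rep(w, each = n)
  ds <- dwvec * w * (1 - w)
  p <- (ly$kk - 1L) %/% 2L
  gp <- c(numeric(p), cache$g, numeric(p))
  dgp <- numeric(C + 2L * p)
  for (tap in seq_len(ly$kk)) {
    rng <- tap:(tap + C - 1L)
    ly$gkernel[tap] <- ly$gkernel[tap] + sum(ds * gp[rng])
    dgp[rng] <- dgp[rng] + ly$kernel[tap] * ds
  }
  dg <- dgp[(p + 1L):(p + C)]
  dx + rep(dg / n, each = n)
}

layer_param_count <- function(ly, include_norm = TRUE, include_bias = TRUE) {
  n <- 0L
  if (ly$kind == "conv") {
    n <- n + length(ly$W)
    if (include_bias && ly$has_bias) n <- n + length(ly$b)
    if (include_norm && ly$has_bn) n <- n + 2L * ly$cout
  } else if (ly$kind == "eca") {
    n <- n + ly$kk
  }
  n
}

layer_params_flat <- function(ly) {
  if (ly$kind == "conv") {
    out <- list(W = ly$W)
    if (ly$has_bias) out$b <- ly$b
    if (ly$has_bn) {
      out$gamma <- ly$gamma
      out$beta <- ly$beta
      out$rmean <- ly$buf$rmean
      out$rvar <- ly$buf$rvar
    }
    out
  } else {
    list(kernel = ly$kernel)
  }
}

layer_params_load <- function(ly, st) {
  if (ly$kind == "conv") {
    ly$W[] <- st$W
    if (ly$has_bias) ly$b[] <- st$b
    if (ly$has_bn) {
      ly$gamma[] <- st$gamma
      ly$beta[] <- st$beta
      ly$buf$rmean[] <- st$rmean
      ly$buf$rvar[] <- st$rvar
    }
  } else {
    ly$kernel[] <- st$kernel
  }
  invisible(ly)
}
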