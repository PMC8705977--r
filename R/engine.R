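# Internal tensor engine.
#
# Activations travel as "tmaps": a (H*W) x C double matrix in column-major
# spatial order (row index = (w-1)*H + h) plus explicit spatial dims. All
# convolutions reduce to BLAS matrix products (1x1 directly, k x k via
# im2col, depthwise via a k^2 tap loop), which keeps the engine fast enough
# for desk-scale training while remaining exactly differentiable.

tm <- function(x, h, w) list(x = x, h = h, w = w)

tm_from_array <- function(a) {
  d <- dim(a)
  if (length(d) == 2L) d <- c(d, 1L)
  tm(matrix(as.numeric(a), nrow = d[1L] * d[2L], ncol = d[3L]), d[1L], d[2L])
}

tm_to_array <- function(t) array(t$x, dim = c(t$h, t$w, ncol(t$x)))

# memoised index tables for padding / im2col
.idx_cache <- new.env(parent = emptyenv())

conv_out_dim <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

pad_interior_idx <- function(h, w, pad) {
  key <- paste0("pad", h, "x", w, "p", pad)
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  hp <- h + 2L * pad
  idx <- as.vector(outer((pad + 1L):(pad + h), (pad + seq_len(w) - 1L) * hp, "+"))
  .idx_cache[[key]] <- idx
  idx
}

pad_tmap <- function(t, pad) {
  if (pad == 0L) return(t)
  hp <- t$h + 2L * pad
  wp <- t$w + 2L * pad
  xp <- matrix(0, hp * wp, ncol(t$x))
  xp[pad_interior_idx(t$h, t$w, pad), ] <- t$x
  tm(xp, hp, wp)
}

unpad_rows <- function(dxp, h, w, pad) {
  if (pad == 0L) return(dxp)
  dxp[pad_interior_idx(h, w, pad), , drop = FALSE]
}

# im2col row-index matrix: (hout*wout) x k^2, entries are row indices into
# the padded activation matrix; tap order is (i, j) with i (row) fastest.
conv_idx <- function(h, w, k, stride, pad) {
  key <- paste0("ci", h, "x", w, "k", k, "s", stride, "p", pad)
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  hp <- h + 2L * pad
  hout <- conv_out_dim(h, k, stride, pad)
  wout <- conv_out_dim(w, k, stride, pad)
  ph0 <- (seq_len(hout) - 1L) * stride
  pw0 <- (seq_len(wout) - 1L) * stride
  base <- as.vector(outer(ph0, pw0 * hp, "+"))
  taps <- as.vector(outer(seq_len(k), (seq_len(k) - 1L) * hp, "+"))
  idx <- outer(base, taps, "+")
  out <- list(idx = idx, hout = hout, wout = wout)
  .idx_cache[[key]] <- out
  out
}

# dense convolution; weight Wcol is (k^2 * cin) x cout with rows ordered
# tap-major (all cin of tap 1, then tap 2, ...), taps ordered as conv_idx
conv_dense_fwd <- function(t, Wcol, k, stride, pad, keep_col = FALSE) {
  cin <- ncol(t$x)
  if (k == 1L && stride == 1L) {
    y <- t$x %*% Wcol
    return(list(out = tm(y, t$h, t$w), col = if (keep_col) t$x else NULL,
                k = k, stride = stride, pad = pad, h = t$h, w = t$w, cin = cin))
  }
  tp <- pad_tmap(t, pad)
  ci <- conv_idx(t$h, t$w, k, stride, pad)
  n <- nrow(ci$idx)
  col <- matrix(0, n, k * k * cin)
  for (tap in seq_len(k * k)) {
    col[, ((tap - 1L) * cin + 1L):(tap * cin)] <- tp$x[ci$idx[, tap], , drop = FALSE]
  }
  y <- col %*% Wcol
  list(out = tm(y, ci$hout, ci$wout), col = if (keep_col) col else NULL,
       k = k, stride = stride, pad = pad, h = t$h, w = t$w, cin = cin)
}

conv_dense_bwd <- function(dy, cache, Wcol) {
  k <- cache$k
  cin <- cache$cin
  if (k == 1L && cache$stride == 1L) {
    dW <- crossprod(cache$col, dy)
    dx <- dy %*% t(Wcol)
    return(list(dx = dx, dW = dW))
  }
  dW <- crossprod(cache$col, dy)
  dcol <- dy %*% t(Wcol)
  ci <- conv_idx(cache$h, cache$w, k, cache$stride, cache$pad)
  hp <- cache$h + 2L * cache$pad
  wp <- cache$w + 2L * cache$pad
  dxp <- matrix(0, hp * wp, cin)
  for (tap in seq_len(k * k)) {
    rows <- ci$idx[, tap]
    dxp[rows, ] <- dxp[rows, , drop = FALSE] +
      dcol[, ((tap - 1L) * cin + 1L):(tap * cin), drop = FALSE]
  }
  list(dx = unpad_rows(dxp, cache$h, cache$w, cache$pad), dW = dW)
}

# depthwise convolution; weight wmat is k^2 x C (tap-major rows).
# computed in channel-major (C x positions) layout so the per-tap channel
# weights broadcast by plain column-major recycling
conv_dw_fwd <- function(t, wmat, k, stride, pad) {
  C <- ncol(t$x)
  tp <- pad_tmap(t, pad)
  ci <- conv_idx(t$h, t$w, k, stride, pad)
  xpt <- t(tp$x)                       # C x padded positions
  yt <- matrix(0, C, nrow(ci$idx))
  for (tap in seq_len(k * k)) {
    yt <- yt + xpt[, ci$idx[, tap], drop = FALSE] * wmat[tap, ]
  }
  list(out = tm(t(yt), ci$hout, ci$wout), xpt = xpt,
       k = k, stride = stride, pad = pad, h = t$h, w = t$w)
}

conv_dw_bwd <- function(dy, cache, wmat) {
  k <- cache$k
  C <- ncol(dy)
  ci <- conv_idx(cache$h, cache$w, k, cache$stride, cache$pad)
  hp <- cache$h + 2L * cache$pad
  wp <- cache$w + 2L * cache$pad
  dyt <- t(dy)
  dxpt <- matrix(0, C, hp * wp)
  dW <- matrix(0, k * k, C)
  for (tap in seq_len(k * k)) {
    cols <- ci$idx[, tap]
    dW[tap, ] <- rowSums(dyt * cache$xpt[, cols, drop = FALSE])
    dxpt[, cols] <- dxpt[, cols, drop = FALSE] + dyt * wmat[tap, ]
  }
  list(dx = unpad_rows(t(dxpt), cache$h, cache$w, cache$pad), dW = dW)
}

maxpool2_fwd <- function(t) {
  h <- t$h; w <- t$w
  stopifnot(h %% 2L == 0L, w %% 2L == 0L)
  ho <- h %/% 2L; wo <- w %/% 2L
  i11 <- as.vector(outer(seq(1L, h, 2L), (seq(1L, w, 2L) - 1L) * h, "+"))
  x <- t$x
  s1 <- x[i11, , drop = FALSE]
  s2 <- x[i11 + 1L, , drop = FALSE]
  s3 <- x[i11 + h, , drop = FALSE]
  s4 <- x[i11 + h + 1L, , drop = FALSE]
  m <- pmax(s1, s2, s3, s4)
  list(out = tm(m, ho, wo), i11 = i11, h = h, w = w,
       m1 = s1 == m, m2 = s2 == m, m3 = s3 == m, m4 = s4 == m)
}

maxpool2_bwd <- function(dy, cache) {
  dx <- matrix(0, cache$h * cache$w, ncol(dy))
  i11 <- cache$i11
  m1 <- cache$m1
  m2 <- cache$m2 & !m1
  m3 <- cache$m3 & !(m1 | cache$m2)
  m4 <- cache$m4 & !(m1 | cache$m2 | cache$m3)
  dx[i11, ] <- dy * m1
  dx[i11 + 1L, ] <- dy * m2
  dx[i11 + cache$h, ] <- dy * m3
  dx[i11 + cache$h + 1L, ] <- dy * m4
  dx
}

upsample2_idx <- function(h, w) {
  key <- paste0("up", h, "x", w)
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  idx <- as.vector(outer(rep(seq_len(h), each = 2L),
                         (rep(seq_len(w), each = 2L) - 1L) * h, "+"))
  .idx_cache[[key]] <- idx
  idx
}

upsample2_fwd <- function(t) {
  idx <- upsample2_idx(t$h, t$w)
  list(out = tm(t$x[idx, , drop = FALSE], 2L * t$h, 2L * t$w),
       h = t$h, w = t$w)
}

upsample2_bwd <- function(dy, cache) {
  idx <- upsample2_idx(cache$h, cache$w)
  dx <- rowsum(dy, group = idx)
  dimnames(dx) <- NULL
  dx
}

bn_fwd <- function(x, gamma, beta, buf, train, momentum = 0.1, eps = 1e-5) {
  n <- nrow(x)
  C <- ncol(x)
  if (train) {
    mu <- colMeans(x)
    v <- colMeans(x * x) - mu * mu
    v[v < 0] <- 0
    buf$rmean <- (1 - momentum) * buf$rmean + momentum * mu
    buf$rvar <- (1 - momentum) * buf$rvar + momentum * v * n / max(n - 1L, 1L)
  } else {
    mu <- buf$rmean
    v <- buf$rvar
  }
  invstd <- 1 / sqrt(v + eps)
  # column-constant broadcasts by column-major recycling (rep each = n)
  xhat <- (x - rep(mu, each = n)) * rep(invstd, each = n)
  y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(y = y, xhat = xhat, invstd = invstd, buf = buf, train = train)
}

bn_bwd <- function(dy, cache, gamma) {
  n <- nrow(dy)
  C <- ncol(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  g <- gamma * cache$invstd
  if (cache$train) {
    dx <- (dy - rep(dbeta / n, each = n) - xhat * rep(dgamma / n, each = n)) *
      rep(g, each = n)
  } else {
    dx <- dy * rep(g, each = n)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
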