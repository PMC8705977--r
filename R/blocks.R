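#' Feature maps
#'
#' A feature map is a dense `H x W x C` activation array together with the
#' downsampling stride of the map relative to the network input. Feature
#' maps are the currency of the backbone building blocks: channel
#' split/shuffle, the symmetric 5x5 depthwise compression blocks and the
#' efficient channel attention (ECA) module all consume and produce them.
#'
#' @param values numeric array `H x W x C` (a matrix is treated as `C = 1`).
#' @param stride integer downsampling factor relative to the network input;
#'   must be a power of two in `{1, 2, 4, 8, 16, 32}`.
#' @return An object of class `feature_map`.
#' @examples
#' x <- feature_map(array(rnorm(8 * 8 * 4), c(8, 8, 4)))
#' dim(x)
#' @export
feature_map <- function(values, stride = 1L) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  d <- dim(values)
  if (any(d < 1L)) stop("invalid-config: feature map dimensions must be >= 1")
  if (!stride %in% c(1L, 2L, 4L, 8L, 16L, 32L)) {
    stop("invalid-config: stride must be one of 1, 2, 4, 8, 16, 32")
  }
  structure(array(as.numeric(values), d), stride = as.integer(stride),
            class = c("feature_map", "array"))
}

#' @export
print.feature_map <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<feature_map %d x %d x %d, stride %d>\n",
              d[1L], d[2L], d[3L], attr(x, "stride")))
  invisible(x)
}

fm_stride <- function(x) attr(x, "stride") %||% 1L

fm_channels <- function(x) dim(x)[3L]

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a feature map into two channel halves
#'
#' The basic compression block routes the first half of the channels around
#' the convolution branch untouched and sends the second half through it.
#' Splitting is exact: concatenating the two halves with [channel_concat()]
#' recovers the input bitwise.
#'
#' @param x a [feature_map()] with an even channel count.
#' @return A list of two feature maps, `first` and `second`.
#' @export
channel_split <- function(x) {
  C <- fm_channels(x)
  if (C %% 2L != 0L) {
    stop(sprintf("invalid-config: channel_split needs an even channel count, got %d", C))
  }
  h <- C %/% 2L
  list(first = feature_map(x[, , seq_len(h), drop = FALSE], fm_stride(x)),
       second = feature_map(x[, , (h + 1L):C, drop = FALSE], fm_stride(x)))
}

#' Concatenate feature maps along the channel axis
#'
#' @param ... feature maps with identical spatial dimensions and stride.
#' @return A single feature map whose channels are the inputs' in order.
#' @export
channel_concat <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) && !is.array(parts[[1L]])) {
    parts <- parts[[1L]]
  }
  d1 <- dim(parts[[1L]])[1:2]
  for (p in parts) {
    if (!identical(dim(p)[1:2], d1)) {
      stop("invalid-input: spatial dimensions differ between concatenated maps")
    }
  }
  vals <- array(unlist(lapply(parts, as.numeric), use.names = FALSE),
                c(d1, sum(vapply(parts, fm_channels, 1L))))
  feature_map(vals, fm_stride(parts[[1L]]))
}

#' Channel shuffle permutation
#'
#' The permutation realised by reshaping `C` channels to a `groups x
#' (C/groups)` matrix, transposing and flattening. With two groups this
#' interleaves the two halves produced by [channel_split()], so information
#' crosses branch boundaries as blocks are stacked.
#'
#' @param channels total channel count `C`.
#' @param groups number of groups; must divide `channels`.
#' @return An integer vector `p` such that shuffled channel `i` is input
#'   channel `p[i]`.
#' @examples
#' shuffle_permutation(4, 2)  # 1 3 2 4
#' @export
shuffle_permutation <- function(channels, groups = 2L) {
  if (channels %% groups != 0L) {
    stop(sprintf("invalid-config: %d channels not divisible by %d groups",
                 channels, groups))
  }
  as.vector(matrix(seq_len(channels), nrow = channels %/% groups, byrow = TRUE))
}

#' Shuffle the channels of a feature map
#'
#' Applies the deterministic reshape-transpose-flatten permutation of
#' [shuffle_permutation()]. Values are untouched; only channel order
#' changes, and the operation is a bijection.
#'
#' @inheritParams channel_split
#' @param groups number of shuffle groups (default 2, matching the two-way
#'   split of the compression block).
#' @return A feature map with permuted channels.
#' @export
channel_shuffle <- function(x, groups = 2L) {
  p <- shuffle_permutation(fm_channels(x), groups)
  feature_map(x[, , p, drop = FALSE], fm_stride(x))
}

#' Adaptive ECA kernel size
#'
#' Efficient channel attention picks the size of its 1-D convolution from
#' the channel dimension: `k = floor(|log2(C)/gamma + b/gamma|)`, bumped to
#' the next odd integer and clamped to at least 3 so the attention always
#' mixes information across neighbouring channels.
#'
#' @param channels channel count `C` (>= 1).
#' @param gamma kernel-mapping divisor (default 2).
#' @param b kernel-mapping offset (default 1).
#' @return An odd integer kernel size `k >= 3`.
#' @examples
#' eca_kernel_size(48)   # 3
#' eca_kernel_size(192)  # 5
#' @export
eca_kernel_size <- function(channels, gamma = 2, b = 1) {
  if (length(channels) != 1L || channels < 1) {
    stop("invalid-config: channel count must be a single value >= 1")
  }
  k <- floor(abs(log2(channels) / gamma + b / gamma))
  if (k %% 2 == 0) k <- k + 1
  as.integer(max(k, 3))
}

#' Efficient channel attention module
#'
#' ECA reweights channels without dimensionality reduction: the feature map
#' is globally average pooled to a length-`C` vector, a 1-D convolution of
#' adaptive odd size `k` (zero padded by `(k-1)/2`) mixes neighbouring
#' channels, and a sigmoid turns the result into per-channel weights in
#' `(0, 1)` that rescale the input map.
#'
#' @param channels channel count the module operates on.
#' @param gamma,b kernel-size mapping constants, see [eca_kernel_size()].
#' @param kernel optional numeric vector of 1-D convolution weights of
#'   length `eca_kernel_size(channels, gamma, b)`; defaults to zeros, which
#'   yields neutral weights of 0.5 everywhere.
#' @return An `eca_module` object.
#' @export
eca_module <- function(channels, gamma = 2, b = 1, kernel = NULL) {
  ly <- new_layer_eca(channels, gamma, b)
  if (!is.null(kernel)) {
    if (length(kernel) != ly$kk) {
      stop(sprintf("invalid-config: kernel must have length %d", ly$kk))
    }
    ly$kernel[] <- kernel
  }
  structure(list(layer = ly, channels = as.integer(channels),
                 gamma = gamma, b = b, k = ly$kk),
            class = "eca_module")
}

#' Apply efficient channel attention
#'
#' @param x a [feature_map()] whose channel count matches the module.
#' @param module an [eca_module()].
#' @return The input feature map rescaled channel-wise by the attention
#'   weights; same shape and stride as `x`.
#' @export
eca_apply <- function(x, module) {
  stopifnot(inherits(module, "eca_module"))
  t <- tm_from_array(x)
  out <- eca_forward(module$layer, t)$out
  feature_map(tm_to_array(out), fm_stride(x))
}

#' ECA attention weights for a feature map
#'
#' Returns the per-channel sigmoid weights the module would scale `x` by.
#'
#' @inheritParams eca_apply
#' @return Numeric vector of length `C`, each entry strictly in `(0, 1)`.
#' @export
eca_weights <- function(x, module) {
  ly <- module$layer
  g <- colMeans(tm_from_array(x)$x)
  p <- (ly$kk - 1L) %/% 2L
  gp <- c(numeric(p), g, numeric(p))
  s <- numeric(length(g))
  for (tap in seq_len(ly$kk)) s <- s + ly$kernel[tap] * gp[tap:(tap + length(g) - 1L)]
  sigmoid(s)
}

#' Symmetric 5x5 depthwise compression block
#'
#' The backbone's building unit, in two flavours. The *basic* unit splits
#' the channels in half, passes the first half through untouched and sends
#' the second half through a 1x1 convolution, a 5x5 depthwise convolution
#' (stride 1) and another 1x1 convolution; the halves are concatenated and
#' channel-shuffled. The *downsample* unit skips the split and runs two
#' symmetric branches over all input channels, each 1x1 -> 5x5 depthwise
#' (stride 2) -> 1x1, doubling the channel count and halving the spatial
#' dimensions. Every convolution is followed by batch normalisation; 1x1
#' convolutions additionally use a ReLU (none after the depthwise).
#'
#' @param in_channels input channel count (even for `mode = "basic"`).
#' @param out_channels output channel count; defaults to `in_channels` for
#'   basic units and `2 * in_channels` for downsample units, the only
#'   values the block admits.
#' @param mode `"basic"` or `"downsample"`.
#' @param dw_kernel odd depthwise kernel size (default 5).
#' @param init_seed optional seed; when given, weights are initialised with
#'   Kaiming-style random draws, otherwise they are zero.
#' @return A `compression_block` object usable with [block_forward()].
#' @export
compression_block <- function(in_channels, out_channels = NULL,
                              mode = c("basic", "downsample"),
                              dw_kernel = 5L, init_seed = NULL) {
  mode <- match.arg(mode)
  if (dw_kernel %% 2L != 1L) stop("invalid-config: dw_kernel must be odd")
  in_channels <- as.integer(in_channels)
  if (mode == "basic") {
    if (in_channels %% 2L != 0L) {
      stop("invalid-config: basic unit needs an even input channel count")
    }
    if (is.null(out_channels)) out_channels <- in_channels
    if (out_channels != in_channels) {
      stop("invalid-config: basic unit requires out_channels == in_channels")
    }
    cb <- in_channels %/% 2L
    branch <- make_branch(cb, dw_kernel, stride = 1L)
    blk <- list(mode = mode, in_channels = in_channels,
                out_channels = as.integer(out_channels),
                dw_kernel = as.integer(dw_kernel), branch = branch)
  } else {
    if (is.null(out_channels)) out_channels <- 2L * in_channels
    if (out_channels != 2L * in_channels) {
      stop("invalid-config: downsample unit requires out_channels == 2 * in_channels")
    }
    blk <- list(mode = mode, in_channels = in_channels,
                out_channels = as.integer(out_channels),
                dw_kernel = as.integer(dw_kernel),
                branch = make_branch(in_channels, dw_kernel, stride = 2L),
                branch2 = make_branch(in_channels, dw_kernel, stride = 2L))
  }
  blk <- structure(blk, class = "compression_block")
  if (!is.null(init_seed)) {
    with_seed(init_seed, for (ly in block_layers(blk)) init_layer(ly))
  }
  blk
}

make_branch <- function(c, dw_kernel, stride) {
  list(pre = new_layer_conv(c, c, k = 1L, act = "relu"),
       dw = new_layer_conv(c, c, k = dw_kernel, stride = stride,
                           groups = c, act = "none"),
       post = new_layer_conv(c, c, k = 1L, act = "relu"))
}

block_layers <- function(blk) {
  if (blk$mode == "basic") unname(blk$branch)
  else c(unname(blk$branch), unname(blk$branch2))
}

branch_forward <- function(branch, t, train = FALSE) {
  t <- layer_forward(branch$pre, t, train)$out
  t <- layer_forward(branch$dw, t, train)$out
  layer_forward(branch$post, t, train)$out
}

#' Run a compression block over a feature map
#'
#' @param block a [compression_block()].
#' @param x a [feature_map()] with `block$in_channels` channels.
#' @param train logical; use batch statistics (`TRUE`) or running averages
#'   (`FALSE`) in the normalisation layers.
#' @return A feature map; basic units preserve shape, downsample units halve
#'   the spatial dimensions (ceiling division) and double the channels.
#' @export
block_forward <- function(block, x, train = FALSE) {
  stopifnot(inherits(block, "compression_block"))
  if (fm_channels(x) != block$in_channels) {
    stop(sprintf("invalid-config: block expects %d channels, got %d",
                 block$in_channels, fm_channels(x)))
  }
  t <- tm_from_array(x)
  if (block$mode == "basic") {
    cb <- block$in_channels %/% 2L
    left <- tm(t$x[, seq_len(cb), drop = FALSE], t$h, t$w)
    right <- tm(t$x[, (cb + 1L):(2L * cb), drop = FALSE], t$h, t$w)
    right <- branch_forward(block$branch, right, train)
    y <- tm(cbind(left$x, right$x), t$h, t$w)
    stride_out <- fm_stride(x)
  } else {
    b1 <- branch_forward(block$branch, t, train)
    b2 <- branch_forward(block$branch2, t, train)
    y <- tm(cbind(b1$x, b2$x), b1$h, b1$w)
    stride_out <- fm_stride(x) * 2L
  }
  p <- shuffle_permutation(ncol(y$x), 2L)
  feature_map(array(y$x[, p], c(y$h, y$w, ncol(y$x))), stride_out)
}

#' Parameter count of a compression block
#'
#' Closed-form count of the block's trainable parameters (convolution
#' weights, optionally the normalisation scale/offset pairs).
#'
#' @param block a [compression_block()].
#' @param include_norm count the batch-norm `gamma`/`beta` pairs too.
#' @return Integer parameter count.
#' @export
block_parameter_count <- function(block, include_norm = TRUE) {
  sum(vapply(block_layers(block), layer_param_count, 1L,
             include_norm = include_norm))
}

# run code under a temporary seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
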