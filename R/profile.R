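#' Analytic parameter and FLOP profiler
#'
#' Walks the detector graph symbolically, propagating spatial dimensions
#' from the input size, and tallies per-layer trainable parameters and
#' multiply-accumulate operations. Convolution parameters are
#' `k^2 * Cin * Cout / groups` (plus `Cout` for a bias and `2 * Cout` for a
#' normalisation scale/offset pair); convolution MACs are the weight count
#' (without bias) times the output area. Normalisation and activation ops
#' are excluded from the MAC tally. GFLOPs are reported under the
#' 1 MAC = 1 FLOP convention that framework profilers customarily use;
#' `gflops_double` gives the 2x convention.
#'
#' @param cfg a model configuration list (or an `sdet_model`, whose config
#'   is used).
#' @param input_size input resolution to count MACs at; defaults to the
#'   config's.
#' @return An object of class `sdet_profile`: a per-layer data frame plus
#'   totals (`total_params`, `params_m`, `total_macs`, `gflops`,
#'   `gflops_double`).
#' @examples
#' pr <- profile_model(default_model_config())
#' pr$params_m  # ~0.358
#' pr$gflops    # ~1.1
#' @export
profile_model <- function(cfg, input_size = NULL) {
  if (inherits(cfg, "sdet_model")) cfg <- cfg$cfg
  if (is.null(input_size)) input_size <- cfg$input_size
  input_size <- as.integer(input_size)
  if (input_size %% 32L != 0L) {
    stop("invalid-input: input_size must be divisible by 32")
  }
  model <- build_detector(cfg)
  dims <- new.env(parent = emptyenv())
  rows <- vector("list", length(model$nodes))
  i <- 0L
  for (nd in model$nodes) {
    dm <- switch(nd$kind,
      input = c(input_size, input_size, 3L),
      conv = {
        ly <- nd$layer
        din <- dims[[nd$inputs]]
        c(conv_out_dim(din[1], ly$k, ly$stride, ly$pad),
          conv_out_dim(din[2], ly$k, ly$stride, ly$pad), ly$cout)
      },
      eca = dims[[nd$inputs]],
      maxpool = {
        din <- dims[[nd$inputs]]
        c(din[1] %/% 2L, din[2] %/% 2L, din[3])
      },
      upsample = {
        din <- dims[[nd$inputs]]
        c(din[1] * 2L, din[2] * 2L, din[3])
      },
      concat = {
        ins <- lapply(nd$inputs, function(nm) dims[[nm]])
        c(ins[[1]][1:2], sum(vapply(ins, function(d) as.numeric(d[3]),
                                    numeric(1))))
      },
      slice = {
        din <- dims[[nd$inputs]]
        c(din[1:2], nd$extra$to - nd$extra$from + 1L)
      },
      shuffle = dims[[nd$inputs]])
    dims[[nd$name]] <- dm
    params <- 0
    macs <- 0
    if (nd$kind == "conv") {
      ly <- nd$layer
      wn <- ly$k^2 * ly$cin * ly$cout / ly$groups
      params <- wn +
        (if (ly$has_bias) ly$cout else 0) +
        (if (ly$has_bn) 2 * ly$cout else 0)
      macs <- wn * dm[1] * dm[2]
    } else if (nd$kind == "eca") {
      params <- nd$layer$kk
      macs <- nd$layer$kk * dm[3]
    }
    i <- i + 1L
    rows[[i]] <- data.frame(name = nd$name, kind = nd$kind,
                            out_h = dm[1], out_w = dm[2], out_c = dm[3],
                            params = params, macs = macs)
  }
  layers <- do.call(rbind, rows)
  total_params <- sum(layers$params)
  total_macs <- sum(layers$macs)
  structure(list(layers = layers,
                 total_params = total_params,
                 params_m = total_params / 1e6,
                 total_macs = total_macs,
                 gflops = total_macs / 1e9,
                 gflops_double = 2 * total_macs / 1e9,
                 input_size = as.integer(input_size)),
            class = "sdet_profile")
}

#' @export
print.sdet_profile <- function(x, ...) {
  act <- x$layers[x$layers$params > 0 | x$layers$kind %in% c("conv", "eca"), ]
  cat(sprintf("Model profile at %d x %d input\n", x$input_size, x$input_size))
  print(act[, c("name", "kind", "out_h", "out_w", "out_c", "params", "macs")],
        row.names = FALSE)
  cat(sprintf("Total: %s parameters (%.4f M), %.4f GFLOPs (1 MAC = 1 FLOP; %.4f at 2x)\n",
              format(x$total_params, big.mark = ","), x$params_m,
              x$gflops, x$gflops_double))
  invisible(x)
}

#' Brute-force parameter enumeration of an instantiated model
#'
#' Counts every trainable weight actually allocated in the model's layer
#' objects (convolution kernels, biases, normalisation scale/offset pairs
#' and attention kernels; running statistics are buffers, not parameters).
#' Serves as an independent cross-check of [profile_model()]'s closed-form
#' arithmetic.
#'
#' @param model an `sdet_model`.
#' @return Integer total parameter count.
#' @export
count_parameters <- function(model) {
  tot <- 0L
  for (ly in model_layers(model)) {
    st <- layer_params_flat(ly)
    st$rmean <- NULL
    st$rvar <- NULL
    tot <- tot + sum(lengths(st))
  }
  tot
}
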