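#' Build the per-pixel fully connected estimator
#'
#' A one-dimensional fully connected network that maps a single pixel's
#' decay curve (one input per echo) to the two parameters `(S0, T)`.
#' The stack is `n_in -> width`, four `width -> width` layers and a
#' `width -> 2` head, with ReLU between weight layers and a linear output
#' (regression targets are unbounded).  At the reference spec
#' (`n_in = 10`, `width = 64`) the network has exactly 17,474 trainable
#' parameters.
#'
#' @param n_in Number of inputs (echoes).
#' @param width Hidden-layer width.
#' @param n_out Number of outputs (2: `S0`, `T`).
#' @param seed Integer seed; identical seeds give identical initial
#'   weights.
#' @return A model object of class `t2_nn` (architecture `"nn1d"`).
#' @export
build_nn1d <- function(n_in = 10L, width = 64L, n_out = 2L, seed = 1L) {
  net <- with_seed(seed, {
    layers <- list(mod_dense(n_in, width), mod_relu())
    for (i in 1:4) {
      layers[[length(layers) + 1L]] <- mod_dense(width, width)
      layers[[length(layers) + 1L]] <- mod_relu()
    }
    layers[[length(layers) + 1L]] <- mod_dense(width, n_out)
    mod_seq(layers)
  })
  structure(list(arch = "nn1d", net = net,
                 spec = list(n_in = n_in, width = width, n_out = n_out),
                 seed = seed, schedule = NULL, trained = FALSE,
                 history = NULL),
            class = "t2_nn")
}

# One encoder/decoder stage of the U-Net, built recursively: a strided
# down block, the nested sub-network behind a channel-concatenating skip,
# and an upsampling block consuming the concatenated channels.
unet_block <- function(cin, cout, channels, strides, is_top, nres) {
  c1 <- channels[1]; s <- strides[1]
  if (length(channels) > 2L) {
    sub <- unet_block(c1, c1, channels[-1], strides[-1], FALSE, nres)
    upc <- 2L * c1
  } else {
    sub <- if (nres > 0) mod_resunit(c1, channels[2], 1L, nres)
           else mod_seq(list(mod_conv(c1, channels[2], 3L, 1L),
                             mod_bn(channels[2]), mod_prelu()))
    upc <- c1 + channels[2]
  }
  down <- if (nres > 0) mod_resunit(cin, c1, s, nres)
          else mod_seq(list(mod_conv(cin, c1, 3L, s), mod_bn(c1), mod_prelu()))
  up_layers <- list(mod_convt(upc, cout, 3L, s))
  if (!(is_top && nres == 0)) {
    up_layers[[2L]] <- mod_bn(cout)
    up_layers[[3L]] <- mod_prelu()
  }
  if (nres > 0)
    up_layers[[length(up_layers) + 1L]] <-
      mod_resunit(cout, cout, 1L, subunits = 1L, last_conv_only = is_top)
  mod_seq(list(down, mod_skip(sub), mod_seq(up_layers)))
}

#' Build the convolutional (U-Net) estimator
#'
#' A residual U-Net mapping a multi-echo stack (one channel per echo) to
#' two parameter maps `(S0, T)` of the same spatial size.  The reference
#' spec has four resolution levels with widths `[128, 128, 256, 512]`,
#' stride-2 downsampling at three stages, 3x3 convolutions throughout,
#' two-subunit residual blocks on the encoding path, batch normalization
#' and PReLU activations, and channel-concatenating skip connections;
#' it has about 6.9 million trainable parameters
#' ([count_trainable_params()] reports the exact figure, 6,950,457).
#' The network is fully convolutional, so any input whose spatial
#' dimensions are divisible by `2^(length(channels) - 1)` is accepted;
#' smaller `channels` presets give proportionally lighter models for
#' CPU-scale training.
#'
#' @param in_channels Input channels (echoes).
#' @param out_channels Output channels (2: `S0`, `T`).
#' @param channels Feature widths per resolution level.
#' @param strides Downsampling factors between levels
#'   (`length(channels) - 1` entries).
#' @param num_res_units Residual sub-units per conv block.
#' @param seed Integer seed for weight initialization.
#' @return A model object of class `t2_nn` (architecture `"cnn"`).
#' @export
build_cnn <- function(in_channels = 10L, out_channels = 2L,
                      channels = c(128L, 128L, 256L, 512L),
                      strides = c(2L, 2L, 2L), num_res_units = 2L,
                      seed = 1L) {
  if (length(strides) != length(channels) - 1L)
    stop("'strides' must have length(channels) - 1 entries")
  net <- with_seed(seed,
    unet_block(in_channels, out_channels, channels, strides, TRUE,
               num_res_units))
  structure(list(arch = "cnn", net = net,
                 spec = list(in_channels = in_channels,
                             out_channels = out_channels,
                             channels = channels, strides = strides,
                             num_res_units = num_res_units,
                             divisor = prod(strides)),
                 seed = seed, schedule = NULL, trained = FALSE,
                 history = NULL),
            class = "t2_nn")
}

#' Count trainable parameters
#'
#' Sums the sizes of all trainable tensors (weights, biases, activation
#' slopes, normalization scales/offsets) of a model; running statistics
#' are buffers, not parameters, and are excluded.
#'
#' @param model A `t2_nn` model (or a bare module).
#' @return Integer parameter count.
#' @examples
#' count_trainable_params(build_nn1d())  # 17474
#' @export
count_trainable_params <- function(model) {
  net <- if (inherits(model, "t2_nn")) model$net else model
  sum(vapply(param_refs(net),
             function(ref) length(ref$mod$params[[ref$name]]), numeric(1)))
}

#' @export
print.t2_nn <- function(x, ...) {
  cat("<t2_nn> arch:", x$arch,
      " params:", format(count_trainable_params(x), big.mark = ","),
      if (x$trained) " (trained)" else " (untrained)", "\n")
  invisible(x)
}
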