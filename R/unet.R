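# Architecture of the modified U-Net used for virtual staining.
#
# The network is the classic encoder-decoder U-Net (two 3x3 convolutions
# per level, 2x2 max-pooling, 2x2 up-convolutions, skip concatenation)
# with three modifications: batch normalization before every activation,
# feature widths reduced to a quarter of the original schedule
# (16, 32, 64, 128, 256 instead of 64 ... 1024), and a residual addition
# of the input image to the output of the last convolutional block, so
# the network learns the difference between phase and fluorescence.

#' Describe a U-Net architecture
#'
#' @param depth number of resolution levels including the bottleneck
#'   (default 5: four poolings).
#' @param base_width feature maps at the first level; widths double per
#'   level. 16 is a quarter of the original U-Net's 64.
#' @param in_channels,out_channels image channels in and out (1 and 1:
#'   one network per fluorophore).
#' @param batch_norm add batch normalization before every activation.
#' @param residual add the input to the output of the final convolution
#'   block (requires `in_channels == out_channels`).
#' @return object of class `unet_spec`.
#' @export
#' @examples
#' count_parameters(unet_spec())                  # ~1.9e6
#' count_parameters(unet_spec(base_width = 64, batch_norm = FALSE,
#'                            residual = FALSE))  # > 3e7
unet_spec <- function(depth = 5, base_width = 16, in_channels = 1,
                      out_channels = 1, batch_norm = TRUE, residual = TRUE) {
  stopifnot(depth >= 1, base_width >= 1, in_channels >= 1, out_channels >= 1)
  if (residual && in_channels != out_channels) {
    stop("residual addition needs in_channels == out_channels")
  }
  structure(list(depth = as.integer(depth),
                 base_width = as.integer(base_width),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 batch_norm = isTRUE(batch_norm),
                 residual = isTRUE(residual)),
            class = "unet_spec")
}

#' @export
print.unet_spec <- function(x, ...) {
  cat("<unet_spec> depth ", x$depth, ", widths ",
      paste(x$base_width * 2^(seq_len(x$depth) - 1), collapse = "-"),
      if (x$batch_norm) ", batch norm" else "",
      if (x$residual) ", residual" else "", "\n", sep = "")
  invisible(x)
}

#' @noRd
unet_width <- function(spec, d) spec$base_width * 2L^(d - 1L)

#' @noRd
init_conv <- function(cin, cout, sd = sqrt(2 / (9 * cin)), bn = FALSE,
                      zero = FALSE) {
  W <- matrix(if (zero) 0 else stats::rnorm(9 * cin * cout, 0, sd),
              9 * cin, cout)
  layer <- list(W = W, b = numeric(cout))
  if (bn) {
    layer$bn <- list(gamma = rep(1, cout), beta = numeric(cout),
                     rmean = numeric(cout), rvar = rep(1, cout))
  }
  layer
}

#' @noRd
init_upconv <- function(cin, cout) {
  list(W = matrix(stats::rnorm(4 * cin * cout, 0, sqrt(2 / (4 * cin))),
                  4 * cin, cout),
       b = numeric(cout))
}

#' Instantiate a U-Net model with freshly initialised weights
#'
#' Convolution weights use He-normal initialisation; the final 1x1
#' convolution is zero-initialised when the residual path is enabled, so
#' an untrained residual model is exactly the identity map.
#'
#' @param spec a [unet_spec()].
#' @param seed integer seed controlling the weight initialisation.
#' @return object of class `unet_model` with elements `spec`, `par`
#'   (nested parameter list) and `norm` (normalization ranges, filled at
#'   training time so checkpoints are self-describing).
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  par <- withr::with_seed(seed, {
    enc <- vector("list", spec$depth)
    for (d in seq_len(spec$depth)) {
      cin <- if (d == 1) spec$in_channels else unet_width(spec, d - 1)
      w <- unet_width(spec, d)
      enc[[d]] <- list(c1 = init_conv(cin, w, bn = spec$batch_norm),
                       c2 = init_conv(w, w, bn = spec$batch_norm))
    }
    dec <- vector("list", max(spec$depth - 1, 0))
    for (d in seq_len(spec$depth - 1)) {
      w <- unet_width(spec, d)
      dec[[d]] <- list(up = init_upconv(unet_width(spec, d + 1), w),
                       c1 = init_conv(2 * w, w, bn = spec$batch_norm),
                       c2 = init_conv(w, w, bn = spec$batch_norm))
    }
    final <- list(W = matrix(if (spec$residual) 0 else
                               stats::rnorm(spec$base_width * spec$out_channels,
                                            0, sqrt(2 / spec$base_width)),
                             spec$base_width, spec$out_channels),
                  b = numeric(spec$out_channels))
    list(enc = enc, dec = dec, final = final)
  })
  structure(list(spec = spec, par = par, norm = NULL, seed = as.integer(seed)),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  print(x$spec)
  cat("  ", format(count_parameters(x), big.mark = ","),
      " trainable parameters\n", sep = "")
  invisible(x)
}

#' Count trainable parameters
#'
#' Sums every trainable scalar: convolution and up-convolution weights and
#' biases, the final 1x1 convolution, and batch-norm scale and shift.
#' Batch-norm running statistics are buffers, not parameters, and are
#' excluded.
#'
#' @param model a `unet_model` or a `unet_spec` (a throwaway model is
#'   built for counting).
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "unet_spec")) model <- build_model(model, seed = 0L)
  stopifnot(inherits(model, "unet_model"))
  n <- 0L
  count_layer <- function(l) {
    n <- length(l$W) + length(l$b)
    if (!is.null(l$bn)) n <- n + length(l$bn$gamma) + length(l$bn$beta)
    n
  }
  for (lv in model$par$enc) n <- n + count_layer(lv$c1) + count_layer(lv$c2)
  for (lv in model$par$dec) {
    n <- n + count_layer(lv$up) + count_layer(lv$c1) + count_layer(lv$c2)
  }
  n + count_layer(model$par$final)
}

#' Zero the final convolutional block of a model
#'
#' With the residual path enabled, a model whose final block is zero
#' computes exactly the identity map; useful as a sanity probe of the
#' residual wiring.
#'
#' @param model a `unet_model`.
#' @return the model with `final$W` and `final$b` set to zero.
#' @export
zero_final_block <- function(model) {
  stopifnot(inherits(model, "unet_model"))
  model$par$final$W[] <- 0
  model$par$final$b[] <- 0
  model
}
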