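#' 1-D CNN architecture configuration
#'
#' The classifier is a compact one-dimensional convolutional network: four
#' stride-1 convolutional layers (kernel `kernel_size`, length-preserving
#' padding) each followed by Tanh and a max-pool of `pool_size`, a flatten,
#' three Tanh fully connected layers, and a linear 2-class output. With the
#' reference hyperparameters (channels 1->4->8->16->16, kernel 3, pool 4,
#' fully connected widths 128/38/4, input length 1024) the network has
#' exactly 14,692 trainable parameters.
#'
#' @param input_len Segment length consumed by the network (default 1024);
#'   must be divisible by `pool_size^4`.
#' @param conv_channels Output channels of the four convolution stages.
#' @param kernel_size Odd convolution kernel length (default 3).
#' @param pool_size Max-pooling factor per stage (default 4).
#' @param fc_widths Widths of the three hidden fully connected layers.
#' @param n_out Output classes (default 2).
#' @return An object of class `cnn_config`.
#' @examples
#' count_parameters(cnn_config())
#' @export
cnn_config <- function(input_len = 1024L, conv_channels = c(4L, 8L, 16L, 16L),
                       kernel_size = 3L, pool_size = 4L,
                       fc_widths = c(128L, 38L, 4L), n_out = 2L) {
  input_len <- as.integer(input_len)
  conv_channels <- as.integer(conv_channels)
  kernel_size <- as.integer(kernel_size)
  pool_size <- as.integer(pool_size)
  fc_widths <- as.integer(fc_widths)
  n_out <- as.integer(n_out)
  if (length(conv_channels) != 4L)
    stop("the architecture has exactly four convolution/pooling stages")
  if (length(fc_widths) != 3L)
    stop("the architecture has three hidden fully connected layers (four FC layers counting the output)")
  if (kernel_size < 1L || kernel_size %% 2L == 0L)
    stop("kernel_size must be odd (length-preserving padding)")
  if (pool_size < 2L) stop("pool_size must be >= 2")
  if (input_len %% pool_size^4 != 0L)
    stop(sprintf("input_len (%d) must be divisible by pool_size^4 (%d)",
                 input_len, pool_size^4))
  if (any(conv_channels < 1L) || any(fc_widths < 1L) || n_out < 2L)
    stop("layer widths must be positive (n_out >= 2)")
  structure(list(input_len = input_len, conv_channels = conv_channels,
                 kernel_size = kernel_size, pool_size = pool_size,
                 fc_widths = fc_widths, n_out = n_out,
                 activation = "tanh"),
            class = "cnn_config")
}

#' @export
print.cnn_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<cnn_config> input %d -> conv(k=%d) channels %s with pool %d",
    " -> fc %s -> %d classes (Tanh)\n  trainable parameters: %d\n"),
    x$input_len, x$kernel_size, paste(x$conv_channels, collapse = "/"),
    x$pool_size, paste(x$fc_widths, collapse = "/"), x$n_out,
    count_parameters(x)))
  invisible(x)
}

#' Closed-form trainable-parameter count
#'
#' Sums weights and biases layer by layer: each convolution contributes
#' `(k*C_in + 1)*C_out`, each fully connected layer `(W_in + 1)*W_out`. The
#' flattened feature length entering the first fully connected layer is
#' `conv_channels[4] * input_len / pool_size^4`. For the reference
#' configuration this totals 14,692, and [build_model()] asserts that the
#' instantiated network carries exactly this many parameters.
#'
#' @param config A [cnn_config()].
#' @return Integer parameter total.
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  k <- config$kernel_size
  ch <- c(1L, config$conv_channels)
  conv <- sum((k * ch[-length(ch)] + 1L) * ch[-1L])
  flat <- config$conv_channels[4L] * config$input_len %/% config$pool_size^4
  w <- c(flat, config$fc_widths, config$n_out)
  fc <- sum((w[-length(w)] + 1L) * w[-1L])
  as.integer(conv + fc)
}
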