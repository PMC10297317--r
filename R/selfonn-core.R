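#' @useDynLib selfonn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx acf fft median optimize quantile rbinom rnorm runif sd setNames var
#' @importFrom utils head read.csv tail write.csv
"_PACKAGE"

#' Specification of a 1D Self-ONN operational layer
#'
#' A Self-ONN (self-organized operational neural network) layer generalizes
#' a 1D convolution: each generative neuron holds a `K x Q` kernel per input
#' channel and computes a sum of convolutions over elementwise powers
#' `x, x^2, ..., x^Q` of its input — a truncated Taylor-series non-linearity
#' learned per tap.  With `taylor_order = 1` the layer reduces exactly to a
#' standard convolution.
#'
#' @param in_channels,out_channels positive integers, channel counts.
#' @param kernel_size positive integer `K`, taps per kernel.
#' @param taylor_order positive integer `Q`, number of Taylor power terms.
#' @param stride positive integer step between output positions.
#' @param padding non-negative integer, zero-padding samples per side.
#' @param bias logical, include an additive bias per output channel.
#'   Convention here: layers immediately followed by batch normalization
#'   omit the bias (it is redundant with the normalization shift).
#' @return An object of class `selfonn_layer_spec`.
#' @examples
#' selfonn_layer_spec(1, 8, kernel_size = 7, taylor_order = 3, stride = 2,
#'                    padding = 3, bias = FALSE)
#' @export
selfonn_layer_spec <- function(in_channels, out_channels, kernel_size,
                               taylor_order = 1L, stride = 1L,
                               padding = 0L, bias = TRUE) {
  spec <- list(in_channels = as.integer(in_channels),
               out_channels = as.integer(out_channels),
               kernel_size = as.integer(kernel_size),
               taylor_order = as.integer(taylor_order),
               stride = as.integer(stride),
               padding = as.integer(padding),
               bias = isTRUE(bias))
  with(spec, {
    if (in_channels < 1L || out_channels < 1L) stop("channel counts must be positive")
    if (kernel_size < 1L) stop("kernel_size must be >= 1")
    if (taylor_order < 1L) stop("taylor_order (Q) must be >= 1")
    if (stride < 1L) stop("stride must be >= 1")
    if (padding < 0L) stop("padding must be >= 0")
  })
  structure(spec, class = "selfonn_layer_spec")
}

#' @export
print.selfonn_layer_spec <- function(x, ...) {
  cat(sprintf("Self-ONN layer spec: %d -> %d channels, K=%d, Q=%d, stride=%d, pad=%d, bias=%s\n",
              x$in_channels, x$out_channels, x$kernel_size, x$taylor_order,
              x$stride, x$padding, x$bias))
  invisible(x)
}

#' Number of learnable parameters of a Self-ONN layer
#'
#' `out * in * K * Q` kernel weights plus one bias per output channel when
#' the layer has a bias.
#'
#' @param spec a [selfonn_layer_spec()].
#' @return integer parameter count.
#' @export
n_layer_parameters <- function(spec) {
  stopifnot(inherits(spec, "selfonn_layer_spec"))
  spec$out_channels * spec$in_channels * spec$kernel_size * spec$taylor_order +
    if (spec$bias) spec$out_channels else 0L
}

#' Initialize a generative-neuron kernel
#'
#' Deterministic, per-power fan-in-scaled uniform initialization: every
#' weight is drawn from `U(-s, s)` with `s = 1 / sqrt(in * K * Q)`; the bias
#' starts at zero.  The scale shrinks with the Taylor order so the summed
#' power series stays well-conditioned for inputs in `[-1, 1]`.
#'
#' @param spec a [selfonn_layer_spec()].
#' @param seed integer seed; identical seeds give bitwise-identical kernels.
#' @return A `generative_neuron_kernel`: list with `weights`, an array of
#'   dim `c(out, in, K, Q)` indexed (out channel, in channel, tap, power),
#'   and `bias`, a length-`out` vector (`NULL` when the layer has no bias).
#' @export
init_kernel <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "selfonn_layer_spec"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  s <- kernel_init_scale(spec)
  n <- spec$out_channels * spec$in_channels * spec$kernel_size * spec$taylor_order
  w <- array(runif(n, -s, s),
             dim = c(spec$out_channels, spec$in_channels,
                     spec$kernel_size, spec$taylor_order))
  structure(list(weights = w,
                 bias = if (spec$bias) numeric(spec$out_channels) else NULL),
            class = "generative_neuron_kernel")
}

#' Uniform initialization half-width for a layer
#' @param spec a [selfonn_layer_spec()].
#' @return the scale `1 / sqrt(in * K * Q)`.
#' @export
kernel_init_scale <- function(spec) {
  1 / sqrt(spec$in_channels * spec$kernel_size * spec$taylor_order)
}

# Coerce input to a (channels, length, batch) array, remembering the
# original rank so results can be returned in kind.
as_feature_map <- function(x) {
  if (is.numeric(x) && is.null(dim(x))) {
    list(x = array(x, dim = c(1L, length(x), 1L)), rank = 1L)
  } else if (is.matrix(x)) {
    list(x = array(x, dim = c(nrow(x), ncol(x), 1L)), rank = 2L)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    list(x = x, rank = 3L)
  } else stop("input must be a numeric vector, a (channel x time) matrix, ",
              "or a (channel x time x batch) array")
}

restore_rank <- function(y, rank) {
  if (rank == 1L) as.numeric(y[1L, , 1L])
  else if (rank == 2L) y[, , 1L, drop = TRUE]
  else y
}

#' Stack elementwise Taylor powers of a feature map
#'
#' Returns the powers `x^1 ... x^Q` that feed the Q parallel convolutions of
#' the operational layer; slice `q = 1` is the input itself.
#'
#' @param x numeric vector, matrix (channel x time), or array
#'   (channel x time x batch).
#' @param Q positive integer Taylor order.
#' @return For a vector input, a `length(x) x Q` matrix; otherwise an array
#'   with one extra trailing dimension of extent `Q`.
#' @examples
#' taylor_feature_powers(c(2, -1), 3)
#' @export
taylor_feature_powers <- function(x, Q) {
  Q <- as.integer(Q)
  if (is.na(Q) || Q < 1L) stop("Q must be a positive integer")
  if (any(!is.finite(x))) stop("input must be finite")
  if (is.numeric(x) && is.null(dim(x))) {
    out <- vapply(seq_len(Q), function(q) x^q, numeric(length(x)))
    return(matrix(out, ncol = Q))
  }
  d <- dim(x)
  array(unlist(lapply(seq_len(Q), function(q) x^q), use.names = FALSE),
        dim = c(d, Q))
}

# Flatten a (O, I, K, Q) weight array to the (O x I*K*Q) GEMM matrix whose
# column index runs q fastest, then tap r, then input channel i — the row
# ordering produced by the C++ powered im2col.
flatten_kernel <- function(weights) {
  d <- dim(weights)
  matrix(aperm(weights, c(1L, 4L, 3L, 2L)), nrow = d[1L])
}

#' 1D Self-ONN operational convolution
#'
#' Computes, per output channel `k` and output position `m`,
#' `y[k, m] = b[k] + sum_{i,r,q} W[k, i, r, q] * x[i, m*stride + r - padding]^q`
#' with zero padding and the correlation (no kernel flip) convention.  With
#' `Q = 1` this is a plain 1D convolution.
#'
#' @param x input: numeric vector, matrix (channel x time), or array
#'   (channel x time x batch); values must be finite.
#' @param kernel a `generative_neuron_kernel` from [init_kernel()] (or a
#'   list with matching `weights`/`bias`).
#' @param spec the [selfonn_layer_spec()] the kernel was built for.
#' @return Feature map of the same rank as the input; output length is
#'   `floor((L + 2*padding - K)/stride) + 1`.
#' @examples
#' sp <- selfonn_layer_spec(1, 1, kernel_size = 1, taylor_order = 2)
#' k <- init_kernel(sp, seed = 1)
#' k$weights[1, 1, 1, ] <- c(1, 0.5)   # y = x + 0.5 x^2
#' k$bias[] <- 0
#' selfonn_conv1d(c(1, -1, 0.5), k, sp)
#' @export
selfonn_conv1d <- function(x, kernel, spec) {
  stopifnot(inherits(spec, "selfonn_layer_spec"))
  fm <- as_feature_map(x)
  check_conv_args(fm$x, kernel, spec)
  res <- cpp_selfonn_conv_fwd(fm$x, flatten_kernel(kernel$weights),
                              if (spec$bias) kernel$bias else numeric(spec$out_channels),
                              spec$kernel_size, spec$taylor_order,
                              spec$stride, spec$padding, spec$bias, FALSE)
  restore_rank(res$y, fm$rank)
}

#' Brute-force reference for the operational convolution
#'
#' Evaluates the same sum as [selfonn_conv1d()] with explicit nested loops
#' over output channel, input channel, position, tap and power — no
#' vectorized shortcut.  Used as the independent oracle in the test suite.
#'
#' @inheritParams selfonn_conv1d
#' @return Feature map identical (to float tolerance) to [selfonn_conv1d()].
#' @export
reference_selfonn_oracle <- function(x, kernel, spec) {
  stopifnot(inherits(spec, "selfonn_layer_spec"))
  fm <- as_feature_map(x)
  check_conv_args(fm$x, kernel, spec)
  y <- cpp_selfonn_conv_naive(fm$x, as.numeric(kernel$weights),
                              if (spec$bias) kernel$bias else numeric(spec$out_channels),
                              spec$out_channels, spec$in_channels,
                              spec$kernel_size, spec$taylor_order,
                              spec$stride, spec$padding, spec$bias)
  restore_rank(y, fm$rank)
}

#' Pure-R loop reference for the operational convolution
#'
#' A second, slower reference written entirely in R, independent of the
#' compiled code path.  Intended for tiny instances in tests.
#'
#' @inheritParams selfonn_conv1d
#' @return Feature map as from [selfonn_conv1d()].
#' @export
selfonn_conv1d_loops <- function(x, kernel, spec) {
  stopifnot(inherits(spec, "selfonn_layer_spec"))
  fm <- as_feature_map(x)
  check_conv_args(fm$x, kernel, spec)
  xs <- fm$x
  K <- spec$kernel_size; Q <- spec$taylor_order
  L <- dim(xs)[2L]; B <- dim(xs)[3L]
  Lout <- (L + 2L * spec$padding - K) %/% spec$stride + 1L
  if (Lout < 1L) stop("input too short for kernel: no valid output positions")
  y <- array(0, dim = c(spec$out_channels, Lout, B))
  for (b in seq_len(B)) for (k in seq_len(spec$out_channels)) for (m in seq_len(Lout)) {
    acc <- if (spec$bias) kernel$bias[k] else 0
    for (i in seq_len(spec$in_channels)) for (r in seq_len(K)) {
      pos <- (m - 1L) * spec$stride + (r - 1L) - spec$padding + 1L
      if (pos < 1L || pos > L) next
      for (q in seq_len(Q))
        acc <- acc + kernel$weights[k, i, r, q] * xs[i, pos, b]^q
    }
    y[k, m, b] <- acc
  }
  restore_rank(y, fm$rank)
}

check_conv_args <- function(x, kernel, spec) {
  if (dim(x)[1L] != spec$in_channels)
    stop("input has ", dim(x)[1L], " channels but spec expects ", spec$in_channels)
  dw <- dim(kernel$weights)
  expect <- c(spec$out_channels, spec$in_channels, spec$kernel_size, spec$taylor_order)
  if (!identical(as.integer(dw), as.integer(expect)))
    stop("kernel weight dimensions (", paste(dw, collapse = "x"),
         ") do not match spec (", paste(expect, collapse = "x"), ")")
  if (spec$bias && length(kernel$bias) != spec$out_channels)
    stop("bias length does not match out_channels")
  if (any(!is.finite(x))) stop("input contains non-finite values")
  invisible(TRUE)
}

#' Output length of a strided, padded 1D convolution
#' @param L input length; @param K kernel size; @param stride,padding ints.
#' @return `floor((L + 2*padding - K)/stride) + 1`.
#' @export
conv_output_length <- function(L, K, stride = 1L, padding = 0L) {
  as.integer((L + 2L * padding - K) %/% stride + 1L)
}
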