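# Shared fixtures: everything is generated in code at test time.

selfonn_ns <- asNamespace("selfonn")

# A small cohort that keeps unit tests fast; the acceptance suite uses the
# full default spec.
tiny_cohort <- function(duration_s = 40, seed = 7, ...) {
  generate_cohort(synthetic_cohort_spec(duration_s = duration_s, seed = seed, ...))
}

# Random small operational-convolution instance for equivalence sweeps.
random_conv_instance <- function() {
  spec <- selfonn_layer_spec(
    in_channels = sample(1:3, 1), out_channels = sample(1:3, 1),
    kernel_size = sample(1:5, 1), taylor_order = sample(1:5, 1),
    stride = sample(1:2, 1), padding = sample(0:2, 1),
    bias = sample(c(TRUE, FALSE), 1))
  L <- sample(spec$kernel_size:16, 1)
  kernel <- init_kernel(spec, seed = sample.int(1e6, 1))
  if (spec$bias) kernel$bias <- rnorm(spec$out_channels)
  x <- array(runif(spec$in_channels * L * 2, -1, 1),
             dim = c(spec$in_channels, L, 2L))
  list(spec = spec, kernel = kernel, x = x)
}

# Independent plain correlation (no kernel flip) for the Q = 1 limit case:
# y[m] = sum_r w[r] * x[m + r - 1], via embed().
plain_correlation <- function(x, w) {
  K <- length(w)
  if (length(x) < K) stop("signal shorter than kernel")
  em <- stats::embed(x, K)     # row m: x[m+K-1], ..., x[m]
  as.numeric(em %*% rev(w))
}

# A clean pulsatile segment for annotation tests.
clean_beat_segment <- function(bpm = 72, n = 1024, fs = 217) {
  p <- waveform_params(heart_rate = bpm, beat_jitter = 0, noise_sd = 0)
  env <- generate_velocity_waveform(p, duration = (n + 10) / fs, fs = fs)
  env$samples[seq_len(n)]
}
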