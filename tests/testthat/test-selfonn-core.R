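test_that("taylor powers stack elementwise powers of the input", {
  expect_equal(taylor_feature_powers(2, 3), matrix(c(2, 4, 8), 1))
  expect_equal(taylor_feature_powers(-1, 2), matrix(c(-1, 1), 1))
  expect_equal(taylor_feature_powers(0.5, 1), matrix(0.5))
  x <- array(runif(2 * 5 * 3, -1, 1), dim = c(2, 5, 3))
  tp <- taylor_feature_powers(x, 3)
  expect_equal(dim(tp), c(2, 5, 3, 3))
  expect_equal(tp[, , , 1], x)
  expect_equal(tp[, , , 3], x^3)
  expect_error(taylor_feature_powers(1:3, 0), "positive")
  expect_error(taylor_feature_powers(c(1, NaN), 2), "finite")
})

test_that("operational convolution matches hand-evaluated examples", {
  sp <- selfonn_layer_spec(1, 1, kernel_size = 1)
  k <- init_kernel(sp)
  k$weights[] <- 1; k$bias[] <- 0
  expect_equal(selfonn_conv1d(c(2, -3, 4), k, sp), c(2, -3, 4))

  sp2 <- selfonn_layer_spec(1, 1, kernel_size = 1, taylor_order = 2)
  k2 <- init_kernel(sp2)
  k2$weights[1, 1, 1, ] <- c(1, 0.5); k2$bias[] <- 0
  expect_equal(selfonn_conv1d(c(1, -1, 0.5), k2, sp2), c(1.5, -0.5, 0.625))

  k2$weights[] <- 0; k2$bias[] <- 2.5
  expect_equal(selfonn_conv1d(runif(6, -1, 1), k2, sp2), rep(2.5, 6))
})

test_that("convolution rejects malformed inputs", {
  sp <- selfonn_layer_spec(2, 1, kernel_size = 3)
  k <- init_kernel(sp, 1)
  expect_error(selfonn_conv1d(runif(8), k, sp), "channels")
  expect_error(selfonn_conv1d(matrix(c(1, NaN), 2, 4), k, sp), "finite")
  sp1 <- selfonn_layer_spec(1, 1, kernel_size = 5)
  k1 <- init_kernel(sp1, 1)
  expect_error(selfonn_conv1d(runif(3), k1, sp1), "too short")
  expect_error(reference_selfonn_oracle(runif(3), k1, sp1), "too short")
  kb <- init_kernel(sp, 1)
  dim(kb$weights) <- c(1, 3, 2, 1)
  expect_error(selfonn_conv1d(matrix(runif(8), 2), kb, sp), "dimensions")
})

test_that("fast path, brute-force oracle and pure-R loops agree on 100 random instances", {
  set.seed(20)
  for (i in 1:100) {
    inst <- random_conv_instance()
    fast <- selfonn_conv1d(inst$x, inst$kernel, inst$spec)
    oracle <- reference_selfonn_oracle(inst$x, inst$kernel, inst$spec)
    expect_lt(max(abs(fast - oracle)), 1e-5)
    if (i <= 15) {  # the pure-R path is slow; spot-check it
      loops <- selfonn_conv1d_loops(inst$x, inst$kernel, inst$spec)
      expect_lt(max(abs(fast - loops)), 1e-10)
    }
  }
})

test_that("Q = 1 reduces to a standard convolution with the same weights", {
  set.seed(21)
  for (i in 1:20) {
    K <- sample(1:7, 1)
    L <- sample((K + 1):40, 1)
    sp <- selfonn_layer_spec(1, 1, kernel_size = K, taylor_order = 1,
                             bias = FALSE)
    k <- init_kernel(sp, seed = i)
    x <- rnorm(L)
    expect_lt(max(abs(selfonn_conv1d(x, k, sp) -
                      plain_correlation(x, as.numeric(k$weights)))), 1e-5)
  }
})

test_that("kernel initialization is seeded, bounded and per-power scaled", {
  sp <- selfonn_layer_spec(3, 4, kernel_size = 5, taylor_order = 3)
  k1 <- init_kernel(sp, seed = 42)
  k2 <- init_kernel(sp, seed = 42)
  k3 <- init_kernel(sp, seed = 43)
  expect_identical(k1, k2)
  expect_false(identical(k1$weights, k3$weights))
  expect_true(all(abs(k1$weights) <= kernel_init_scale(sp)))
  expect_equal(kernel_init_scale(sp), 1 / sqrt(3 * 5 * 3))
  expect_equal(k1$bias, numeric(4))
})

test_that("parameter count scales linearly in the Taylor order", {
  sp1 <- selfonn_layer_spec(3, 4, kernel_size = 5, taylor_order = 1)
  sp3 <- selfonn_layer_spec(3, 4, kernel_size = 5, taylor_order = 3)
  expect_equal(n_layer_parameters(sp1), 4 * 3 * 5 + 4)
  expect_equal(n_layer_parameters(sp3) - 4L,
               3L * (n_layer_parameters(sp1) - 4L))
})

test_that("output is linear in the weights and obeys the length formula", {
  set.seed(22)
  inst <- random_conv_instance()
  inst$kernel$bias <- if (inst$spec$bias) numeric(inst$spec$out_channels)
  y1 <- selfonn_conv1d(inst$x, inst$kernel, inst$spec)
  k2 <- inst$kernel
  k2$weights <- 2 * k2$weights
  expect_equal(selfonn_conv1d(inst$x, k2, inst$spec), 2 * y1)

  for (L in c(8, 31)) for (K in c(1, 3, 7)) for (s in 1:3) for (p in 0:3) {
    if (L + 2 * p < K) next
    sp <- selfonn_layer_spec(1, 1, kernel_size = K, stride = s, padding = p)
    k <- init_kernel(sp, 1)
    y <- selfonn_conv1d(runif(L), k, sp)
    expect_length(y, conv_output_length(L, K, s, p))
    expect_length(y, (L + 2 * p - K) %/% s + 1)
  }
})
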