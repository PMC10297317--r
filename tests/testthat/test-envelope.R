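test_that("STFT spectrogram maps a pure tone to the Doppler velocity", {
  fs <- 8000
  fd <- 1000                      # Doppler shift, Hz
  v_expect <- 1540 * fd / (2 * 1.75e6) * 100   # cm/s
  x <- sin(2 * pi * fd * seq(0, 2, by = 1 / fs))
  sp <- doppler_spectrogram(x, fs)
  ridge <- sp$velocity_axis[apply(sp$magnitude, 2, which.max)]
  bin <- diff(sp$velocity_axis[1:2])
  expect_true(all(abs(ridge - v_expect) <= bin + 1e-9))
  # framing arithmetic
  win <- round(0.05 * fs); hop <- round(0.01 * fs)
  expect_equal(ncol(sp$magnitude), (length(x) - win) %/% hop + 1)
  expect_error(doppler_spectrogram(numeric(0), fs), "empty")
})

test_that("zero signal gives an all-zero magnitude", {
  sp <- doppler_spectrogram(numeric(4000), 8000)
  expect_true(all(sp$magnitude == 0))
})

test_that("binarization thresholds signal against noise floor", {
  vax <- 1:50; tax <- seq(0, 0.99, by = 0.01)
  two <- matrix(0, 50, 100); two[10:20, ] <- 1
  sp <- doppler_spectrogram_obj(two, vax, tax)
  b <- binarize_spectrogram(sp)
  expect_equal(b$mask, two == 1)
  # all-equal image: midpoint fallback, all-false mask
  flat <- doppler_spectrogram_obj(matrix(1, 50, 100), vax, tax)
  expect_false(any(binarize_spectrogram(flat)$mask))
  # ridge at 0 dB over a -40 dB floor
  m <- matrix(10^(-40 / 20), 50, 100); m[25:30, ] <- 1
  bs <- binarize_spectrogram(doppler_spectrogram_obj(m, vax, tax))
  expect_true(all(bs$mask[25:30, ]))
  expect_false(any(bs$mask[-(25:30), ]))
})

test_that("despeckle kernel conversion and majority behaviour", {
  vax <- seq(1, 60, by = 1)                 # 1 cm/s bins
  tax <- seq(0, 0.99, by = 0.01)            # 10 ms hop
  mask <- matrix(FALSE, 60, 100)
  bin <- structure(list(mask = mask, velocity_axis = vax, time_axis = tax,
                        threshold_db = 0), class = "binary_spectrogram")
  d0 <- despeckle(bin)
  expect_equal(unname(d0$kernel_bins), c(5L, 3L))   # 5 cm/s x 0.03 s
  # isolated pixel removed
  bin$mask[30, 50] <- TRUE
  expect_false(any(despeckle(bin)$mask))
  # solid rectangle interior preserved
  bin$mask[,] <- FALSE; bin$mask[20:40, 30:70] <- TRUE
  d <- despeckle(bin)
  expect_true(all(d$mask[23:37, 33:67]))
  expect_false(any(d$mask[c(1:17, 43:60), ]))
  # idempotent on kernel-constant regions (a velocity band, away from the
  # clipped time borders where zero padding keeps eroding)
  bin$mask[,] <- FALSE; bin$mask[20:40, ] <- TRUE
  band <- despeckle(bin)
  expect_equal(band$mask[, 3:98], despeckle(band)$mask[, 3:98])
})

test_that("tracing a clean filled spectrum recovers the column tops", {
  vax <- seq(2, 120, by = 2)
  tax <- seq(0, 0.49, by = 0.01)
  tops <- round(30 + 10 * sin(seq(0, 2 * pi, length.out = 50)))
  mask <- vapply(tops, function(v) seq_along(vax) <= v, logical(length(vax)))
  bin <- structure(list(mask = mask, velocity_axis = vax, time_axis = tax,
                        threshold_db = 0), class = "binary_spectrogram")
  env <- trace_envelope(bin, out_fs = 100)  # same rate as frames: no resampling error
  expect_s3_class(env, "velocity_envelope")
  expect_true(all(env$valid_mask))
  expect_equal(env$samples[seq_along(tops)], vax[tops], tolerance = 1e-9)
  # empty columns are invalid
  mask[, 10] <- FALSE
  bin$mask <- mask
  env2 <- trace_envelope(bin, out_fs = 100)
  expect_false(env2$valid_mask[10])
})

test_that("envelope values respect the velocity axis bounds", {
  set.seed(50)
  mask <- matrix(runif(60 * 80) < 0.4, 60, 80)
  bin <- structure(list(mask = mask, velocity_axis = seq(2, 120, 2),
                        time_axis = seq(0, 0.79, 0.01), threshold_db = 0),
                   class = "binary_spectrogram")
  env <- suppressWarnings(trace_envelope(bin))
  v <- env$samples[env$valid_mask]
  expect_true(all(v > 0 & v <= 120))
})

test_that("known waveforms are recovered from synthetic spectrograms within 2 bins", {
  p <- waveform_params(systolic_peak = 100, diastolic_floor = 40,
                       heart_rate = 66, beat_jitter = 0, noise_sd = 0)
  truth <- generate_velocity_waveform(p, duration = 20, fs = 217)
  sp <- synth_doppler_spectrogram(truth, bin_cm_s = 2)
  bin_w <- 2
  traced <- trace_envelope(despeckle(binarize_spectrogram(sp)),
                           jump_max = 30, out_fs = 217)
  n <- min(length(traced$samples), length(truth$samples))
  ok <- traced$valid_mask[1:n]
  rmse <- sqrt(mean((traced$samples[1:n][ok] - truth$samples[1:n][ok])^2))
  expect_lt(rmse / bin_w, 2)

  # 0.1% speckle: recovery unchanged within one bin after despeckling
  sps <- synth_doppler_spectrogram(truth, bin_cm_s = 2, speckle_rate = 0.001,
                                   seed = 9)
  traced_s <- trace_envelope(despeckle(binarize_spectrogram(sps)),
                             jump_max = 30, out_fs = 217)
  ok2 <- ok & traced_s$valid_mask[1:n]
  rmse_s <- sqrt(mean((traced_s$samples[1:n][ok2] - truth$samples[1:n][ok2])^2))
  expect_lt(abs(rmse_s - rmse) / bin_w, 1)
})

test_that("a zero envelope yields an all-floor spectrogram and no trace", {
  zero_env <- velocity_envelope(rep(0, 217 * 3), sample_rate = 217)
  sp <- synth_doppler_spectrogram(zero_env)
  expect_true(all(sp$magnitude == 10^(-40 / 20)))
  traced <- trace_envelope(despeckle(binarize_spectrogram(sp)))
  expect_false(any(traced$valid_mask))
})

test_that("the full extraction pipeline is deterministic", {
  set.seed(51)
  fs <- 8000
  x <- sin(2 * pi * 800 * seq(0, 1, by = 1 / fs)) + rnorm(8001, sd = 0.05)
  e1 <- extract_envelope(x, fs)
  e2 <- extract_envelope(x, fs)
  expect_identical(e1, e2)
})

test_that("envelope CSV round-trips values and validity", {
  env <- velocity_envelope(c(10, 20, NaN, 40), sample_rate = 217)
  path <- tempfile(fileext = ".csv")
  write_envelope_csv(env, path)
  back <- read_envelope_csv(path)
  expect_equal(back$samples[c(1, 2, 4)], c(10, 20, 40))
  expect_equal(back$valid_mask, c(TRUE, TRUE, FALSE, TRUE))
})
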