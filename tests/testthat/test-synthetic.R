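count_systolic_peaks <- function(env, min_height = NULL) {
  x <- env$samples
  if (is.null(min_height)) min_height <- min(x) + 0.6 * (max(x) - min(x))
  up <- which(diff(sign(diff(x))) == -2) + 1L   # local maxima
  sum(x[up] >= min_height)
}

test_that("waveform parameters validate physiological ranges", {
  expect_s3_class(waveform_params(), "waveform_params")
  expect_error(waveform_params(systolic_peak = 40, diastolic_floor = 50), "<")
  expect_error(waveform_params(systolic_peak = 400), "<=")
  expect_error(waveform_params(heart_rate = 20), "heart_rate")
  expect_error(generate_velocity_waveform(waveform_params(heart_rate = 30),
                                          duration = 1), "beat")
})

test_that("the beat train has floor(duration * HR / 60) systolic peaks", {
  p <- waveform_params(heart_rate = 60, beat_jitter = 0, noise_sd = 0)
  env <- generate_velocity_waveform(p, duration = 1024 / 217, fs = 217)
  expect_equal(count_systolic_peaks(env), 4)
  env10 <- generate_velocity_waveform(p, duration = 10, fs = 217)
  expect_equal(count_systolic_peaks(env10), 10)
})

test_that("noise-free waveforms are exactly periodic at the beat period", {
  p <- waveform_params(heart_rate = 60, beat_jitter = 0, noise_sd = 0)
  env <- generate_velocity_waveform(p, duration = 4, fs = 217)
  x <- env$samples
  # compare beat 2 and beat 3 (both complete, 217 samples at 60 bpm)
  expect_equal(x[218:434], x[435:651], tolerance = 1e-9)
})

test_that("empirical pulsatility index matches the value implied by the parameters", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- waveform_params(systolic_peak = runif(1, 80, 120),
                         diastolic_floor = runif(1, 20, 50),
                         heart_rate = runif(1, 55, 100),
                         beat_jitter = 0, noise_sd = 0)
    env <- generate_velocity_waveform(p, duration = 30, fs = 217)
    x <- env$samples[1:(217 * 29)]     # complete beats only
    pi_emp <- (max(x) - min(x)) / mean(x)
    expect_equal(pi_emp, implied_pulsatility_index(p), tolerance = 0.1)
  }
})

test_that("cohorts reproduce the 6 healthy / 12 ICU structure deterministically", {
  coh <- tiny_cohort(seed = 77)
  tab <- table(unique(coh$manifest[, c("subject_id", "class_label")])$class_label)
  expect_equal(unname(tab[["Healthy"]]), 6L)
  expect_equal(unname(tab[["ICU"]]), 12L)
  expect_equal(anyDuplicated(coh$manifest$session_id), 0L)
  coh2 <- tiny_cohort(seed = 77)
  expect_identical(coh$envelopes, coh2$envelopes)
  coh3 <- tiny_cohort(seed = 78)
  expect_false(identical(coh$envelopes, coh3$envelopes))
  for (env in coh$envelopes) {
    expect_true(all(is.finite(env$samples[env$valid_mask])))
    expect_true(all(env$samples[env$valid_mask] > 0 &
                    env$samples[env$valid_mask] <= 300))
  }
})

test_that("the two classes differ in pulsatility by construction", {
  coh <- tiny_cohort(duration_s = 30, seed = 80,
                     nan_cut_rate = 0, flat_line_rate = 0, spike_rate = 0)
  pi_of <- function(env) {
    x <- env$samples
    (quantile(x, 0.99) - quantile(x, 0.01)) / mean(x)
  }
  pis <- vapply(coh$envelopes, pi_of, numeric(1))
  cls <- coh$manifest$class_label[match(names(pis), coh$manifest$session_id)]
  expect_gt(min(pis[cls == "ICU"]), max(pis[cls == "Healthy"]))
})

test_that("artifact injection composes with cut removal and annotation", {
  p <- waveform_params(beat_jitter = 0, noise_sd = 1)
  env <- generate_velocity_waveform(p, duration = 2148 / 217, fs = 217, seed = 1)
  # one NaN cut splits the envelope into two usable runs
  cut <- env
  cut$samples[1025:1124] <- NaN
  cut$valid_mask[1025:1124] <- FALSE
  expect_length(remove_cuts(cut, 1024), 2)
  # a 300-sample flat line makes its segment rejected
  flat <- env$samples[1:1024]
  flat[200:499] <- flat[200]
  expect_equal(auto_annotate(flat), "rejected")
  # zero rates leave the envelope unchanged
  same <- inject_artifacts(env, rates = list(nan_cut = 0, flat_line = 0,
                                             spike = 0), seed = 4)
  expect_equal(same$samples, env$samples)
  # positive rates are reproducible given the seed
  a1 <- inject_artifacts(env, seed = 5)
  a2 <- inject_artifacts(env, seed = 5)
  expect_identical(a1$samples, a2$samples)
})

test_that("segment tables drop rejected segments and honour manifest overrides", {
  coh <- tiny_cohort(duration_s = 30, seed = 81)
  tab <- build_segment_table(coh, overlap_fraction = 0)
  expect_false(anyNA(tab$segments))
  expect_true(all(tab$meta$quality %in% c("clear", "corrupted")))
  expect_equal(nrow(tab$segments), nrow(tab$meta))
  expect_equal(tab$meta$label, as.integer(tab$meta$class_label == "ICU"))
  # manifest quality override applies to all of a session's segments
  coh$manifest$quality <- "corrupted"
  tab2 <- build_segment_table(coh, overlap_fraction = 0)
  expect_true(all(tab2$meta$quality == "corrupted"))
  expect_equal(nrow(build_segment_table(coh, overlap_fraction = 0,
                                        include_corrupted = FALSE)$segments), 0)
})
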