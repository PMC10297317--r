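#' Parameters of a synthetic pulsatile CBFV waveform
#'
#' One beat is modelled as a diastolic baseline with an early-diastolic
#' decay, a systolic Gaussian upstroke and a smaller dicrotic secondary
#' wave; beats repeat at the heart rate with optional period jitter and
#' additive Gaussian noise.  The Gaussian beat model is a deliberate
#' simplification: only the statistical structure (pulsatility, periodicity,
#' class contrast) matters for testing the pipeline.
#'
#' @param systolic_peak peak systolic velocity, cm/s.
#' @param diastolic_floor end-diastolic velocity, cm/s; must satisfy
#'   `0 < diastolic_floor < systolic_peak <= 300`.
#' @param heart_rate beats per minute, in `[30, 180]`.
#' @param dicrotic_amplitude dicrotic wave height as a fraction of the
#'   systolic excursion.
#' @param beat_jitter relative standard deviation of the beat period.
#' @param noise_sd additive Gaussian noise, cm/s.
#' @param mean_velocity optional mean velocity, cm/s; when `NULL` it is
#'   derived by integrating the noiseless beat template.
#' @return An object of class `waveform_params`.
#' @export
waveform_params <- function(systolic_peak = 100, diastolic_floor = 40,
                            heart_rate = 70, dicrotic_amplitude = 0.25,
                            beat_jitter = 0.03, noise_sd = 1.5,
                            mean_velocity = NULL) {
  if (!(diastolic_floor > 0 && diastolic_floor < systolic_peak &&
        systolic_peak <= 300))
    stop("need 0 < diastolic_floor < systolic_peak <= 300")
  if (heart_rate < 30 || heart_rate > 180)
    stop("heart_rate must lie in [30, 180] bpm")
  if (beat_jitter < 0 || noise_sd < 0) stop("jitter and noise_sd must be >= 0")
  p <- list(systolic_peak = systolic_peak, diastolic_floor = diastolic_floor,
            heart_rate = heart_rate, dicrotic_amplitude = dicrotic_amplitude,
            beat_jitter = beat_jitter, noise_sd = noise_sd)
  if (is.null(mean_velocity)) {
    u <- seq(0, 1, length.out = 2048L)
    mean_velocity <- mean(beat_template(u, p))
  }
  p$mean_velocity <- mean_velocity
  structure(p, class = "waveform_params")
}

# Noiseless velocity at beat phase u in [0, 1).
beat_template <- function(u, p) {
  exc <- p$systolic_peak - p$diastolic_floor
  p$diastolic_floor * (1 + 0.15 * exp(-4 * u)) +
    exc * exp(-(u - 0.13)^2 / (2 * 0.055^2)) +
    p$dicrotic_amplitude * exc * exp(-(u - 0.42)^2 / (2 * 0.05^2))
}

#' Pulsatility index implied by waveform parameters
#'
#' `(systolic - diastolic velocity) / mean velocity`, computed from the
#' noiseless beat template on a fine phase grid.
#'
#' @param params a [waveform_params()].
#' @return Implied pulsatility index.
#' @export
implied_pulsatility_index <- function(params) {
  stopifnot(inherits(params, "waveform_params"))
  u <- seq(0, 1, length.out = 2048L)
  v <- beat_template(u, params)
  (max(v) - min(v)) / mean(v)
}

#' Generate one synthetic CBFV envelope
#'
#' Synthesizes a beat train of nominal period `60/heart_rate` seconds
#' (jittered per beat), samples it at `fs`, adds Gaussian noise and clamps
#' to `(0, 300]` cm/s.  Only complete beats carry the systolic and dicrotic
#' components; a trailing partial beat continues the diastolic baseline, so
#' the number of systolic peaks equals the number of complete beats.
#'
#' @param params a [waveform_params()].
#' @param duration recording length, seconds; must cover at least one beat.
#' @param fs sampling rate, Hz (default 217).
#' @param seed integer seed; the waveform is deterministic given it.
#' @param session_id,subject_id,class_label metadata passed through to the
#'   returned envelope.
#' @return A [velocity_envelope()].
#' @export
generate_velocity_waveform <- function(params, duration, fs = 217,
                                       seed = NULL,
                                       session_id = NA_character_,
                                       subject_id = NA_character_,
                                       class_label = NA_character_) {
  stopifnot(inherits(params, "waveform_params"))
  period <- 60 / params$heart_rate
  if (duration < period) stop("duration must cover at least one beat")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- floor(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  # jittered beat boundaries covering the recording
  n_beats_max <- ceiling(duration / period) + 2L
  periods <- period * (1 + params$beat_jitter * rnorm(n_beats_max))
  periods <- pmax(periods, 0.3 * period)
  bounds <- c(0, cumsum(periods))
  v <- numeric(n)
  for (j in seq_len(n_beats_max)) {
    in_beat <- t >= bounds[j] & t < bounds[j + 1L]
    if (!any(in_beat)) next
    u <- (t[in_beat] - bounds[j]) / periods[j]
    complete <- bounds[j + 1L] <= duration
    v[in_beat] <- if (complete) beat_template(u, params)
                  else params$diastolic_floor * (1 + 0.15 * exp(-4 * u))
  }
  if (params$noise_sd > 0) v <- v + rnorm(n, sd = params$noise_sd)
  v <- pmin(pmax(v, 0.1), 300)
  velocity_envelope(v, sample_rate = fs, session_id = session_id,
                    subject_id = subject_id, class_label = class_label)
}

#' Specification of a synthetic cohort
#'
#' Defaults emulate the clinical cohort structure: 6 healthy and 12 ICU
#' subjects, one recording session each, 300 s per recording at 217 Hz.
#' The class contrast is a synthetic design convention — ICU waveforms draw
#' a higher pulsatility (depressed diastolic floor) than healthy ones — and
#' is explicitly not a claim about any clinical dataset.
#'
#' @param n_healthy,n_icu subjects per class.
#' @param recordings_per_subject sessions per subject.
#' @param duration_s seconds per recording.
#' @param fs sampling rate, Hz.
#' @param healthy_ranges,icu_ranges named lists of `c(min, max)` ranges for
#'   `systolic_peak`, `diastolic_floor`, `heart_rate`, `dicrotic_amplitude`;
#'   per-subject parameters are drawn uniformly from them.
#' @param beat_jitter,noise_sd shared waveform nuisance parameters.
#' @param nan_cut_rate,flat_line_rate,spike_rate expected artifact counts
#'   per recording (Poisson), passed to [inject_artifacts()].
#' @param seed integer master seed.
#' @return An object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_healthy = 6L, n_icu = 12L,
                                  recordings_per_subject = 1L,
                                  duration_s = 300, fs = 217,
                                  healthy_ranges = list(
                                    systolic_peak = c(85, 115),
                                    diastolic_floor = c(35, 50),
                                    heart_rate = c(55, 85),
                                    dicrotic_amplitude = c(0.2, 0.35)),
                                  icu_ranges = list(
                                    systolic_peak = c(85, 125),
                                    diastolic_floor = c(12, 26),
                                    heart_rate = c(60, 110),
                                    dicrotic_amplitude = c(0.05, 0.2)),
                                  beat_jitter = 0.03, noise_sd = 2,
                                  nan_cut_rate = 2, flat_line_rate = 1,
                                  spike_rate = 1, seed = 1L) {
  spec <- list(n_healthy = as.integer(n_healthy), n_icu = as.integer(n_icu),
               recordings_per_subject = as.integer(recordings_per_subject),
               duration_s = duration_s, fs = fs,
               healthy_ranges = healthy_ranges, icu_ranges = icu_ranges,
               beat_jitter = beat_jitter, noise_sd = noise_sd,
               nan_cut_rate = nan_cut_rate, flat_line_rate = flat_line_rate,
               spike_rate = spike_rate, seed = as.integer(seed))
  if (spec$n_healthy < 1L || spec$n_icu < 1L || spec$recordings_per_subject < 1L)
    stop("subject and recording counts must be positive")
  if (any(c(nan_cut_rate, flat_line_rate, spike_rate) < 0))
    stop("artifact rates must be >= 0")
  structure(spec, class = "synthetic_cohort_spec")
}

draw_params <- function(ranges, jitter, noise_sd) {
  draw <- function(r) runif(1, r[1], r[2])
  waveform_params(systolic_peak = draw(ranges$systolic_peak),
                  diastolic_floor = draw(ranges$diastolic_floor),
                  heart_rate = draw(ranges$heart_rate),
                  dicrotic_amplitude = draw(ranges$dicrotic_amplitude),
                  beat_jitter = jitter, noise_sd = noise_sd)
}

#' Generate a synthetic CBFV cohort
#'
#' Draws per-subject waveform parameters from the class-specific ranges,
#' synthesizes every recording session, injects artifacts (NaN cuts, flat
#' "plane lines", spikes) at the configured rates, and assembles the
#' manifest.  Fully reproducible given `spec$seed`.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @return An object of class `synthetic_cohort`: list with `manifest`
#'   (data frame: session_id, subject_id, class_label, quality) and
#'   `envelopes` (named list of [velocity_envelope()], keyed by session id).
#' @export
generate_cohort <- function(spec = synthetic_cohort_spec()) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  set.seed(spec$seed)
  envelopes <- list()
  rows <- list()
  subjects <- data.frame(
    subject_id = c(sprintf("H%02d", seq_len(spec$n_healthy)),
                   sprintf("P%02d", seq_len(spec$n_icu))),
    class_label = c(rep("Healthy", spec$n_healthy), rep("ICU", spec$n_icu)))
  for (i in seq_len(nrow(subjects))) {
    ranges <- if (subjects$class_label[i] == "Healthy") spec$healthy_ranges
              else spec$icu_ranges
    params <- draw_params(ranges, spec$beat_jitter, spec$noise_sd)
    for (r in seq_len(spec$recordings_per_subject)) {
      sid <- sprintf("%s_s%d", subjects$subject_id[i], r)
      env <- generate_velocity_waveform(
        params, spec$duration_s, spec$fs,
        seed = sample.int(.Machine$integer.max, 1L),
        session_id = sid, subject_id = subjects$subject_id[i],
        class_label = subjects$class_label[i])
      env <- inject_artifacts(env,
                              rates = list(nan_cut = spec$nan_cut_rate,
                                           flat_line = spec$flat_line_rate,
                                           spike = spec$spike_rate),
                              seed = sample.int(.Machine$integer.max, 1L))
      envelopes[[sid]] <- env
      rows[[sid]] <- data.frame(session_id = sid,
                                subject_id = subjects$subject_id[i],
                                class_label = subjects$class_label[i],
                                quality = NA_character_)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(manifest = manifest, envelopes = envelopes, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$manifest$class_label)
  cat(sprintf("Synthetic CBFV cohort: %d sessions (%s), %g s each @ %g Hz\n",
              nrow(x$manifest),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              x$spec$duration_s, x$spec$fs))
  invisible(x)
}

#' Inject recording artifacts into an envelope
#'
#' Inserts the artifact types seen in real TCD recordings: NaN signal cuts,
#' constant "plane line" runs (probe loss) and isolated velocity spikes.
#' Counts per recording are Poisson with the configured rates; zero rates
#' leave the envelope unchanged.  The validity mask is updated for NaN cuts.
#'
#' @param envelope a [velocity_envelope()].
#' @param rates named list: expected counts per recording for `nan_cut`,
#'   `flat_line` and `spike`.
#' @param cut_len,flat_len ranges (samples) for cut and flat-run lengths.
#' @param seed integer seed.
#' @return The modified [velocity_envelope()].
#' @export
inject_artifacts <- function(envelope,
                             rates = list(nan_cut = 2, flat_line = 1, spike = 1),
                             cut_len = c(50L, 400L), flat_len = c(250L, 500L),
                             seed = NULL) {
  stopifnot(inherits(envelope, "velocity_envelope"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- envelope$samples
  n <- length(x)
  rate_of <- function(nm) if (is.null(rates[[nm]])) 0 else rates[[nm]]
  place <- function(len_range) {
    len <- sample(len_range[1]:len_range[2], 1L)
    start <- sample.int(max(1L, n - len), 1L)
    start:(start + len - 1L)
  }
  for (i in seq_len(rpois_det(rate_of("nan_cut")))) x[place(cut_len)] <- NaN
  for (i in seq_len(rpois_det(rate_of("flat_line")))) {
    idx <- place(flat_len)
    x[idx] <- x[idx[1L]]
  }
  for (i in seq_len(rpois_det(rate_of("spike")))) {
    at <- sample.int(n, 1L)
    x[at] <- min(295, x[at] + runif(1, 60, 150))
  }
  velocity_envelope(x, sample_rate = envelope$sample_rate,
                    session_id = envelope$session_id,
                    subject_id = envelope$subject_id,
                    class_label = envelope$class_label)
}

rpois_det <- function(rate) if (rate <= 0) 0L else stats::rpois(1L, rate)

#' Synthesize a Doppler spectrogram from a known envelope
#'
#' Ground-truth fixture for envelope-recovery testing: a filled spectrum
#' whose magnitude is high for every velocity bin at or below the true
#' envelope `v(t)` and sits at a low noise floor above it, with optional
#' speckle pixels sprinkled above the envelope.
#'
#' @param true_envelope a [velocity_envelope()] (the known `v(t)`).
#' @param noise_floor_db floor magnitude relative to the signal, dB.
#' @param bin_cm_s velocity bin width, cm/s.
#' @param v_max top of the velocity axis, cm/s.
#' @param frame_rate spectrogram frames per second.
#' @param speckle_rate fraction of above-envelope pixels flipped to signal
#'   level (speckle noise).
#' @param seed integer seed for the speckle draw.
#' @return A `doppler_spectrogram` (see [doppler_spectrogram()]).
#' @export
synth_doppler_spectrogram <- function(true_envelope, noise_floor_db = -40,
                                      bin_cm_s = 2, v_max = 200,
                                      frame_rate = 100, speckle_rate = 0,
                                      seed = NULL) {
  stopifnot(inherits(true_envelope, "velocity_envelope"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  fs <- true_envelope$sample_rate
  x <- true_envelope$samples
  dur <- length(x) / fs
  time_axis <- seq(0, dur - 1 / frame_rate, by = 1 / frame_rate)
  velocity_axis <- seq(bin_cm_s, v_max, by = bin_cm_s)
  src_t <- (seq_along(x) - 1L) / fs
  vt <- approx(src_t, x, xout = time_axis, rule = 2)$y
  floor_mag <- 10^(noise_floor_db / 20)
  mag <- matrix(floor_mag, nrow = length(velocity_axis),
                ncol = length(time_axis))
  filled <- outer(velocity_axis, vt, `<=`)
  mag[filled] <- 1
  if (speckle_rate > 0) {
    above <- which(!filled)
    flip <- above[runif(length(above)) < speckle_rate]
    mag[flip] <- 1
  }
  doppler_spectrogram_obj(mag, velocity_axis, time_axis)
}
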