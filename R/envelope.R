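#' Doppler spectrogram container
#'
#' Magnitude spectrogram on a velocity-by-time grid.  Frequency bins map to
#' velocity through the Doppler equation `v = c * f_d / (2 * f0)` with
#' carrier `f0` = 1.75 MHz, speed of sound 1540 m/s and zero insonation
#' angle.
#'
#' @param magnitude non-negative matrix, velocity bins in rows, time frames
#'   in columns.
#' @param velocity_axis strictly increasing, uniform cm/s bin centres.
#' @param time_axis strictly increasing, uniform frame times in seconds.
#' @param carrier_frequency transducer carrier, Hz.
#' @return An object of class `doppler_spectrogram`.
#' @export
doppler_spectrogram_obj <- function(magnitude, velocity_axis, time_axis,
                                    carrier_frequency = 1.75e6) {
  if (!is.matrix(magnitude) || any(!is.finite(magnitude)) || any(magnitude < 0))
    stop("magnitude must be a finite non-negative matrix")
  check_uniform_axis <- function(a, nm) {
    if (length(a) > 1L) {
      d <- diff(a)
      if (any(d <= 0) || (max(d) - min(d)) > 1e-6 * mean(d))
        stop(nm, " must be strictly increasing and uniform")
    }
  }
  check_uniform_axis(velocity_axis, "velocity_axis")
  check_uniform_axis(time_axis, "time_axis")
  if (nrow(magnitude) != length(velocity_axis) ||
      ncol(magnitude) != length(time_axis))
    stop("magnitude dimensions must match the axes")
  structure(list(magnitude = magnitude, velocity_axis = velocity_axis,
                 time_axis = time_axis, carrier_frequency = carrier_frequency),
            class = "doppler_spectrogram")
}

#' @export
print.doppler_spectrogram <- function(x, ...) {
  cat(sprintf("Doppler spectrogram: %d velocity bins (%.1f-%.1f cm/s) x %d frames (%.2f s)\n",
              nrow(x$magnitude), min(x$velocity_axis), max(x$velocity_axis),
              ncol(x$magnitude), diff(range(x$time_axis))))
  invisible(x)
}

#' Short-time Fourier spectrogram of a Doppler-shift signal
#'
#' Computes a magnitude STFT (Hann window) of the audio-range Doppler-shift
#' signal and maps the frequency axis to velocity via
#' `v = c_sound * f / (2 * f0)`.  Frame count is
#' `floor((L - window)/hop) + 1`.
#'
#' @param x real Doppler-shift signal.
#' @param fs sampling rate, Hz.
#' @param window_s,hop_s STFT window and hop, seconds
#'   (defaults 0.05 and 0.01).
#' @param carrier_frequency transducer carrier `f0`, Hz (default 1.75 MHz).
#' @param c_sound speed of sound in tissue, m/s (default 1540).
#' @return A [doppler_spectrogram_obj()]; velocities in cm/s.
#' @export
doppler_spectrogram <- function(x, fs, window_s = 0.05, hop_s = 0.01,
                                carrier_frequency = 1.75e6, c_sound = 1540) {
  if (length(x) == 0L) stop("empty signal")
  if (fs <= 0) stop("fs must be positive")
  if (hop_s <= 0 || window_s < hop_s) stop("need window_s >= hop_s > 0")
  win <- max(2L, round(window_s * fs))
  hop <- max(1L, round(hop_s * fs))
  if (length(x) < win) stop("signal shorter than one STFT window")
  sg <- signal::specgram(x, n = win, Fs = fs, window = signal::hanning(win),
                         overlap = win - hop)
  vel <- c_sound * as.numeric(sg$f) / (2 * carrier_frequency) * 100  # cm/s
  keep <- vel > 0
  doppler_spectrogram_obj(abs(sg$S)[keep, , drop = FALSE], vel[keep],
                          as.numeric(sg$t), carrier_frequency)
}

otsu_threshold <- function(v, n_bins = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(mean(rng))  # constant image: midpoint fallback
  h <- tabulate(pmin(n_bins, 1L + floor((v - rng[1]) / diff(rng) * n_bins)),
                n_bins)
  p <- h / sum(h)
  centers <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  centers[which.max(between)]
}

#' Binarize a spectrogram
#'
#' Converts the magnitude to decibels relative to its maximum (floored at
#' `floor_db` to avoid `log(0)`), picks a global threshold — Otsu's method
#' on the dB image by default — and marks every pixel strictly above it.
#' A constant image falls back to the range midpoint, yielding an all-false
#' mask.
#'
#' @param spec a `doppler_spectrogram`.
#' @param method `"otsu"` or a numeric dB threshold (relative to peak).
#' @param floor_db dB floor applied before thresholding (default -80).
#' @return An object of class `binary_spectrogram`: logical `mask` plus the
#'   source axes and the threshold used.
#' @export
binarize_spectrogram <- function(spec, method = "otsu", floor_db = -80) {
  stopifnot(inherits(spec, "doppler_spectrogram"))
  mx <- max(spec$magnitude)
  db <- if (mx > 0) 20 * log10(pmax(spec$magnitude / mx, 10^(floor_db / 20)))
        else matrix(floor_db, nrow(spec$magnitude), ncol(spec$magnitude))
  thr <- if (is.numeric(method)) method else otsu_threshold(as.numeric(db))
  structure(list(mask = db > thr, velocity_axis = spec$velocity_axis,
                 time_axis = spec$time_axis, threshold_db = thr),
            class = "binary_spectrogram")
}

# Majority (binary median) filter with a kt x kv rectangular kernel via
# summed-area tables; outside pixels count as FALSE, matching a
# zero-padded median.
majority_filter <- function(mask, kv, kt) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  nr <- nrow(m); nc <- ncol(m)
  hv <- (kv - 1L) %/% 2L; ht <- (kt - 1L) %/% 2L
  cs <- rbind(0, apply(m, 2L, cumsum))
  cs <- cbind(0, t(apply(cs, 1L, cumsum)))     # (nr+1) x (nc+1) integral image
  r1 <- pmax(seq_len(nr) - hv, 1L); r2 <- pmin(seq_len(nr) + hv, nr)
  c1 <- pmax(seq_len(nc) - ht, 1L); c2 <- pmin(seq_len(nc) + ht, nc)
  counts <- cs[r2 + 1L, c2 + 1L, drop = FALSE] - cs[r1, c2 + 1L, drop = FALSE] -
    cs[r2 + 1L, c1, drop = FALSE] + cs[r1, c1, drop = FALSE]
  counts > (kv * kt) / 2
}

nearest_odd <- function(x) max(1L, 2L * round((x - 1) / 2) + 1L)

#' Despeckle a binary spectrogram
#'
#' 2D median filter on the binary mask with a physical kernel of 0.03 s
#' (time) by 5 cm/s (velocity), converted to the nearest odd number of bins
#' (minimum 1) from the spectrogram axes.  For a binary image the median
#' filter is a majority vote over the kernel window, so isolated speckle
#' pixels are removed while solid regions are preserved.
#'
#' @param bin a `binary_spectrogram`.
#' @param kernel_t_s,kernel_v_cms physical kernel extents.
#' @return The despeckled `binary_spectrogram`; the kernel used is attached
#'   as the `kernel_bins` element `c(velocity, time)`.
#' @export
despeckle <- function(bin, kernel_t_s = 0.03, kernel_v_cms = 5) {
  stopifnot(inherits(bin, "binary_spectrogram"))
  hop <- if (length(bin$time_axis) > 1L) diff(bin$time_axis[1:2]) else kernel_t_s
  bw <- if (length(bin$velocity_axis) > 1L) diff(bin$velocity_axis[1:2]) else kernel_v_cms
  kt <- nearest_odd(kernel_t_s / hop)
  kv <- nearest_odd(kernel_v_cms / bw)
  out <- bin
  out$mask <- majority_filter(bin$mask, kv, kt)
  out$kernel_bins <- c(velocity = kv, time = kt)
  out
}

#' Trace the maximal flow-velocity envelope
#'
#' Per time frame, the envelope is the top of the highest column run of
#' true pixels whose length is at least `accept_frac` of the column's true
#' pixels (an adaptive per-column acceptance that skips detached noise
#' blobs above the spectrum).  Two physiological sanity checks follow, in
#' order: a range check marking values outside `(0, v_max_physio]` invalid,
#' and a continuity check replacing frame-to-frame jumps larger than
#' `jump_max` by the carried-forward value and flagging them invalid.  The
#' result is resampled to `out_fs` (default 217 Hz) with the validity mask
#' propagated; samples interpolated from any invalid frame are invalid.
#'
#' @param bin a (despeckled) `binary_spectrogram`.
#' @param v_max_physio physiological velocity ceiling, cm/s (default 300).
#' @param jump_max largest plausible frame-to-frame change, cm/s
#'   (default 30).
#' @param accept_frac run-length acceptance fraction (default 0.5).
#' @param out_fs output sampling rate, Hz (default 217).
#' @return A [velocity_envelope()] with `NA` samples where invalid.
#' @export
trace_envelope <- function(bin, v_max_physio = 300, jump_max = 30,
                           accept_frac = 0.5, out_fs = 217) {
  stopifnot(inherits(bin, "binary_spectrogram"))
  vax <- bin$velocity_axis
  nfr <- ncol(bin$mask)
  env <- rep(NA_real_, nfr)
  for (j in seq_len(nfr)) {
    col <- bin$mask[, j]
    total <- sum(col)
    if (total == 0L) next
    r <- rle(col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    for (i in rev(runs)) {            # highest-velocity run first
      if (r$lengths[i] >= accept_frac * total) {
        env[j] <- vax[ends[i]]
        break
      }
    }
  }
  valid <- is.finite(env)
  # sanity check 1: physiological range
  bad <- valid & (env <= 0 | env > v_max_physio)
  env[bad] <- NA_real_
  valid[bad] <- FALSE
  # sanity check 2: continuity — carry forward across implausible jumps
  last <- NA_real_
  for (j in seq_len(nfr)) {
    if (!valid[j]) next
    if (is.finite(last) && abs(env[j] - last) > jump_max) {
      env[j] <- last
      valid[j] <- FALSE
    } else last <- env[j]
  }
  resample_envelope(env, valid, bin$time_axis, out_fs)
}

resample_envelope <- function(env, valid, time_axis, out_fs) {
  t_out <- seq(time_axis[1L], time_axis[length(time_axis)], by = 1 / out_fs)
  if (!any(valid)) {
    return(velocity_envelope(rep(NA_real_, length(t_out)), sample_rate = out_fs,
                             valid_mask = rep(FALSE, length(t_out))))
  }
  vals <- approx(time_axis[valid], env[valid], xout = t_out, rule = 2)$y
  ok <- approx(time_axis, as.numeric(valid), xout = t_out)$y >= 1
  vals[!ok] <- NA_real_
  velocity_envelope(vals, sample_rate = out_fs, valid_mask = ok)
}

#' Extract an envelope from a raw Doppler signal
#'
#' Convenience front-end chaining [doppler_spectrogram()],
#' [binarize_spectrogram()], [despeckle()] and [trace_envelope()].
#'
#' @param x raw Doppler-shift signal.
#' @param fs its sampling rate, Hz.
#' @param window_s,hop_s STFT parameters.
#' @param v_max_physio,jump_max sanity-check parameters of
#'   [trace_envelope()].
#' @param out_fs output envelope rate, Hz.
#' @return A [velocity_envelope()].
#' @export
extract_envelope <- function(x, fs, window_s = 0.05, hop_s = 0.01,
                             v_max_physio = 300, jump_max = 30,
                             out_fs = 217) {
  sp <- doppler_spectrogram(x, fs, window_s, hop_s)
  trace_envelope(despeckle(binarize_spectrogram(sp)),
                 v_max_physio = v_max_physio, jump_max = jump_max,
                 out_fs = out_fs)
}

#' Write / read an envelope as two-column CSV
#'
#' Columns `time_s` and `velocity_cm_s`, with `NA` where the envelope is
#' invalid.
#'
#' @param envelope a [velocity_envelope()]; @param path CSV path.
#' @return `write_envelope_csv` returns `path` invisibly;
#'   `read_envelope_csv` a [velocity_envelope()].
#' @param sample_rate sampling rate assumed when reading, Hz.
#' @export
write_envelope_csv <- function(envelope, path) {
  stopifnot(inherits(envelope, "velocity_envelope"))
  v <- envelope$samples
  v[!envelope$valid_mask] <- NA_real_
  df <- data.frame(time_s = (seq_along(v) - 1L) / envelope$sample_rate,
                   velocity_cm_s = v)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_envelope_csv
#' @export
read_envelope_csv <- function(path, sample_rate = 217) {
  df <- read.csv(path)
  velocity_envelope(df$velocity_cm_s, sample_rate = sample_rate)
}
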