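#' Construct a velocity envelope record
#'
#' The 1D maximal cerebral blood-flow-velocity waveform of one recording
#' session: cm/s samples at a fixed sampling rate (217 Hz after the
#' extraction pipeline) with a validity mask marking signal cuts, plus
#' session metadata.
#'
#' @param samples numeric cm/s values; may contain `NA`/`NaN` where invalid.
#' @param sample_rate sampling rate in Hz (default 217).
#' @param valid_mask logical, same length; defaults to `is.finite(samples)`.
#' @param session_id,subject_id identifier strings.
#' @param class_label `"Healthy"` or `"ICU"` (or `NA` when unknown).
#' @return An object of class `velocity_envelope`.
#' @export
velocity_envelope <- function(samples, sample_rate = 217, valid_mask = NULL,
                              session_id = NA_character_,
                              subject_id = NA_character_,
                              class_label = NA_character_) {
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (is.null(valid_mask)) valid_mask <- is.finite(samples)
  if (length(valid_mask) != length(samples))
    stop("valid_mask must match samples in length")
  if (any(!is.finite(samples[valid_mask])))
    stop("samples must be finite wherever valid_mask is TRUE")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 valid_mask = as.logical(valid_mask),
                 session_id = session_id, subject_id = subject_id,
                 class_label = class_label),
            class = "velocity_envelope")
}

#' @export
print.velocity_envelope <- function(x, ...) {
  cat(sprintf("Velocity envelope: %d samples @ %g Hz (%.1f s), %.1f%% valid",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              100 * mean(x$valid_mask)))
  if (!is.na(x$session_id))
    cat(sprintf(" | session %s, subject %s, class %s",
                x$session_id, x$subject_id, x$class_label))
  cat("\n")
  invisible(x)
}

#' Split an envelope at signal cuts
#'
#' Returns the maximal contiguous runs of valid, finite samples that are at
#' least `min_run` samples long, in temporal order.  Each run is a numeric
#' vector with a `start_index` attribute (0-based offset into the source
#' envelope).
#'
#' @param envelope a [velocity_envelope()] or a numeric vector (invalid
#'   samples encoded as `NA`/`NaN`).
#' @param min_run minimum run length to keep (default 1024, one segment).
#' @return List of numeric vectors; empty list when no run is long enough.
#' @export
remove_cuts <- function(envelope, min_run = 1024L) {
  if (inherits(envelope, "velocity_envelope")) {
    x <- envelope$samples
    ok <- envelope$valid_mask & is.finite(x)
  } else {
    x <- as.numeric(envelope)
    ok <- is.finite(x)
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_run)
  lapply(keep, function(i) {
    run <- x[starts[i]:ends[i]]
    attr(run, "start_index") <- starts[i] - 1L
    run
  })
}

#' Slide fixed-length windows over a contiguous run
#'
#' Windows start at multiples of `stride = floor(length * (1 -
#' overlap_fraction))`; the count is `floor((L - length)/stride) + 1`.
#' With 80% overlap and 1024-sample windows the stride is 204 samples.
#'
#' @param run numeric vector (one contiguous valid run).
#' @param length window length in samples (default 1024).
#' @param overlap_fraction fraction in `[0, 1)` of overlap between
#'   consecutive windows (default 0; training augmentation uses 0.8).
#' @return Matrix with one window per row and a `start_index` attribute
#'   (0-based window starts relative to the run); zero rows when the run is
#'   shorter than `length`.
#' @export
segment_signal <- function(run, length = 1024L, overlap_fraction = 0) {
  length <- as.integer(length)
  if (length < 1L) stop("window length must be positive")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1)")
  stride <- max(1L, as.integer(floor(length * (1 - overlap_fraction))))
  L <- base::length(run)
  if (L < length) {
    out <- matrix(numeric(0), nrow = 0L, ncol = length)
    attr(out, "start_index") <- integer(0)
    return(out)
  }
  starts <- seq.int(0L, L - length, by = stride)
  out <- t(vapply(starts, function(s) run[(s + 1L):(s + length)],
                  numeric(length)))
  attr(out, "start_index") <- as.integer(starts)
  out
}

#' Automatic segment quality annotation
#'
#' Heuristic stand-in for manual annotation.  A segment is `rejected` when
#' it contains any non-finite value, any constant ("plane line") run longer
#' than `flat_run_max` samples, or values outside `(0, v_max]` cm/s.
#' Otherwise it is `corrupted` when its beat-periodicity score — the
#' maximum normalized autocorrelation in the `lag_band` (seconds,
#' default 0.4-1.5 s, i.e. 40-150 bpm) — falls below
#' `periodicity_threshold`, and `clear` otherwise.  Manual labels carried
#' in a manifest always take precedence over this heuristic.
#'
#' @param samples numeric segment (typically 1024 samples).
#' @param fs sampling rate Hz (default 217).
#' @param flat_run_max longest tolerated constant run, samples (default
#'   217, about one second).
#' @param v_max physiological ceiling, cm/s (default 300).
#' @param periodicity_threshold minimum beat-periodicity score for a
#'   `clear` label (default 0.3).
#' @param lag_band autocorrelation search band in seconds.
#' @return One of `"clear"`, `"corrupted"`, `"rejected"`.
#' @export
auto_annotate <- function(samples, fs = 217, flat_run_max = 217L,
                          v_max = 300, periodicity_threshold = 0.3,
                          lag_band = c(0.4, 1.5)) {
  if (any(!is.finite(samples))) return("rejected")
  if (any(samples <= 0 | samples > v_max)) return("rejected")
  d <- rle(abs(diff(samples)) < 1e-9)
  if (any(d$values & (d$lengths + 1L) > flat_run_max)) return("rejected")
  lags <- seq.int(ceiling(lag_band[1] * fs), floor(lag_band[2] * fs))
  lag_max <- max(lags)
  if (lag_max >= length(samples)) return("corrupted")
  ac <- acf(samples, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  score <- max(ac[lags + 1L])
  if (!is.finite(score) || score < periodicity_threshold) "corrupted" else "clear"
}

#' Read or write a cohort manifest
#'
#' The manifest is a CSV with header `path, session_id, subject_id,
#' class_label, quality` — one row per envelope (or segment) file.  A
#' session id must map to exactly one subject and one class.
#'
#' @param manifest data frame in manifest layout.
#' @param path CSV path.
#' @return `read_manifest` returns the validated data frame;
#'   `write_manifest` returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(m)
  m
}

validate_manifest <- function(m) {
  need <- c("session_id", "subject_id", "class_label")
  if (!all(need %in% names(m)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  per <- unique(m[, need])
  if (anyDuplicated(per$session_id))
    stop("a session_id maps to more than one subject or class")
  invisible(TRUE)
}
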