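#' Zero-phase Butterworth bandpass filter
#'
#' 4th-order Butterworth filter applied forward and backward
#' (`signal::filtfilt`), so the pass is zero-phase and peak positions are
#' not shifted — a requirement for downstream RR metrics. The signal is
#' mirror-padded before filtering to suppress edge transients. Presets:
#' ECG 0.4–45 Hz, PPG 0.3–8 Hz.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz; `0 < lo < hi < fs/2`. Defaults come from
#'   `preset`.
#' @param preset `"ecg"` (0.4–45 Hz) or `"ppg"` (0.3–8 Hz); ignored when
#'   `lo`/`hi` are given.
#' @param order filter order (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, fs, lo = NULL, hi = NULL,
                     preset = c("ecg", "ppg"), order = 4) {
  preset <- match.arg(preset)
  if (is.null(lo)) lo <- if (preset == "ecg") 0.4 else 0.3
  if (is.null(hi)) hi <- if (preset == "ecg") 45 else 8
  if (!(lo > 0 && hi > lo)) stop("need 0 < lo < hi")
  if (hi >= fs / 2) stop("`hi` must be below the Nyquist frequency fs/2")
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L) stop("signal too short to filter")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  pad <- min(n - 1L, max(3L * ceiling(fs / lo), 100L))
  xp <- c(2 * x[1] - rev(x[2:(pad + 1L)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1L):(pad + n)]
}

#' Anti-aliased rate conversion
#'
#' Polyphase resampling (`signal::resample`) from `fs_in` to `fs_out`.
#' Output length is `round(length(x) * fs_out / fs_in)`.
#'
#' @param x numeric signal.
#' @param fs_in,fs_out sampling rates in Hz (> 0).
#' @return Resampled signal.
#' @export
resample_signal <- function(x, fs_in, fs_out) {
  if (fs_in <= 0 || fs_out <= 0) stop("sampling rates must be > 0")
  x <- as.numeric(x)
  if (fs_in == fs_out) return(x)
  frac <- .as_ratio(fs_out / fs_in)
  y <- signal::resample(x, frac[1], frac[2])
  n_out <- round(length(x) * fs_out / fs_in)
  length(y) <- n_out  # pads with NA if short
  y[is.na(y)] <- 0
  y
}

# small rational approximation p/q of a positive ratio
.as_ratio <- function(r, max_den = 1000L) {
  best <- c(1L, 1L); err <- Inf
  for (q in 1:max_den) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(r - p / q)
    if (e < err - 1e-15) { best <- c(as.integer(p), q); err <- e }
    if (err < 1e-12) break
  }
  best
}

#' Align a signal pair on their first peaks
#'
#' Left-truncates whichever signal's first detected peak occurs later so
#' that the two first peaks fall on the same sample index, then truncates
#' both to a common length. This removes the ECG-to-PPG transmission delay
#' without explicit synchronization.
#'
#' @param ecg,ppg numeric signals.
#' @param fs sampling rate in Hz.
#' @param min_distance,min_prominence passed to [detect_peaks()].
#' @return List with elements `ecg` and `ppg`, equal length.
#' @export
align_first_peaks <- function(ecg, ppg, fs, min_distance = 50,
                              min_prominence = 0.3) {
  pe <- detect_peaks(ecg, fs, min_distance, min_prominence)
  pp <- detect_peaks(ppg, fs, min_distance, min_prominence)
  if (length(pe$indices) < 1L || length(pp$indices) < 1L)
    stop("both signals must contain at least one detectable peak")
  fe <- pe$indices[1]; fp <- pp$indices[1]
  if (fe < fp) ppg <- ppg[(fp - fe + 1L):length(ppg)]
  else if (fp < fe) ecg <- ecg[(fe - fp + 1L):length(ecg)]
  n <- min(length(ecg), length(ppg))
  list(ecg = ecg[1:n], ppg = ppg[1:n])
}

#' Fixed-window segmentation with overlap
#'
#' Cuts a signal into windows of `window` samples whose starts are spaced
#' `window * (1 - overlap)` samples apart (1-based, half-open windows).
#' An incomplete final window is dropped.
#'
#' @param x numeric signal.
#' @param window window length in samples (default 512).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @param fs sampling rate carried into the result (optional).
#' @return An object of class `segment_set`: list with `segments` (matrix,
#'   one row per window), `starts` (1-based start indices), `window`, `fs`.
#'   A short signal yields zero segments, not an error.
#' @export
segment_signal <- function(x, window = 512, overlap = 0.5, fs = NA_real_) {
  if (window <= 0) stop("`window` must be > 0")
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)")
  x <- as.numeric(x)
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  n <- length(x)
  starts <- if (n >= window) seq(1L, n - window + 1L, by = step) else integer(0)
  seg <- if (length(starts))
    t(vapply(starts, function(s) x[s:(s + window - 1L)], numeric(window)))
  else matrix(numeric(0), nrow = 0, ncol = window)
  structure(list(segments = seg, starts = as.integer(starts),
                 window = as.integer(window), fs = fs),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d windows of %d samples (starts step %s)\n",
              nrow(x$segments), x$window,
              if (length(x$starts) > 1) diff(x$starts)[1] else "-"))
  invisible(x)
}

#' Min-max scaling to a fixed range
#'
#' Linearly maps the record minimum/maximum to the target range (default
#' [-1, 1]). Scaling is applied per record, before segmentation, so windows
#' of one record stay on a common scale. Constant input maps to the range
#' midpoint with a warning.
#'
#' @param x numeric signal.
#' @param range length-2 target range.
#' @return Scaled signal.
#' @export
minmax_scale <- function(x, range = c(-1, 1)) {
  x <- as.numeric(x)
  if (!length(x)) return(x)
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    warning("constant signal: min-max scaling maps it to the range midpoint")
    return(rep(mean(range), length(x)))
  }
  (x - lo) / (hi - lo) * (range[2] - range[1]) + range[1]
}
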