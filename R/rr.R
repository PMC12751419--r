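#' Detect peaks by the distance-and-prominence rule
#'
#' Finds local maxima, discards those whose topographic prominence is below
#' `min_prominence` times the signal range, then enforces the minimum
#' separation `min_distance` greedily from the highest peak down. This is
#' the distance-based finder used for R-peak and PPG systolic-peak
#' detection throughout the package; alternative detectors can be supplied
#' wherever a `detector` argument is accepted.
#'
#' The prominence gate (default 0.3 of the signal range) is what keeps T
#' waves of the built-in morphologies from being reported as R peaks.
#'
#' @param signal numeric vector.
#' @param fs sampling rate in Hz (carried into the result).
#' @param min_distance minimum peak separation in samples (default 50).
#' @param min_prominence minimum prominence as a fraction of the signal
#'   range (default 0.3). Set to 0 to disable.
#' @return An object of class `peak_indices`: list with `indices` (1-based,
#'   strictly increasing) and `fs`. A constant or empty signal yields an
#'   empty result, not an error.
#' @export
detect_peaks <- function(signal, fs, min_distance = 50, min_prominence = 0.3) {
  signal <- as.numeric(signal)
  n <- length(signal)
  empty <- structure(list(indices = integer(0), fs = fs),
                     class = "peak_indices")
  if (n < 3L) return(empty)
  rng <- diff(range(signal))
  if (rng == 0) return(empty)

  left <- signal[1:(n - 2)]; mid <- signal[2:(n - 1)]; right <- signal[3:n]
  cand <- which(mid > left & mid >= right) + 1L
  if (length(cand) == 0L) return(empty)

  if (min_prominence > 0) {
    prom <- vapply(cand, function(i) .prominence(signal, i), numeric(1))
    cand <- cand[prom >= min_prominence * rng]
    if (length(cand) == 0L) return(empty)
  }

  # greedy distance filter, highest peak first (ties: earlier index wins)
  ord <- cand[order(-signal[cand], cand)]
  keep <- logical(0)
  chosen <- integer(0)
  for (i in ord) {
    if (all(abs(chosen - i) >= min_distance)) chosen <- c(chosen, i)
  }
  structure(list(indices = sort(chosen), fs = fs), class = "peak_indices")
}

# topographic prominence of the local maximum at index i: height above the
# higher of the two key saddles found before reaching taller terrain
.prominence <- function(x, i) {
  h <- x[i]
  lmin <- h
  j <- i - 1L
  while (j >= 1L && x[j] <= h) { if (x[j] < lmin) lmin <- x[j]; j <- j - 1L }
  rmin <- h
  j <- i + 1L
  n <- length(x)
  while (j <= n && x[j] <= h) { if (x[j] < rmin) rmin <- x[j]; j <- j + 1L }
  h - max(lmin, rmin)
}

#' @export
print.peak_indices <- function(x, ...) {
  cat("<peak_indices>", length(x$indices), "peaks at fs =", x$fs, "Hz\n")
  invisible(x)
}

#' RR interval series
#'
#' @param intervals numeric vector of inter-beat intervals in milliseconds,
#'   all > 0.
#' @param source_fs sampling rate (Hz) of the signal the intervals came from.
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(intervals, source_fs = NA_real_) {
  intervals <- as.numeric(intervals)
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop("all RR intervals must be finite and > 0")
  structure(list(intervals = intervals, source_fs = source_fs),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d intervals, mean %.1f ms, sd %.1f ms\n",
              length(x$intervals), mean(x$intervals),
              sd_pop(x$intervals)))
  invisible(x)
}

#' RR intervals from detected peaks
#'
#' @param peaks a [detect_peaks()] result with at least two peaks.
#' @return An [rr_series()] with `length(indices) - 1` intervals in ms.
#' @export
rr_from_peaks <- function(peaks) {
  stopifnot(inherits(peaks, "peak_indices"))
  if (length(peaks$indices) < 2L)
    stop("need at least 2 peaks to form RR intervals")
  rr_series(diff(peaks$indices) / peaks$fs * 1000, source_fs = peaks$fs)
}

#' Beat-wise heart rate from RR intervals
#'
#' HR (BPM) = 60 / RR (seconds).
#'
#' @param rr an [rr_series()] or numeric vector of intervals in ms.
#' @return Numeric vector of per-beat heart rates in BPM.
#' @export
hr_from_rr <- function(rr) {
  iv <- as_rr_intervals(rr)
  60 / (iv / 1000)
}

#' Heart-rate variability summary
#'
#' Mean and population standard deviation of the RR intervals (ms).
#'
#' @param rr an [rr_series()] or numeric vector of intervals in ms.
#' @return Named numeric vector `c(mean = , sd = )`.
#' @export
hrv_summary <- function(rr) {
  iv <- as_rr_intervals(rr)
  if (length(iv) < 1L) stop("empty RR series")
  c(mean = mean(iv), sd = sd_pop(iv))
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

as_rr_intervals <- function(rr) {
  iv <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  if (length(iv) && (any(!is.finite(iv)) || any(iv <= 0)))
    stop("all RR intervals must be finite and > 0")
  iv
}

#' Derive a simulation RR schedule from a PPG signal
#'
#' Detects the systolic peaks of a PPG recording and returns the successive
#' peak-to-peak spacings in samples, the form consumed by [simulate_pair()].
#' This is how a synthetic pair is made to emulate the RR-interval
#' distribution of a real recording.
#'
#' @param ppg numeric PPG vector.
#' @param fs sampling rate in Hz.
#' @param min_distance,min_prominence passed to [detect_peaks()].
#' @return Integer vector of peak-to-peak spacings in samples.
#' @export
rr_schedule_from_ppg <- function(ppg, fs, min_distance = 50,
                                 min_prominence = 0.3) {
  pk <- detect_peaks(ppg, fs, min_distance, min_prominence)
  if (length(pk$indices) < 2L)
    stop("PPG must contain at least 2 detectable systolic peaks")
  as.integer(diff(pk$indices))
}
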