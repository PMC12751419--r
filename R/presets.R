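#' Waveform morphology parameters
#'
#' Bundles the per-wave amplitudes `a`, angular widths `b` (radians) and
#' reference angles `theta` (radians, in (-pi, pi]) that shape the ECG trace.
#' Five waves reproduce the canonical P, Q, R, S and T deflections; additional
#' entries model small irregular waves of the arrhythmic morphologies.
#'
#' @param a numeric vector of wave amplitudes (dimensionless, may be negative).
#' @param b numeric vector of angular widths in radians; all strictly positive.
#' @param theta numeric vector of reference angles in radians, in (-pi, pi].
#' @param strict logical; require `theta` to be strictly increasing (the
#'   preset convention). Perturbed parameter sets may relax this.
#' @return An object of class `waveform_params`.
#' @seealso [rhythm_preset()], [perturb_params()]
#' @export
waveform_params <- function(a, b, theta, strict = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b); theta <- as.numeric(theta)
  n <- length(a)
  if (length(b) != n || length(theta) != n)
    stop("`a`, `b` and `theta` must have equal length")
  if (n < 5L)
    stop("at least 5 waves (P, Q, R, S, T) are required; got ", n)
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(!is.finite(theta)))
    stop("waveform parameters must be finite")
  if (any(b <= 0))
    stop("all widths `b` must be strictly positive")
  if (any(theta <= -pi) || any(theta > pi))
    stop("all angles `theta` must lie in (-pi, pi]")
  if (strict && any(diff(theta) <= 0))
    stop("`theta` must be strictly increasing")
  structure(list(a = a, b = b, theta = theta), class = "waveform_params")
}

#' Coupling and baseline constants of the oscillator
#'
#' @param A baseline-wander amplitude (dimensionless, >= 0).
#' @param f0 baseline-wander frequency in cycles per ODE time unit.
#' @param B0,B1,B2 decay/coupling rates of the PPG subsystem
#'   (per ODE time unit, all > 0).
#' @param fbar base cycle frequency in cycles per ODE time unit. At the
#'   default 0.1, a cycle whose RR interval equals the sampling rate in
#'   samples corresponds to a heart rate of 60 BPM.
#' @return An object of class `coupling_constants`.
#' @export
coupling_constants <- function(A = 0.01, f0 = 0.25,
                               B0 = 0.5, B1 = 0.5, B2 = 1.25,
                               fbar = 0.1) {
  vals <- c(A = A, f0 = f0, B0 = B0, B1 = B1, B2 = B2, fbar = fbar)
  if (any(!is.finite(vals))) stop("coupling constants must be finite")
  if (A < 0) stop("`A` must be >= 0")
  if (any(vals[-1] <= 0)) stop("`f0`, `B0`, `B1`, `B2`, `fbar` must be > 0")
  structure(as.list(vals), class = "coupling_constants")
}

#' Rhythm presets
#'
#' Returns the waveform parameter vectors and coupling constants of one of
#' the three built-in rhythm morphologies:
#'
#' * `"rsr"` — regular sinus rhythm, the five canonical waves;
#' * `"sa"`  — sinus arrhythmia, seven waves (two extra entries model the
#'   erratic P waves);
#' * `"afib"` — atrial fibrillation, eleven waves (six extra entries model
#'   the fibrillatory P/T activity).
#'
#' @param name rhythm label, one of `"rsr"`, `"sa"`, `"afib"`
#'   (case-insensitive).
#' @return An object of class `rhythm_preset`: a list with elements `name`,
#'   `params` ([waveform_params()]) and `constants` ([coupling_constants()]).
#' @examples
#' rhythm_preset("rsr")$params$a
#' length(rhythm_preset("afib")$params$a)
#' @export
rhythm_preset <- function(name) {
  key <- tolower(as.character(name)[1])
  params <- switch(key,
    rsr = waveform_params(
      a = c(1.2, -5.0, 30.0, -7.5, 0.75),
      b = c(0.25, 0.1, 0.1, 0.1, 0.4),
      theta = c(-pi / 3, -pi / 12, 0, pi / 12, pi / 2)),
    sa = waveform_params(
      a = c(1.0, 2.0, 3.0, 3.0, 2.5, -1.0, 0.5),
      b = c(0.2, 0.15, 0.15, 0.2, 0.15, 0.2, 0.4),
      theta = c(-pi / 1.5, -pi / 2.0, -pi / 6.5, -pi / 12.0, 0,
                pi / 12.0, pi / 1.5)),
    afib = waveform_params(
      a = c(-1.0, 0.5, 1.0, -2.0, 25.0, -10.0, 2.0, -2.0, 0.5, 0.5, 0.5),
      b = c(0.1, 0.15, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.2, 0.2, 0.2),
      theta = c(-pi / 2.0, -pi / 3.0, -pi / 5.0, -pi / 12.0, 0,
                pi / 12.0, pi / 6.0, pi / 5.0, pi / 2.5, pi / 2.0, pi / 1.5)),
    stop("unknown rhythm '", name, "'; valid names are: rsr, sa, afib")
  )
  structure(list(name = key, params = params,
                 constants = coupling_constants()),
            class = "rhythm_preset")
}

#' @export
print.rhythm_preset <- function(x, ...) {
  cat("<rhythm_preset>", toupper(x$name), "-", length(x$params$a),
      "waves; fbar =", x$constants$fbar, "\n")
  invisible(x)
}

#' @export
print.waveform_params <- function(x, ...) {
  cat("<waveform_params>", length(x$a), "waves\n")
  print(rbind(a = x$a, b = x$b, theta = x$theta))
  invisible(x)
}
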