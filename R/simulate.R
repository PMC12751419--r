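#' Time derivatives of the coupled ECG-PPG oscillator
#'
#' Evaluates the right-hand side of the five-state system. The pair (x, y)
#' rotates on an attracting unit limit cycle at angular rate omega = 2*pi*f;
#' the ECG trace z is forced by one Gaussian bump per wave at angle
#' `theta[i]` and relaxed towards the baseline z0 = A*sin(2*pi*f0*t); the
#' PPG trace v and its intermediary w are driven by z^2 with linear decay:
#' dv/dt = -B0*v + B1*w, dw/dt = z^2 - B2*w.
#'
#' Angle differences theta - theta_i are wrapped into (-pi, pi].
#'
#' @param state numeric length-5 state vector c(x, y, z, v, w).
#' @param t ODE time.
#' @param params a [waveform_params()] object.
#' @param constants a [coupling_constants()] object.
#' @param f cycle frequency in cycles per ODE time unit (> 0).
#' @return Numeric length-5 vector of rates c(dx, dy, dz, dv, dw).
#' @export
ode_derivatives <- function(state, t, params, constants, f) {
  if (length(state) != 5L || any(!is.finite(state)))
    stop("`state` must be a finite length-5 vector (integration blow-up?)")
  if (!is.finite(f) || f <= 0) stop("`f` must be > 0")
  x <- state[1]; y <- state[2]; z <- state[3]; v <- state[4]; w <- state[5]
  alpha <- 1 - sqrt(x^2 + y^2)
  theta <- atan2(y, x)
  omega <- 2 * pi * f
  dth <- wrap_angle(theta - params$theta)
  forcing <- sum(params$a * dth * exp(-dth^2 / (2 * params$b^2)))
  z0 <- constants$A * sin(2 * pi * constants$f0 * t)
  c(alpha * x - omega * y,
    alpha * y + omega * x,
    -forcing - (z - z0),
    -constants$B0 * v + constants$B1 * w,
    z^2 - constants$B2 * w)
}

# wrap angles into (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Per-cycle frequency from an RR interval
#'
#' When the RR interval of cycle c deviates from the mean RR interval, the
#' cycle frequency is rescaled as f = fbar * rr_mean / rr_c, so that the
#' cycle spans exactly `rr_c` output samples.
#'
#' @param fbar base cycle frequency (cycles per ODE time unit).
#' @param rr_mean mean RR interval of the schedule, in samples.
#' @param rr_c RR interval of this cycle, in samples.
#' @return The cycle frequency (may be vectorized over `rr_c`).
#' @examples
#' frequency_for_cycle(0.1, 125, 250) # half the base frequency
#' @export
frequency_for_cycle <- function(fbar, rr_mean, rr_c) {
  if (!is.finite(fbar) || fbar <= 0) stop("`fbar` must be > 0")
  if (!is.finite(rr_mean) || rr_mean <= 0) stop("`rr_mean` must be > 0")
  if (any(!is.finite(rr_c)) || any(rr_c <= 0)) stop("`rr_c` must be > 0")
  fbar * rr_mean / rr_c
}

#' Inject white parameter noise
#'
#' Adds independent Gaussian noise to every element of the waveform
#' parameter vectors: each value p is replaced by p + N(0, (frac*|p|)^2).
#' Widths `b` are clipped to remain strictly positive. Uses the current R
#' random number stream, so results are reproducible under `set.seed()`.
#'
#' @param params a [waveform_params()] object.
#' @param frac noise fraction (standard deviation as a fraction of |p|);
#'   the simulation default is 0.1.
#' @return A perturbed `waveform_params` object. Angle ordering is not
#'   re-imposed after perturbation.
#' @export
perturb_params <- function(params, frac = 0.1) {
  stopifnot(inherits(params, "waveform_params"))
  if (!is.finite(frac) || frac < 0) stop("`frac` must be >= 0")
  if (frac == 0) return(params)
  jitter <- function(p) p + rnorm(length(p), mean = 0, sd = frac * abs(p))
  b <- pmax(jitter(params$b), 1e-6)
  waveform_params(jitter(params$a), b,
                  wrap_angle(jitter(params$theta)), strict = FALSE)
}

#' Simulate a paired synthetic ECG and PPG signal
#'
#' Integrates the coupled oscillator with a classical fixed-step 4th-order
#' Runge-Kutta scheme, one step per output sample, from the initial state
#' u0 = (1/sqrt(2), 1/sqrt(2), 0.2, 0.005, 0). The ODE time step is
#' dt = 1 / (fbar * mean(rr_schedule)) per sample, so a cycle running at the
#' base frequency spans exactly the mean RR interval in samples. The angular
#' rate is piecewise constant: cycle c runs at
#' `frequency_for_cycle(fbar, mean(rr_schedule), rr_schedule[c])` and the
#' rate switches when the phase crosses the R-peak angle (theta = 0), so
#' consecutive R peaks are separated by exactly the scheduled number of
#' samples (up to integration tolerance).
#'
#' The raw traces are unnormalized; amplitude scaling to [-1, 1] belongs to
#' the preprocessing chain (see [minmax_scale()]).
#'
#' @param preset a [rhythm_preset()] object.
#' @param rr_schedule integer vector of per-cycle RR intervals in samples;
#'   all entries > 0.
#' @param fs output sampling rate in Hz (default 125).
#' @param seed integer seed for the parameter-noise draw, or `NULL` to use
#'   the current RNG stream.
#' @param noise_frac fraction for [perturb_params()]; one perturbation is
#'   drawn per signal pair. 0 disables noise.
#' @param return_states if `TRUE`, attach the full 5-column state matrix.
#' @return An object of class `signal_pair`: list with `ecg`, `ppg`
#'   (numeric, length `sum(rr_schedule)`), `fs`, `rr_schedule`, `rhythm`,
#'   `seed`, `noise_frac` and (optionally) `states`.
#' @examples
#' pair <- simulate_pair(rhythm_preset("rsr"), rep(125L, 10), fs = 125)
#' length(pair$ecg)
#' @export
simulate_pair <- function(preset, rr_schedule, fs = 125, seed = NULL,
                          noise_frac = 0, return_states = FALSE) {
  stopifnot(inherits(preset, "rhythm_preset"))
  rr_schedule <- as.integer(round(rr_schedule))
  if (length(rr_schedule) == 0L) stop("`rr_schedule` must be non-empty")
  if (any(!is.finite(rr_schedule)) || any(rr_schedule <= 0L))
    stop("all `rr_schedule` entries must be > 0")
  if (!is.finite(fs) || fs <= 0) stop("`fs` must be > 0")
  if (!is.null(seed)) set.seed(as.integer(seed))

  params <- perturb_params(preset$params, noise_frac)
  cst <- preset$constants
  rr_mean <- mean(rr_schedule)
  dt <- 1 / (cst$fbar * rr_mean)
  f_per_cycle <- frequency_for_cycle(cst$fbar, rr_mean, rr_schedule)
  u0 <- c(1 / sqrt(2), 1 / sqrt(2), 0.2, 0.005, 0)

  states <- .integrate_pair_cpp(u0, params$a, params$b, params$theta,
                                cst$A, cst$f0, cst$B0, cst$B1, cst$B2,
                                2 * pi * f_per_cycle, rr_schedule, dt)
  out <- structure(list(ecg = states[, 3], ppg = states[, 4], fs = fs,
                        rr_schedule = rr_schedule, rhythm = preset$name,
                        seed = seed, noise_frac = noise_frac,
                        params = params),
                   class = "signal_pair")
  if (return_states) out$states <- states
  out
}

#' @export
print.signal_pair <- function(x, ...) {
  cat(sprintf("<signal_pair> %s: %d samples at %g Hz (%.1f s), %d cycles%s\n",
              toupper(x$rhythm), length(x$ecg), x$fs, length(x$ecg) / x$fs,
              length(x$rr_schedule),
              if (x$noise_frac > 0)
                sprintf(", %g%% parameter noise", 100 * x$noise_frac)
              else ""))
  invisible(x)
}

#' Draw a Gaussian RR schedule
#'
#' Helper for building simulation inputs: draws per-cycle RR intervals from
#' N(`mean_ms`, `sd_ms`^2), converts them to samples at `fs` and truncates
#' at +/- 3 SD (and at a floor of 2 samples) so intervals stay positive.
#' Enough cycles are drawn to cover `duration_s` seconds.
#'
#' @param duration_s target duration in seconds.
#' @param mean_ms mean RR interval in milliseconds.
#' @param sd_ms standard deviation of the RR interval in milliseconds.
#' @param fs sampling rate in Hz.
#' @return Integer vector of per-cycle RR intervals in samples.
#' @export
rr_schedule_gaussian <- function(duration_s, mean_ms, sd_ms, fs = 125) {
  if (mean_ms <= 0 || sd_ms < 0) stop("invalid RR distribution parameters")
  n <- ceiling(duration_s * 1000 / mean_ms) + 5L
  ms <- rnorm(n, mean_ms, sd_ms)
  ms <- pmin(pmax(ms, mean_ms - 3 * sd_ms), mean_ms + 3 * sd_ms)
  smp <- pmax(2L, as.integer(round(ms * fs / 1000)))
  keep <- which(cumsum(smp) <= duration_s * fs)
  if (length(keep) < 1L) keep <- 1L
  smp[keep]
}
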