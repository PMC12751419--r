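test_that("the compiled integrator matches an R-side RK4 oracle", {
  preset <- rhythm_preset("rsr")
  sched <- rep(125L, 3)
  pair <- simulate_pair(preset, sched, 125, noise_frac = 0,
                        return_states = TRUE)
  cst <- preset$constants
  dt <- 1 / (cst$fbar * mean(sched))
  f <- frequency_for_cycle(cst$fbar, mean(sched), sched[1])
  u <- c(1 / sqrt(2), 1 / sqrt(2), 0.2, 0.005, 0)
  t <- 0
  for (s in 1:10) {
    expect_equal(unname(pair$states[s, ]), u, tolerance = 1e-12)
    k1 <- ode_derivatives(u, t, preset$params, cst, f)
    k2 <- ode_derivatives(u + dt / 2 * k1, t + dt / 2, preset$params, cst, f)
    k3 <- ode_derivatives(u + dt / 2 * k2, t + dt / 2, preset$params, cst, f)
    k4 <- ode_derivatives(u + dt * k3, t + dt, preset$params, cst, f)
    u <- u + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
})

test_that("the orbit settles on the unit limit cycle", {
  st <- simulate_pair(rhythm_preset("rsr"), rep(125L, 3), 125,
                      return_states = TRUE)$states
  r <- sqrt(st[, 1]^2 + st[, 2]^2)
  expect_lt(abs(r[125] - 1), 0.01)        # within 1% after one cycle
  expect_lt(max(abs(r[250:375] - 1)), 0.01)
})

test_that("constant schedules give metronomic R peaks at the right rate", {
  pair <- make_pair("rsr", duration_s = 60, rr_mean_ms = 1000, rr_sd_ms = 0)
  pk <- detect_peaks(pair$ecg, pair$fs)
  spacing <- diff(pk$indices)
  expect_true(all(abs(spacing - 125) <= 1))
  hr <- mean(hr_from_rr(rr_from_peaks(pk)))
  expect_lt(abs(hr - 60), 1)
})

test_that("a variable schedule is recovered beat by beat from the ECG", {
  set.seed(42)
  sched <- rr_schedule_gaussian(60, 800, 40, 125)
  pair <- simulate_pair(rhythm_preset("rsr"), sched, 125, seed = 7,
                        noise_frac = 0.1)
  det <- diff(detect_peaks(pair$ecg, 125)$indices)
  # the first scheduled cycle is partial (the orbit starts just past the
  # R-peak phase), so detected intervals line up with sched[-1]
  tgt <- sched[-1]
  k <- min(length(det), length(tgt))
  expect_gt(k, 50)
  expect_true(all(abs(det[1:k] - tgt[1:k]) <= 2))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  sched <- rep(100L, 10)
  a <- simulate_pair(rhythm_preset("afib"), sched, 125, seed = 3,
                     noise_frac = 0.1)
  b <- simulate_pair(rhythm_preset("afib"), sched, 125, seed = 3,
                     noise_frac = 0.1)
  expect_identical(a$ecg, b$ecg)
  expect_identical(a$ppg, b$ppg)
  c <- simulate_pair(rhythm_preset("afib"), sched, 125, seed = 4,
                     noise_frac = 0.1)
  expect_false(identical(a$ecg, c$ecg))
})

test_that("the PPG trace is non-negative once the transient has passed", {
  for (rh in c("rsr", "sa", "afib")) {
    pair <- make_pair(rh, duration_s = 30, seed = 2, noise_frac = 0.1)
    expect_true(all(pair$ppg[500:length(pair$ppg)] >= 0))
  }
})

test_that("with zero forcing and no baseline drive the ECG state decays", {
  quiet <- structure(list(
    name = "quiet",
    params = waveform_params(rep(0, 5), rep(0.1, 5),
                             seq(-1, 1, length.out = 5)),
    constants = coupling_constants(A = 0)), class = "rhythm_preset")
  st <- simulate_pair(quiet, rep(125L, 4), 125, return_states = TRUE)$states
  expect_lt(abs(st[nrow(st), 3]), 0.01 * 0.2)  # z: 0.2 -> ~0
})

test_that("invalid schedules are rejected", {
  p <- rhythm_preset("rsr")
  expect_error(simulate_pair(p, integer(0), 125), "non-empty")
  expect_error(simulate_pair(p, c(100, 0), 125), "> 0")
  expect_error(simulate_pair(p, c(100, -5), 125), "> 0")
  expect_error(simulate_pair(p, rep(100, 5), fs = 0), "fs")
})

test_that("output length equals the scheduled sample count", {
  sched <- c(100L, 120L, 90L)
  pair <- simulate_pair(rhythm_preset("sa"), sched, 125)
  expect_length(pair$ecg, sum(sched))
  expect_length(pair$ppg, sum(sched))
})
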