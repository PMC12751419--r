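# Shared fixtures, built in code at test time.

# a clean (or noisy) synthetic pair with a Gaussian RR schedule
make_pair <- function(rhythm = "rsr", duration_s = 30, rr_mean_ms = 800,
                      rr_sd_ms = 8, fs = 125, seed = 1, noise_frac = 0) {
  set.seed(seed)
  sched <- rr_schedule_gaussian(duration_s, rr_mean_ms, rr_sd_ms, fs)
  pair <- simulate_pair(rhythm_preset(rhythm), sched, fs, seed = seed,
                        noise_frac = noise_frac)
  pair$schedule <- sched
  pair
}

# aligned min-max scaled segment matrices for a set of pairs
make_segment_bank <- function(rhythms, n_per, duration_s = 20, seed0 = 100,
                              noise_frac = 0.1) {
  ppg <- list(); ecg <- list(); labels <- character(0)
  k <- 0L
  for (rh in rhythms) for (i in seq_len(n_per)) {
    k <- k + 1L
    set.seed(seed0 + k)
    sched <- rr_schedule_gaussian(duration_s, runif(1, 600, 900),
                                  runif(1, 3, 12), 125)
    pair <- simulate_pair(rhythm_preset(rh), sched, 125, seed = seed0 + k,
                          noise_frac = noise_frac)
    prep <- prepare_record(pair)
    ppg[[k]] <- prep$ppg_segments$segments
    ecg[[k]] <- prep$ecg_segments$segments
    labels[k] <- rh
  }
  list(ppg = ppg, ecg = ecg, rhythm = labels)
}

# independent unit-earth transport oracles for the earth mover's distance
# between equal-mass unit histograms: exhaustive over matchings for small
# totals, sorted (monotone) matching otherwise
emd_unit_earth <- function(counts_a, counts_b, exhaustive = FALSE) {
  pos_a <- rep(seq_along(counts_a) - 1L, counts_a)
  pos_b <- rep(seq_along(counts_b) - 1L, counts_b)
  stopifnot(length(pos_a) == length(pos_b))
  if (exhaustive) {
    perms <- function(v) {
      if (length(v) <= 1L) return(list(v))
      out <- list()
      for (i in seq_along(v))
        out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
      out
    }
    min(vapply(perms(pos_b), function(p) sum(abs(pos_a - p)), numeric(1)))
  } else {
    sum(abs(sort(pos_a) - sort(pos_b)))
  }
}

# Denman-Beavers iteration for the square root of a matrix with positive
# spectrum (independent of the eigendecomposition route)
sqrtm_db <- function(a, iter = 60) {
  y <- a; z <- diag(nrow(a))
  for (i in seq_len(iter)) {
    y1 <- 0.5 * (y + solve(z))
    z <- 0.5 * (z + solve(y))
    y <- y1
  }
  y
}
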