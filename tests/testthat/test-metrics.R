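test_that("shared unit histograms bin both samples on one integer grid", {
  h <- shared_unit_histograms(c(1.2, 2.7, 2.9), c(5.1, 5.9))
  expect_equal(h$a$edges, 1:5)
  expect_equal(h$a$counts, c(1, 2, 0, 0, 0))
  expect_equal(h$b$counts, c(0, 0, 0, 0, 2))
  expect_equal(sum(h$a$counts), 3)
  expect_error(unit_histogram(c(1, 2), edges = c(0, 2)), "unit width")
  expect_error(unit_histogram(c(-1, 2)), "non-negative")
})

test_that("relative histogram intersection handles the canonical cases", {
  a <- unit_histogram(c(2, 3, 1))
  expect_equal(rhi(a, a), 1)
  expect_equal(rhi(unit_histogram(c(2, 0)), unit_histogram(c(0, 2))), 0)
  expect_equal(rhi(unit_histogram(c(2, 0)), unit_histogram(c(1, 1))), 0.5)
  # sample interface
  expect_equal(rhi(c(1, 1, 2), c(1, 2, 2)), 2 / 3)
  expect_error(rhi(unit_histogram(c(0, 0)), a), "empty|grid")
})

test_that("rEMD matches independent unit-earth transport oracles", {
  expect_equal(remd(unit_histogram(c(1, 2, 1)), unit_histogram(c(1, 2, 1))), 0)
  # all mass at bin 0 vs bin k of m bins -> k/(m-1)
  for (m in 3:6) for (k in c(1, m - 1)) {
    ca <- numeric(m); ca[1] <- 4
    cb <- numeric(m); cb[k + 1] <- 4
    expect_equal(remd(unit_histogram(ca), unit_histogram(cb)), k / (m - 1))
  }
  set.seed(7)
  # exhaustive matching oracle for totals <= 6
  for (rep in 1:20) {
    nb <- sample(2:6, 1)
    n <- sample(2:6, 1)
    ca <- tabulate(sample.int(nb, n, replace = TRUE), nb)
    cb <- tabulate(sample.int(nb, n, replace = TRUE), nb)
    expected <- emd_unit_earth(ca, cb, exhaustive = TRUE) / (n * (nb - 1))
    expect_equal(remd(unit_histogram(ca), unit_histogram(cb)), expected,
                 tolerance = 1e-12)
  }
  # sorted-matching oracle for totals <= 10
  for (rep in 1:20) {
    nb <- sample(2:6, 1)
    n <- sample(2:10, 1)
    ca <- tabulate(sample.int(nb, n, replace = TRUE), nb)
    cb <- tabulate(sample.int(nb, n, replace = TRUE), nb)
    expected <- emd_unit_earth(ca, cb) / (n * (nb - 1))
    expect_equal(remd(unit_histogram(ca), unit_histogram(cb)), expected,
                 tolerance = 1e-12)
    expect_equal(remd(unit_histogram(ca), unit_histogram(cb)),
                 remd(unit_histogram(cb), unit_histogram(ca)))
  }
  # a single shared bin carries equal mass after renormalization: cost 0
  expect_equal(remd(unit_histogram(3), unit_histogram(3)), 0)
  expect_equal(remd(unit_histogram(3, 5), unit_histogram(2, 5)), 0)
})

test_that("KL divergence matches direct summation and is asymmetric", {
  a <- unit_histogram(c(2, 2))
  expect_equal(kl_divergence(a, a), 0)
  b <- unit_histogram(c(1, 3))
  expected <- 0.5 * log(2) + 0.5 * log(2 / 3)
  expect_equal(kl_divergence(a, b), expected, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(kl_divergence(a, b), kl_divergence(b, a))))
  expect_gte(kl_divergence(b, a), 0)
  # smoothing keeps zero bins finite
  expect_true(is.finite(kl_divergence(unit_histogram(c(4, 0)),
                                      unit_histogram(c(0, 4)))))
})

test_that("the KS statistic equals the brute-force CDF supremum", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(1, 2, 3), c(4, 5, 6)), 1)
  set.seed(12)
  for (rep in 1:10) {
    a <- round(rnorm(sample(5:40, 1), 0, 2), 1)
    b <- round(rnorm(sample(5:40, 1), 0.5, 2), 1)
    pool <- c(a, b)
    brute <- max(vapply(pool, function(t)
      abs(mean(a <= t) - mean(b <= t)), numeric(1)))
    expect_equal(ks_statistic(a, b), brute)
    # cross-check against the stats implementation
    expect_equal(ks_statistic(a, b),
                 unname(suppressWarnings(stats::ks.test(a, b)$statistic)))
  }
})

test_that("rRMSE pairs sorted series and quantile-matches unequal lengths", {
  expect_equal(rrmse(c(1000, 900), c(900, 1000)), 0)
  expect_equal(rrmse(c(1000, 1000), c(1010, 1010)), 0.01)
  set.seed(4)
  a <- runif(9, 700, 900)
  b <- runif(14, 650, 950)
  n <- length(a)
  sb <- sort(b)
  qb <- vapply(seq_len(n), function(i) {
    h <- (i - 1) / (n - 1) * (length(b) - 1)
    lo <- floor(h)
    sb[lo + 1] * (1 - (h - lo)) + sb[min(lo + 2, length(b))] * (h - lo)
  }, numeric(1))
  expected <- sqrt(mean((sort(a) - qb)^2)) / mean(a)
  expect_equal(rrmse(a, b), expected, tolerance = 1e-9)
})

test_that("waveform RMSE matches a two-pass oracle", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2), c(0, 1)), 1)
  set.seed(5)
  x <- rnorm(500); y <- rnorm(500)
  expect_equal(rmse(x, y), sqrt(sum((x - y)^2) / 500), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("heart-rate MAE converts and truncates correctly", {
  expect_equal(mae_hr(c(1000, 1000), c(1000, 1000)), 0)
  # HR pairs (60, 60) vs (62, 58)
  g <- 60000 / c(60, 60); r <- 60000 / c(62, 58)
  expect_equal(mae_hr(g, r), 2)
  expect_equal(mae_hr(1000, 1200), 10)
  expect_equal(mae_hr(c(1000, 500), 1000), 0)  # truncated to min length
})

test_that("Frechet distance matches closed forms and a matrix-sqrt oracle", {
  set.seed(6)
  feats <- matrix(rnorm(40 * 3), 40)
  cl <- feature_cloud(feats)
  expect_equal(frechet_distance(cl, cl), 0, tolerance = 1e-9)

  # 1-D closed form: unit variances, mean shift 1 -> FD = 1
  r <- feature_cloud(mu = 0, sigma = matrix(1))
  g <- feature_cloud(mu = 1, sigma = matrix(1))
  expect_equal(frechet_distance(r, g), 1, tolerance = 1e-9)

  # random 3-D Gaussians vs Denman-Beavers square-root oracle
  for (rep in 1:5) {
    a <- crossprod(matrix(rnorm(9), 3)) + diag(3) * 0.5
    b <- crossprod(matrix(rnorm(9), 3)) + diag(3) * 0.5
    mu_r <- rnorm(3); mu_g <- rnorm(3)
    fd <- frechet_distance(feature_cloud(mu = mu_r, sigma = a),
                           feature_cloud(mu = mu_g, sigma = b))
    oracle <- sum((mu_r - mu_g)^2) +
      sum(diag(a + b - 2 * sqrtm_db(a %*% b)))
    expect_equal(fd, oracle, tolerance = 1e-6)
  }

  # symmetry and non-negativity on random clouds
  x <- feature_cloud(matrix(rnorm(30 * 4), 30))
  y <- feature_cloud(matrix(rnorm(25 * 4, 0.3), 25))
  expect_equal(frechet_distance(x, y), frechet_distance(y, x),
               tolerance = 1e-9)
  expect_gte(frechet_distance(x, y), 0)
  expect_error(frechet_distance(x, feature_cloud(matrix(rnorm(30), 10))),
               "dimensions differ")
})

test_that("the default feature extractor is deterministic and exchangeable", {
  set.seed(9)
  seg <- matrix(rnorm(6 * 512), 6)
  f1 <- extract_features(seg)
  f2 <- extract_features(seg)
  expect_identical(f1$mu, f2$mu)
  expect_match(f1$extractor, "STFT")
  expect_equal(frechet_distance(f1, f2), 0, tolerance = 1e-9)
  # permuting segments leaves the Gaussian summary unchanged
  f3 <- extract_features(seg[c(3, 1, 6, 2, 5, 4), ])
  expect_equal(f3$mu, f1$mu)
  expect_equal(f3$sigma, f1$sigma)
  expect_error(extract_features(seg[1, , drop = FALSE]), "at least 2")
  fr <- extract_features(seg, type = "raw")
  expect_match(fr$extractor, "raw")
})

test_that("metric reports carry the full comparison bundle", {
  pair <- make_pair("rsr", duration_s = 30, seed = 10)
  rr <- rr_from_peaks(detect_peaks(pair$ecg, 125))
  rep <- metric_report(rr, rr, pair$ecg, pair$ecg)
  expect_equal(rep$rhi, 1)
  expect_equal(rep$remd, 0)
  expect_equal(rep$ks, 0)
  expect_equal(rep$kl, 0, tolerance = 1e-9)
  expect_equal(rep$rmse, 0)
  expect_equal(rep$mae_hr, 0)
  expect_output(print(rep), "rHI")
})
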