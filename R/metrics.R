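#' Unit-width histogram
#'
#' Histogram with contiguous integer-edge bins of width 1 (milliseconds for
#' RR work). Bin i covers the half-open interval [edges[i], edges[i] + 1).
#'
#' @param counts non-negative counts, one per bin.
#' @param edges integer left edges, contiguous (`edges[i+1] = edges[i] + 1`);
#'   either length `length(counts)` (left edges) or `length(counts) + 1`.
#' @return An object of class `unit_histogram`.
#' @export
unit_histogram <- function(counts, edges = seq_along(counts) - 1) {
  counts <- as.numeric(counts)
  if (length(edges) == length(counts) + 1L) edges <- edges[-length(edges)]
  if (length(edges) != length(counts))
    stop("`edges` must give one left edge per bin")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(edges) > 1L && any(diff(edges) != 1))
    stop("bins must be contiguous with unit width")
  structure(list(counts = counts, edges = as.numeric(edges)),
            class = "unit_histogram")
}

#' Build two unit histograms on a shared grid
#'
#' Bins both samples into unit-width integer-edge bins spanning the union
#' of their supports, so bin-wise metrics compare like with like.
#'
#' @param a,b numeric samples (e.g. RR intervals in ms) or [rr_series()].
#' @return List of two `unit_histogram`s on the identical grid.
#' @export
shared_unit_histograms <- function(a, b) {
  a <- round(as_rr_or_numeric(a), 9); b <- round(as_rr_or_numeric(b), 9)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  lo <- floor(min(a, b)); hi <- floor(max(a, b))
  edges <- lo:hi
  bin <- function(x) tabulate(floor(x) - lo + 1L, nbins = length(edges))
  list(a = unit_histogram(bin(a), edges),
       b = unit_histogram(bin(b), edges))
}

as_rr_or_numeric <- function(x) {
  if (inherits(x, "rr_series")) x$intervals else as.numeric(x)
}

# resolve a pair of inputs into two unit histograms on one grid
.hist_pair <- function(a, b) {
  if (inherits(a, "unit_histogram") && inherits(b, "unit_histogram")) {
    if (length(a$counts) != length(b$counts) ||
        any(a$edges != b$edges))
      stop("histograms must share the same bin grid")
    if (sum(a$counts) == 0 || sum(b$counts) == 0)
      stop("empty histogram")
    list(a = a, b = b)
  } else {
    shared_unit_histograms(a, b)
  }
}

#' Relative histogram intersection
#'
#' `rHI = sum_i min(count_A(i), count_B(i)) / min(sum A, sum B)`, in
#' [0, 1] with 1 for identical histograms.
#'
#' @param a,b numeric samples, [rr_series()], or two [unit_histogram()]s on
#'   a shared grid.
#' @return Scalar in [0, 1].
#' @export
rhi <- function(a, b) {
  h <- .hist_pair(a, b)
  sum(pmin(h$a$counts, h$b$counts)) / min(sum(h$a$counts), sum(h$b$counts))
}

#' Relative earth mover's distance
#'
#' The EMD between two unit-width histograms is the L1 distance between
#' their cumulative counts times the bin width; it is normalized by the
#' maximum possible EMD, `TotalEarth * MaxDistance`, with TotalEarth the
#' reference histogram A's total count and MaxDistance the span
#' `(nbins - 1) * binwidth`. B's counts are rescaled to A's total before
#' the comparison so both carry equal mass.
#'
#' @inheritParams rhi
#' @return Scalar in [0, 1]; 0 for identical histograms.
#' @export
remd <- function(a, b) {
  h <- .hist_pair(a, b)
  ca <- h$a$counts
  cb <- h$b$counts * sum(ca) / sum(h$b$counts)
  nb <- length(ca)
  # a single shared bin: after mass renormalization both histograms are
  # identical, so the transport cost is zero
  if (nb == 1L) return(0)
  sum(abs(cumsum(ca) - cumsum(cb))) / (sum(ca) * (nb - 1))
}

#' Kullback-Leibler divergence between binned distributions
#'
#' Counts are normalized to probabilities, smoothed additively by `eps`,
#' renormalized, and compared with `sum(P * log(P / Q))` (natural log).
#' Asymmetric: `kl_divergence(a, b) != kl_divergence(b, a)` in general.
#'
#' @inheritParams rhi
#' @param eps additive smoothing applied to the probabilities (default 1e-9).
#' @return Non-negative scalar.
#' @export
kl_divergence <- function(a, b, eps = 1e-9) {
  h <- .hist_pair(a, b)
  p <- h$a$counts / sum(h$a$counts) + eps
  q <- h$b$counts / sum(h$b$counts) + eps
  p <- p / sum(p); q <- q / sum(q)
  sum(p * log(p / q))
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum over the pooled sample points of the absolute difference
#' between the two empirical cumulative distribution functions.
#'
#' @param a,b numeric samples or [rr_series()].
#' @return Scalar in [0, 1].
#' @export
ks_statistic <- function(a, b) {
  # round away float fuzz so equal physical values pool into one point
  a <- round(as_rr_or_numeric(a), 9); b <- round(as_rr_or_numeric(b), 9)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  pool <- sort(unique(c(a, b)))
  fa <- vapply(pool, function(t) mean(a <= t), numeric(1))
  fb <- vapply(pool, function(t) mean(b <= t), numeric(1))
  max(abs(fa - fb))
}

#' Relative RMSE between two RR-interval series
#'
#' The two series are paired monotonically: both are sorted, and when the
#' lengths differ B is quantile-interpolated onto A's N points. The RMSE of
#' the paired differences is divided by A's mean interval.
#'
#' @param a reference (real) series: [rr_series()] or numeric ms.
#' @param b comparison series.
#' @return Non-negative scalar.
#' @export
rrmse <- function(a, b) {
  a <- as_rr_or_numeric(a); b <- as_rr_or_numeric(b)
  if (!length(a) || !length(b)) stop("both series must be non-empty")
  n <- length(a)
  sa <- sort(a)
  qb <- if (n == 1L) stats::median(b)
        else as.numeric(quantile(b, probs = (seq_len(n) - 1) / (n - 1),
                                 type = 7, names = FALSE))
  sqrt(mean((sa - qb)^2)) / mean(a)
}

#' Waveform root-mean-square error
#'
#' `sqrt(sum((s_g - s_r)^2) / n)` between two equal-length signals.
#'
#' @param sig_g,sig_r numeric signals of equal length.
#' @return Non-negative scalar.
#' @export
rmse <- function(sig_g, sig_r) {
  sig_g <- as.numeric(sig_g); sig_r <- as.numeric(sig_r)
  if (length(sig_g) != length(sig_r)) stop("signals must have equal length")
  if (!length(sig_g)) stop("signals must be non-empty")
  sqrt(mean((sig_g - sig_r)^2))
}

#' Mean absolute heart-rate error
#'
#' Converts both RR series to beat-wise heart rates (60 / RR in seconds),
#' truncates to the shorter count, and averages the absolute differences.
#'
#' @param rr_g,rr_r ground-truth and reconstructed RR series
#'   ([rr_series()] or numeric ms).
#' @return Non-negative scalar in BPM.
#' @export
mae_hr <- function(rr_g, rr_r) {
  g <- as_rr_or_numeric(rr_g); r <- as_rr_or_numeric(rr_r)
  if (!length(g) || !length(r)) stop("both series must be non-empty")
  n <- min(length(g), length(r))
  mean(abs(60 / (g[1:n] / 1000) - 60 / (r[1:n] / 1000)))
}

#' Feature cloud: Gaussian summary of per-segment features
#'
#' @param features n x d matrix of per-segment feature vectors; omit when
#'   giving `mu`/`sigma` directly.
#' @param mu,sigma Gaussian summary (mean vector, covariance matrix) when
#'   the features themselves are not supplied.
#' @param extractor label recording how the features were produced.
#' @return An object of class `feature_cloud` with `features` (possibly
#'   NULL), `mu`, `sigma`, `extractor`.
#' @export
feature_cloud <- function(features = NULL, mu = NULL, sigma = NULL,
                          extractor = "raw") {
  if (is.null(mu)) {
    features <- as.matrix(features)
    if (nrow(features) < 2L)
      stop("need at least 2 feature vectors to estimate a covariance")
    mu <- colMeans(features)
    sigma <- stats::cov(features)
  } else {
    mu <- as.numeric(mu)
    sigma <- as.matrix(sigma)
  }
  structure(list(features = features, mu = mu, sigma = sigma,
                 extractor = extractor),
            class = "feature_cloud")
}

#' Frechet distance between two feature distributions
#'
#' `FD = ||mu_r - mu_g||^2 + Tr(Sigma_r + Sigma_g - 2 (Sigma_r Sigma_g)^(1/2))`,
#' comparing Gaussian fits of real and generated feature clouds. The matrix
#' square root is taken through symmetric eigendecompositions with negative
#' eigenvalues clipped at zero.
#'
#' @param real,gen [feature_cloud()]s (or n x d feature matrices) of equal
#'   feature dimension.
#' @return Non-negative scalar.
#' @export
frechet_distance <- function(real, gen) {
  if (!inherits(real, "feature_cloud")) real <- feature_cloud(real)
  if (!inherits(gen, "feature_cloud")) gen <- feature_cloud(gen)
  if (length(real$mu) != length(gen$mu))
    stop("feature dimensions differ: ", length(real$mu), " vs ",
         length(gen$mu))
  s1 <- .sqrtm_sym(real$sigma)
  inner <- s1 %*% gen$sigma %*% s1
  tr_sqrt <- sum(sqrt(pmax(eigen((inner + t(inner)) / 2,
                                 symmetric = TRUE,
                                 only.values = TRUE)$values, 0)))
  fd <- sum((real$mu - gen$mu)^2) +
    sum(diag(real$sigma)) + sum(diag(gen$sigma)) - 2 * tr_sqrt
  max(fd, 0)
}

# symmetric PSD square root, negative eigenvalues clipped at zero
.sqrtm_sym <- function(m) {
  m <- as.matrix(m)
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Default per-segment feature extractor
#'
#' Deterministic features for Frechet-distance evaluation: per segment,
#' the flattened log-magnitude STFT (default) or the raw samples.
#'
#' @param segments a [segment_signal()] result or a matrix with one
#'   segment per row.
#' @param type `"stft"` (default) or `"raw"`.
#' @param window_len,hop STFT parameters (see [stft_spectrogram()]).
#' @return A [feature_cloud()] with the extractor identity recorded.
#' @export
extract_features <- function(segments, type = c("stft", "raw"),
                             window_len = 128, hop = 32) {
  type <- match.arg(type)
  seg <- if (inherits(segments, "segment_set")) segments$segments
         else as.matrix(segments)
  if (nrow(seg) < 2L) stop("need at least 2 segments")
  feats <- if (type == "raw") seg
  else t(apply(seg, 1, function(r)
    as.numeric(log(stft_spectrogram(r, window_len, hop) + 1e-8))))
  feature_cloud(feats, extractor = if (type == "stft")
    sprintf("log-magnitude STFT (win %d, hop %d)", window_len, hop)
    else "raw segment")
}

#' Assemble a metric report
#'
#' Bundles the RR-distribution metrics (rHI, rRMSE, rEMD, KL, KS), waveform
#' RMSE, heart-rate MAE, HRV summary and Frechet distance for one
#' ground-truth/reconstruction comparison.
#'
#' @param rr_truth,rr_pred RR series of the two signals.
#' @param sig_truth,sig_pred equal-length waveform vectors (optional).
#' @param fd Frechet distance (optional, precomputed).
#' @param extractor feature-extractor label for `fd`.
#' @return An object of class `metric_report` (a named list).
#' @export
metric_report <- function(rr_truth, rr_pred, sig_truth = NULL,
                          sig_pred = NULL, fd = NA_real_,
                          extractor = NA_character_) {
  hrv_t <- hrv_summary(rr_truth)
  hrv_p <- hrv_summary(rr_pred)
  structure(list(
    rhi = rhi(rr_truth, rr_pred),
    rrmse = rrmse(rr_truth, rr_pred),
    remd = remd(rr_truth, rr_pred),
    kl = kl_divergence(rr_truth, rr_pred),
    ks = ks_statistic(rr_truth, rr_pred),
    rmse = if (is.null(sig_truth)) NA_real_ else rmse(sig_truth, sig_pred),
    mae_hr = mae_hr(rr_truth, rr_pred),
    hrv_mean = unname(hrv_t["mean"]), hrv_sd = unname(hrv_t["sd"]),
    hrv_mean_pred = unname(hrv_p["mean"]), hrv_sd_pred = unname(hrv_p["sd"]),
    fd = fd, extractor = extractor),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  cat(sprintf("  RR distribution: rHI %.3f | rRMSE %.4f | rEMD %.3g | KL %.3f | KS %.3f\n",
              x$rhi, x$rrmse, x$remd, x$kl, x$ks))
  cat(sprintf("  Waveform: RMSE %s | MAE_HR %.2f BPM | FD %s\n",
              if (is.na(x$rmse)) "-" else sprintf("%.4f", x$rmse),
              x$mae_hr,
              if (is.na(x$fd)) "-" else sprintf("%.3f", x$fd)))
  cat(sprintf("  HRV (truth/pred): mean %.1f/%.1f ms, sd %.2f/%.2f ms\n",
              x$hrv_mean, x$hrv_mean_pred, x$hrv_sd, x$hrv_sd_pred))
  invisible(x)
}
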