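#' Write a signal pair to CSV
#'
#' Columns `t_sec`, `ecg`, `ppg` with a header row; values written at full
#' double precision (15 significant digits), so a read-back round-trips to
#' well below 1e-9.
#'
#' @param pair a [simulate_pair()] result or a list with `ecg`, `ppg`, `fs`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal_pair <- function(pair, path) {
  if (is.null(pair$ecg) || is.null(pair$ppg) || is.null(pair$fs))
    stop("`pair` must carry `ecg`, `ppg` and `fs`")
  n <- length(pair$ecg)
  df <- data.frame(t_sec = (seq_len(n) - 1) / pair$fs,
                   ecg = pair$ecg, ppg = pair$ppg)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("t_sec,ecg,ppg", con)
  writeLines(sprintf("%.15g,%.15g,%.15g", df$t_sec, df$ecg, df$ppg), con)
  invisible(path)
}

#' Load a paired ECG/PPG record
#'
#' Supported formats: `"csv"` (header row with columns `t_sec`, `ecg`,
#' `ppg`; the sampling rate is inferred from `t_sec` unless given) and
#' `"rds"` (a saved record list). `"auto"` picks by file extension.
#'
#' @param path file path.
#' @param format `"auto"`, `"csv"` or `"rds"`.
#' @param fs sampling rate override in Hz.
#' @param id record identifier (defaults to the file name).
#' @return An object of class `record_bundle`: list with `id`, `ecg`,
#'   `ppg`, `fs`, `meta` (subject metadata, possibly empty) and
#'   `provenance`.
#' @export
load_record <- function(path, format = c("auto", "csv", "rds"),
                        fs = NULL, id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", rds = "rds",
                     stop("unsupported record format '", ext,
                          "'; supported: csv, rds"))
  }
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  if (format == "rds") {
    rec <- readRDS(path)
    if (is.null(rec$ecg) || is.null(rec$ppg))
      stop("RDS record must contain `ecg` and `ppg`")
    return(record_bundle(id, rec$ecg, rec$ppg,
                         fs %||% rec$fs, rec$meta %||% list(), "rds"))
  }
  df <- read.csv(path)
  need <- c("ecg", "ppg")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("channel(s) ", paste(missing_cols, collapse = ", "),
         " not found; available columns: ", paste(names(df), collapse = ", "))
  if (is.null(fs)) {
    if (!"t_sec" %in% names(df) || nrow(df) < 2L)
      stop("cannot infer `fs`: no t_sec column; pass `fs` explicitly")
    # sampling rates are physically round; strip float fuzz from the
    # reciprocal of the median time step (125 Hz, not 124.9999999999)
    fs <- round(1 / stats::median(diff(df$t_sec)), 3)
  }
  record_bundle(id, df$ecg, df$ppg, fs, list(), "csv")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a record bundle
#'
#' @param id record identifier.
#' @param ecg,ppg numeric channels (equal length).
#' @param fs sampling rate in Hz (> 0).
#' @param meta optional subject metadata list (e.g. `sex`, `age`).
#' @param provenance one of `"synthetic"`, `"csv"`, `"rds"`.
#' @return An object of class `record_bundle`.
#' @export
record_bundle <- function(id, ecg, ppg, fs, meta = list(),
                          provenance = "synthetic") {
  if (length(ecg) != length(ppg))
    stop("`ecg` and `ppg` must have equal length")
  if (is.null(fs) || !is.finite(fs) || fs <= 0) stop("`fs` must be > 0")
  structure(list(id = as.character(id), ecg = as.numeric(ecg),
                 ppg = as.numeric(ppg), fs = fs, meta = meta,
                 provenance = provenance),
            class = "record_bundle")
}

#' @export
print.record_bundle <- function(x, ...) {
  cat(sprintf("<record_bundle> %s (%s): %d samples at %g Hz\n",
              x$id, x$provenance, length(x$ecg), x$fs))
  invisible(x)
}

#' Generate a demo dataset of synthetic pairs
#'
#' Writes `n_per_rhythm` CSV signal pairs for each of the three rhythms.
#' Each pair draws a target RR mean and RR standard deviation uniformly
#' from the given ranges, builds a Gaussian RR schedule, and simulates with
#' 10% parameter noise (one perturbation per pair). A JSON manifest records
#' ids, rhythms, per-pair seeds and the requested RR statistics; the
#' manifest seeds fully reconstruct the dataset.
#'
#' @param n_per_rhythm pairs per rhythm (>= 1).
#' @param out_dir output directory (created if needed).
#' @param rr_mean_range RR mean range in ms (default 600–900, i.e. heart
#'   rates of roughly 67–100 BPM).
#' @param rr_std_range RR standard-deviation range in ms (default 3–12,
#'   the scale of short-term variability in resting recordings).
#' @param duration_s record duration in seconds (default 60).
#' @param fs sampling rate in Hz (default 125).
#' @param noise_frac parameter-noise fraction (default 0.1).
#' @param seed master seed; per-pair seeds are derived deterministically.
#' @return The manifest (a data frame), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
make_demo_dataset <- function(n_per_rhythm, out_dir,
                              rr_mean_range = c(600, 900),
                              rr_std_range = c(3, 12),
                              duration_s = 60, fs = 125,
                              noise_frac = 0.1, seed = 1) {
  if (n_per_rhythm < 1) stop("`n_per_rhythm` must be >= 1")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  set.seed(as.integer(seed))
  rhythms <- rep(c("rsr", "sa", "afib"), each = n_per_rhythm)
  n <- length(rhythms)
  mean_ms <- runif(n, rr_mean_range[1], rr_mean_range[2])
  sd_ms <- runif(n, rr_std_range[1], rr_std_range[2])
  pair_seed <- sample.int(.Machine$integer.max %/% 2L, n)
  ids <- sprintf("%s_%02d", rhythms, rep(seq_len(n_per_rhythm), 3))
  for (i in seq_len(n)) {
    set.seed(pair_seed[i])
    sched <- rr_schedule_gaussian(duration_s, mean_ms[i], sd_ms[i], fs)
    pair <- simulate_pair(rhythm_preset(rhythms[i]), sched, fs,
                          seed = pair_seed[i], noise_frac = noise_frac)
    # drop the simulator's settling transient so the stored record starts
    # in steady state, like a real recording
    drop <- seq_len(round(2 * fs))
    pair$ecg <- pair$ecg[-drop]
    pair$ppg <- pair$ppg[-drop]
    write_signal_pair(pair, file.path(out_dir, paste0(ids[i], ".csv")))
  }
  manifest <- data.frame(id = ids, rhythm = rhythms, seed = pair_seed,
                         rr_mean_ms = mean_ms, rr_sd_ms = sd_ms,
                         duration_s = duration_s, fs = fs,
                         noise_frac = noise_frac)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
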