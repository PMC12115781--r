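# Sliding-window feature engineering.
#
# Each 40-sample (10 s at 4 Hz) window with 50% overlap yields 19 features:
#   EDA  min/max/mean/std, sample skewness, excess kurtosis, and the
#        skin-conductance-response peak triple (count, total prominence,
#        total width-at-half-prominence in seconds)      -> 9
#   HR   min/max/mean/std, RMS of first differences      -> 5
#   TEMP min/max/mean/std, RMS of first differences      -> 5
# Lagged means of EDA/HR/TEMP from the previous 1..max_lag windows are then
# appended (30 columns at the default lag depth of 10).
#
# Std uses the population denominator n; skewness is the Fisher-Pearson
# moment coefficient and kurtosis is excess kurtosis, both defined as 0 for
# zero-variance windows.

#' Feature-extraction configuration
#'
#' @param window_size Window length in samples (default 40 = 10 s at 4 Hz).
#' @param step Step between window starts in samples (default 20, 50% overlap).
#' @param max_lag Number of previous windows whose channel means are appended
#'   as lag features (default 10).
#' @param peak_prominence Minimum topographic prominence (in microsiemens) for
#'   a local EDA maximum to count as a skin-conductance response (default 0.01).
#' @param peak_width_fraction Fraction of the prominence below the peak at
#'   which peak width is measured (default 0.5, i.e. width at half prominence).
#' @return A `feature_config` object.
#' @export
feature_config <- function(window_size = 40L, step = 20L, max_lag = 10L,
                           peak_prominence = 0.01, peak_width_fraction = 0.5) {
  window_size <- as.integer(window_size)
  step <- as.integer(step)
  max_lag <- as.integer(max_lag)
  if (step <= 0L || step > window_size)
    sw_abort("need 0 < step <= window_size", "sw_validation_error")
  if (max_lag < 0L) sw_abort("max_lag must be >= 0", "sw_validation_error")
  if (!is_scalar_number(peak_prominence) || peak_prominence <= 0)
    sw_abort("peak_prominence must be > 0", "sw_validation_error")
  if (!is_scalar_number(peak_width_fraction) ||
      peak_width_fraction <= 0 || peak_width_fraction > 1)
    sw_abort("peak_width_fraction must be in (0, 1]", "sw_validation_error")
  structure(list(window_size = window_size, step = step, max_lag = max_lag,
                 peak_prominence = peak_prominence,
                 peak_width_fraction = peak_width_fraction),
            class = "feature_config")
}

#' Sliding-window index ranges
#'
#' Window k (k = 0, 1, ...) covers samples `k*step + 1 .. k*step + window_size`
#' (1-based); the number of windows is `floor((N - window_size)/step) + 1`.
#'
#' @param signals An `aligned_signals` object, or a single integer giving the
#'   signal length in samples.
#' @param cfg A [feature_config()].
#' @return Data frame with columns `start` and `end` (1-based, inclusive).
#' @export
make_windows <- function(signals, cfg = feature_config()) {
  n <- if (inherits(signals, "aligned_signals")) length(signals$eda)
       else as.integer(signals)
  if (n < cfg$window_size)
    sw_abort(sprintf("signal length %d is shorter than one window (%d samples)",
                     n, cfg$window_size), "sw_insufficient_data_error")
  k <- 0:((n - cfg$window_size) %/% cfg$step)
  data.frame(start = k * cfg$step + 1L, end = k * cfg$step + cfg$window_size)
}

#' Root mean square of first differences
#'
#' A short-term variability measure: `sqrt(mean(diff(x)^2))`.
#'
#' @param x Numeric vector of length at least 2.
#' @return Non-negative scalar.
#' @export
rms_first_diff <- function(x) {
  if (length(x) < 2L)
    sw_abort("rms_first_diff needs at least 2 samples", "sw_insufficient_data_error")
  sqrt(mean(diff(x)^2))
}

# Strict local maxima of x with topographic prominence and width at
# (height - width_frac * prominence). Returns a data frame with one row per
# retained peak: index, prominence, width (in samples, interpolated).
find_scr_peaks <- function(x, min_prominence, width_frac = 0.5) {
  n <- length(x)
  out <- data.frame(index = integer(0), prominence = numeric(0), width = numeric(0))
  if (n < 3L) return(out)
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
  for (p in cand) {
    # left base: minimum between the peak and the previous higher sample
    lmin <- x[p]
    j <- p - 1L
    while (j >= 1L && x[j] <= x[p]) { if (x[j] < lmin) lmin <- x[j]; j <- j - 1L }
    rmin <- x[p]
    j <- p + 1L
    while (j <= n && x[j] <= x[p]) { if (x[j] < rmin) rmin <- x[j]; j <- j + 1L }
    prom <- x[p] - max(lmin, rmin)
    if (prom < min_prominence) next
    h <- x[p] - width_frac * prom
    # walk outwards to the interpolated crossings of height h
    j <- p
    while (j > 1L && x[j - 1L] > h) j <- j - 1L
    left_ip <- if (j == 1L) 1 else (j - 1L) + (h - x[j - 1L]) / (x[j] - x[j - 1L])
    j <- p
    while (j < n && x[j + 1L] > h) j <- j + 1L
    right_ip <- if (j == n) n else j + (x[j] - h) / (x[j] - x[j + 1L])
    out <- rbind(out, data.frame(index = p, prominence = prom,
                                 width = right_ip - left_ip))
  }
  out
}

#' EDA peak (skin-conductance response) features for one window
#'
#' Peaks are strict local maxima whose topographic prominence reaches
#' `cfg$peak_prominence`. The window's phasic activity is summarized by the
#' peak count, the total prominence ("amplitude", microsiemens), and the
#' total peak width measured `peak_width_fraction * prominence` below each
#' peak, converted to seconds.
#'
#' @param eda Numeric EDA vector (one window).
#' @param cfg A [feature_config()].
#' @param rate Sampling rate in Hz used to convert widths to seconds.
#' @return Named vector `c(peaks, amplitude, duration)`.
#' @export
eda_peak_features <- function(eda, cfg = feature_config(), rate = 4) {
  pk <- find_scr_peaks(eda, cfg$peak_prominence, cfg$peak_width_fraction)
  c(peaks = nrow(pk), amplitude = sum(pk$prominence), duration = sum(pk$width) / rate)
}

# Moment-based shape statistics with the zero-variance convention.
window_skewness <- function(x) {
  s <- e1071::skewness(x, type = 1)
  if (!is.finite(s)) 0 else s
}
window_kurtosis <- function(x) {
  k <- e1071::kurtosis(x, type = 1)
  if (!is.finite(k)) 0 else k
}

pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Extract the 19 current-window features for every window
#'
#' @param signals An `aligned_signals` object.
#' @param cfg A [feature_config()].
#' @return Feature table: data frame with `window_start_time`, `subject_id`
#'   and the 19 canonical feature columns, one row per window, ordered by
#'   window start.
#' @export
extract_window_features <- function(signals, cfg = feature_config()) {
  stopifnot(inherits(signals, "aligned_signals"))
  win <- make_windows(signals, cfg)
  nw <- nrow(win)
  ws <- cfg$window_size
  idx <- outer(0:(ws - 1L), win$start, `+`)   # ws x nw index matrix

  stats_block <- function(x, prefix, rms = FALSE) {
    M <- matrix(x[idx], nrow = ws)
    m <- colMeans(M)
    out <- list(
      Min = apply(M, 2L, min), Max = apply(M, 2L, max), Mean = m,
      Std = sqrt(colMeans(M^2) - m^2)
    )
    out$Std[!is.finite(out$Std)] <- 0   # guard tiny negative round-off
    if (rms) out$RMS <- sqrt(colMeans(diff(M)^2))
    names(out) <- paste0(prefix, "_", names(out))
    out
  }

  eda_b <- stats_block(signals$eda, "EDA")
  hr_b <- stats_block(signals$hr, "HR", rms = TRUE)
  temp_b <- stats_block(signals$temp, "TEMP", rms = TRUE)

  E <- matrix(signals$eda[idx], nrow = ws)
  eda_shape <- vapply(seq_len(nw), function(k) {
    x <- E[, k]
    pk <- eda_peak_features(x, cfg, rate = signals$grid_rate)
    c(Skew = window_skewness(x), Kurtosis = window_kurtosis(x), pk)
  }, numeric(5))

  out <- data.frame(
    window_start_time = signals$grid_start + (win$start - 1L) / signals$grid_rate,
    subject_id = signals$subject_id,
    EDA_Min = eda_b$EDA_Min, EDA_Max = eda_b$EDA_Max, EDA_Mean = eda_b$EDA_Mean,
    EDA_Std = eda_b$EDA_Std,
    EDA_Skew = eda_shape["Skew", ], EDA_Kurtosis = eda_shape["Kurtosis", ],
    EDA_Peaks = eda_shape["peaks", ], EDA_Amplitude = eda_shape["amplitude", ],
    EDA_Duration = eda_shape["duration", ],
    HR_Min = hr_b$HR_Min, HR_Max = hr_b$HR_Max, HR_Mean = hr_b$HR_Mean,
    HR_Std = hr_b$HR_Std, HR_RMS = hr_b$HR_RMS,
    TEMP_Min = temp_b$TEMP_Min, TEMP_Max = temp_b$TEMP_Max,
    TEMP_Mean = temp_b$TEMP_Mean, TEMP_Std = temp_b$TEMP_Std,
    TEMP_RMS = temp_b$TEMP_RMS,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Append lagged channel-mean features
#'
#' For each lag k in `1..max_lag` and channel mean s in
#' `{EDA_Mean, HR_Mean, TEMP_Mean}`, column `s_lag{k}` holds the value of
#' that mean k windows earlier within the same subject. The first `max_lag`
#' windows of each subject have incomplete history and are dropped; a
#' subject with fewer than `max_lag + 1` windows contributes no rows (with
#' a warning).
#'
#' @param table Feature table ordered by window start within each subject.
#' @param cfg A [feature_config()].
#' @return Feature table with `3 * max_lag` extra columns and `max_lag`
#'   fewer rows per subject.
#' @export
add_lags <- function(table, cfg = feature_config()) {
  if (cfg$max_lag == 0L) return(table)
  base_cols <- c("EDA_Mean", "HR_Mean", "TEMP_Mean")
  if (!all(base_cols %in% names(table)))
    sw_abort("table lacks the channel mean columns needed for lags", "sw_schema_error")
  subj <- if ("subject_id" %in% names(table)) table$subject_id
          else rep("all", nrow(table))
  pieces <- lapply(split(seq_len(nrow(table)), subj), function(ridx) {
    ridx <- ridx[order(table$window_start_time[ridx] %||% ridx)]
    nr <- length(ridx)
    if (nr <= cfg$max_lag) {
      warning(sprintf("subject %s has %d window(s); %d needed for lag features -- dropped",
                      subj[ridx[1L]], nr, cfg$max_lag + 1L))
      return(NULL)
    }
    block <- table[ridx, , drop = FALSE]
    for (s in c("EDA", "HR", "TEMP")) {
      v <- block[[paste0(s, "_Mean")]]
      for (k in seq_len(cfg$max_lag)) {
        block[[sprintf("%s_Mean_lag%d", s, k)]] <-
          c(rep(NA_real_, k), v[seq_len(nr - k)])
      }
    }
    block[-seq_len(cfg$max_lag), , drop = FALSE]
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    sw_abort("no subject has enough windows for the requested lag depth",
             "sw_insufficient_data_error")
  rownames(out) <- NULL
  out
}

#' Min-max scaling fit on a training table
#'
#' Per feature column, `x' = (x - min_train) / (max_train - min_train)`.
#' Zero-range columns map to 0 everywhere. Tables scaled with training
#' parameters may exceed `[0, 1]`. Fit scalers on training folds only: the
#' transform leaks fold information if fit on pooled data.
#'
#' @param train Training feature table (non-empty).
#' @param others Optional list of further tables to scale with the training
#'   parameters.
#' @return List with `train`, `others`, and `params` (per-column min/range).
#' @export
minmax_scale <- function(train, others = list()) {
  params <- minmax_fit(train)
  list(train = minmax_apply(train, params),
       others = lapply(others, minmax_apply, params = params),
       params = params)
}

minmax_fit <- function(table) {
  cols <- feature_columns(table)
  if (nrow(table) == 0L) sw_abort("cannot fit a scaler on an empty table", "sw_validation_error")
  mins <- vapply(table[cols], min, numeric(1))
  maxs <- vapply(table[cols], max, numeric(1))
  list(columns = cols, min = mins, range = maxs - mins)
}

minmax_apply <- function(table, params) {
  for (j in seq_along(params$columns)) {
    cn <- params$columns[j]
    if (!cn %in% names(table)) sw_abort(sprintf("column %s absent", cn), "sw_schema_error")
    table[[cn]] <- if (params$range[j] == 0) rep(0, nrow(table))
                   else (table[[cn]] - params$min[j]) / params$range[j]
  }
  table
}
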