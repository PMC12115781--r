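# Independent brute-force reference implementations used to cross-check the
# feature-engineering path. Deliberately naive: explicit loops, no shared
# code with the package.

oracle_windows <- function(n, size, step) {
  starts <- integer(0)
  s <- 1L
  while (s + size - 1L <= n) {
    starts <- c(starts, s)
    s <- s + step
  }
  starts
}

oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  list(mean = mu, sd = sqrt(m2),
       skew = if (m2 > 0) m3 / m2^1.5 else 0,
       kurt = if (m2 > 0) m4 / m2^2 - 3 else 0)
}

oracle_rms_diff <- function(x) {
  acc <- 0
  for (i in 2:length(x)) acc <- acc + (x[i] - x[i - 1])^2
  sqrt(acc / (length(x) - 1))
}

# Naive peak analysis: strict local maxima, prominence by explicit scans,
# width by stepping outwards sample-by-sample with linear interpolation.
oracle_peaks <- function(x, min_prom, width_frac, rate) {
  n <- length(x)
  count <- 0; amp <- 0; dur <- 0
  for (p in seq_len(n)) {
    if (p == 1L || p == n) next
    if (!(x[p] > x[p - 1] && x[p] > x[p + 1])) next
    lmin <- x[p]
    for (j in (p - 1):1) {
      if (x[j] > x[p]) break
      if (x[j] < lmin) lmin <- x[j]
    }
    rmin <- x[p]
    for (j in (p + 1):n) {
      if (x[j] > x[p]) break
      if (x[j] < rmin) rmin <- x[j]
    }
    prom <- x[p] - max(lmin, rmin)
    if (prom < min_prom) next
    h <- x[p] - width_frac * prom
    li <- p
    while (li > 1 && x[li - 1] > h) li <- li - 1
    left <- if (li == 1) 1 else (li - 1) + (h - x[li - 1]) / (x[li] - x[li - 1])
    ri <- p
    while (ri < n && x[ri + 1] > h) ri <- ri + 1
    right <- if (ri == n) n else ri + (x[ri] - h) / (x[ri] - x[ri + 1])
    count <- count + 1
    amp <- amp + prom
    dur <- dur + (right - left) / rate
  }
  c(count, amp, dur)
}

# Full 19-feature table for an aligned-signals object, by naive loops.
oracle_features <- function(sig, cfg) {
  starts <- oracle_windows(length(sig$eda), cfg$window_size, cfg$step)
  rows <- lapply(starts, function(s) {
    idx <- s:(s + cfg$window_size - 1L)
    e <- sig$eda[idx]; h <- sig$hr[idx]; tp <- sig$temp[idx]
    em <- oracle_moments(e); hm <- oracle_moments(h); tm <- oracle_moments(tp)
    pk <- oracle_peaks(e, cfg$peak_prominence, cfg$peak_width_fraction,
                       sig$grid_rate)
    data.frame(
      window_start_time = sig$grid_start + (s - 1) / sig$grid_rate,
      EDA_Min = min(e), EDA_Max = max(e), EDA_Mean = em$mean, EDA_Std = em$sd,
      EDA_Skew = em$skew, EDA_Kurtosis = em$kurt,
      EDA_Peaks = pk[1], EDA_Amplitude = pk[2], EDA_Duration = pk[3],
      HR_Min = min(h), HR_Max = max(h), HR_Mean = hm$mean, HR_Std = hm$sd,
      HR_RMS = oracle_rms_diff(h),
      TEMP_Min = min(tp), TEMP_Max = max(tp), TEMP_Mean = tm$mean,
      TEMP_Std = tm$sd, TEMP_RMS = oracle_rms_diff(tp)
    )
  })
  do.call(rbind, rows)
}

# Lag stacking by explicit row shifting on a single-subject table.
oracle_lags <- function(tab, max_lag) {
  n <- nrow(tab)
  if (n <= max_lag) return(NULL)
  out <- tab
  for (s in c("EDA", "HR", "TEMP")) {
    for (k in seq_len(max_lag)) {
      col <- rep(NA_real_, n)
      for (i in (k + 1):n) col[i] <- tab[[paste0(s, "_Mean")]][i - k]
      out[[sprintf("%s_Mean_lag%d", s, k)]] <- col
    }
  }
  out[(max_lag + 1):n, , drop = FALSE]
}

# Random aligned-signals object for property tests.
random_signals <- function(n, subject = "T") {
  structure(list(subject_id = subject, grid_start = 0, grid_rate = 4,
                 eda = cumsum(rnorm(n, 0, 0.05)) + 1.5,
                 hr = 80 + cumsum(rnorm(n, 0, 0.5)),
                 temp = 31.5 + cumsum(rnorm(n, 0, 0.01))),
            class = "aligned_signals")
}
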