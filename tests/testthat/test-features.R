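# Windowing, window statistics, SCR peak analysis, lags, scaling.

test_that("window count follows the closed form and matches enumeration", {
  cfg <- feature_config()
  expect_equal(nrow(make_windows(40L, cfg)), 1L)
  w <- make_windows(100L, cfg)
  expect_equal(w$start, c(1L, 21L, 41L, 61L))
  expect_error(make_windows(39L, cfg), class = "sw_insufficient_data_error")
  withr::with_seed(2, {
    for (i in 1:50) {
      size <- sample(2:60, 1)
      step <- sample(seq_len(size), 1)
      n <- sample(size:400, 1)
      cfg2 <- feature_config(window_size = size, step = step, max_lag = 0)
      w <- make_windows(n, cfg2)
      expect_equal(nrow(w), floor((n - size) / step) + 1)          # closed form
      expect_equal(w$start, oracle_windows(n, size, step))         # brute force
      expect_true(all(w$end - w$start + 1L == size))
    }
  })
})

test_that("RMS of first differences matches hand values", {
  expect_equal(rms_first_diff(rep(3.2, 10)), 0)
  expect_equal(rms_first_diff(c(0, 1, 0, 1)), 1)
  expect_equal(rms_first_diff(c(0, 2, 3)), sqrt((4 + 1) / 2))
  expect_error(rms_first_diff(1), class = "sw_insufficient_data_error")
})

test_that("peak analysis recovers the constructed triangle exactly", {
  cfg <- feature_config()
  # monotone window: no local maxima
  expect_equal(unname(eda_peak_features(seq(0, 1, length.out = 40), cfg)),
               c(0, 0, 0))
  # triangle of height 1 over baseline 0, width 8 samples at half height
  tri <- c(rep(0, 5), (0:8) / 8, (7:0) / 8, rep(0, 5))
  pk <- eda_peak_features(tri, cfg)
  expect_equal(unname(pk), c(1, 1, 2))   # 8 samples / 4 Hz = 2 s
  # two identical, well-separated bumps double every total
  two <- c(tri, rep(0, 4), tri)
  pk2 <- eda_peak_features(two, cfg)
  expect_equal(unname(pk2), 2 * unname(pk))
  # bumps below the prominence threshold are ignored
  expect_equal(unname(eda_peak_features(tri * 0.005, cfg))[1], 0)
})

test_that("window features match expectations on constructed windows", {
  cfg <- feature_config()
  mk_sig <- function(eda, hr, temp) {
    structure(list(subject_id = "s", grid_start = 0, grid_rate = 4,
                   eda = eda, hr = hr, temp = temp),
              class = "aligned_signals")
  }
  # constant channels: dispersion, shape and peak features all zero
  sig <- mk_sig(rep(1.2, 40), rep(75, 40), rep(31.5, 40))
  ft <- extract_window_features(sig, cfg)
  expect_equal(nrow(ft), 1L)
  expect_equal(length(feature_columns(ft)), 19L)
  for (cn in c("EDA_Std", "EDA_Skew", "EDA_Kurtosis", "EDA_Peaks",
               "EDA_Amplitude", "EDA_Duration", "HR_Std", "HR_RMS",
               "TEMP_Std", "TEMP_RMS"))
    expect_equal(ft[[cn]], 0)
  expect_equal(ft$EDA_Min, 1.2); expect_equal(ft$EDA_Max, 1.2)
  expect_equal(ft$HR_Mean, 75); expect_equal(ft$TEMP_Mean, 31.5)
  # arithmetic ramp on EDA
  sig2 <- mk_sig((0:39) / 39, rep(70, 40), rep(31, 40))
  ft2 <- extract_window_features(sig2, cfg)
  expect_equal(ft2$EDA_Min, 0); expect_equal(ft2$EDA_Max, 1)
  expect_equal(ft2$EDA_Mean, 0.5)
  # symmetric triangle has (near) zero skewness
  sig3 <- mk_sig(c(0:19, 19:0) / 19, rep(70, 40), rep(31, 40))
  ft3 <- extract_window_features(sig3, cfg)
  expect_lt(abs(ft3$EDA_Skew), 1e-12)
})

test_that("feature extraction agrees with the brute-force oracle", {
  cfg <- feature_config(max_lag = 0)
  withr::with_seed(9, {
    for (i in 1:30) {
      n <- sample(40:200, 1)
      sig <- random_signals(n)
      got <- extract_window_features(sig, cfg)
      ref <- oracle_features(sig, cfg)
      for (cn in names(ref))
        expect_equal(got[[cn]], ref[[cn]], tolerance = 1e-9, label = cn)
    }
  })
})

test_that("lag columns shift per subject and drop incomplete history", {
  tab <- data.frame(window_start_time = 0:2 * 5, subject_id = "a",
                    EDA_Mean = c(1, 2, 3), HR_Mean = c(4, 5, 6),
                    TEMP_Mean = c(7, 8, 9))
  cfg1 <- feature_config(max_lag = 1)
  out <- add_lags(tab, cfg1)
  expect_equal(nrow(out), 2L)
  expect_equal(out$EDA_Mean_lag1, c(1, 2))
  expect_equal(out$TEMP_Mean_lag1, c(7, 8))
  # max_lag 0 leaves the table unchanged
  expect_identical(add_lags(tab, feature_config(max_lag = 0)), tab)
  # 11 windows at max_lag 10 leave exactly one row
  tab11 <- data.frame(window_start_time = 0:10 * 5, subject_id = "a",
                      EDA_Mean = 1:11, HR_Mean = 1:11, TEMP_Mean = 1:11)
  out11 <- add_lags(tab11, feature_config(max_lag = 10))
  expect_equal(nrow(out11), 1L)
  expect_equal(out11$EDA_Mean_lag10, 1)
  # a too-short subject contributes no rows, with a warning
  tab_two <- rbind(tab11, transform(tab11[1:3, ], subject_id = "b"))
  expect_warning(out_two <- add_lags(tab_two, feature_config(max_lag = 10)),
                 "subject b")
  expect_equal(unique(out_two$subject_id), "a")
})

test_that("lag stacking is shift-consistent and matches the oracle", {
  withr::with_seed(13, {
    for (i in 1:10) {
      nr <- sample(12:40, 1)
      tab <- data.frame(window_start_time = seq_len(nr) * 5, subject_id = "a",
                        EDA_Mean = rnorm(nr), HR_Mean = rnorm(nr),
                        TEMP_Mean = rnorm(nr))
      lag <- sample(1:10, 1)
      cfg <- feature_config(max_lag = lag)
      got <- add_lags(tab, cfg)
      ref <- oracle_lags(tab, lag)
      expect_equal(nrow(got), nr - lag)
      for (cn in setdiff(names(ref), "subject_id"))
        expect_equal(got[[cn]], ref[[cn]], tolerance = 1e-9)
      # shift consistency against the pre-drop table
      for (k in seq_len(lag))
        expect_equal(got[[paste0("HR_Mean_lag", k)]],
                     tab$HR_Mean[(lag + 1 - k):(nr - k)])
    }
  })
})

test_that("min-max scaling maps train to [0,1] and is affine-invariant", {
  tr <- data.frame(EDA_Mean = c(2, 4), HR_Mean = c(1, 1))
  oth <- data.frame(EDA_Mean = 3, HR_Mean = 5)
  sc <- minmax_scale(tr, list(oth))
  expect_equal(sc$train$EDA_Mean, c(0, 1))
  expect_equal(sc$train$HR_Mean, c(0, 0))      # zero-range convention
  expect_equal(sc$others[[1]]$EDA_Mean, 0.5)
  tr2 <- data.frame(EDA_Mean = c(0, 10))
  expect_equal(minmax_scale(tr2, list(data.frame(EDA_Mean = 5)))$others[[1]]$EDA_Mean,
               0.5)
  withr::with_seed(21, {
    x <- rnorm(30)
    a <- runif(1, 0.5, 3); b <- rnorm(1)
    s1 <- minmax_scale(data.frame(EDA_Mean = x))$train$EDA_Mean
    s2 <- minmax_scale(data.frame(EDA_Mean = a * x + b))$train$EDA_Mean
    expect_equal(s1, s2, tolerance = 1e-12)
  })
})
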