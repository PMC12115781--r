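# The synthetic cohort generator: determinism, calibration structure,
# missingness, stress-dependent effects.

test_that("stress profiles are deterministic, banded, and emergency-elevated", {
  p <- generator_params(n_subjects = 1L, session_duration = 600, seed = 3L)
  tr1 <- make_stress_profile(p, seed = 5)
  tr2 <- make_stress_profile(p, seed = 5)
  expect_identical(tr1$values, tr2$values)
  expect_true(all(tr1$values >= 0 & tr1$values <= 1))
  # zero jitter: the trace takes exactly the per-segment band centers
  p0 <- generator_params(n_subjects = 1L, session_duration = 600,
                         jitter_sd = 0, seed = 3L)
  tr0 <- make_stress_profile(p0, seed = 5)
  expect_true(all(tr0$values %in% (c(1, 3, 5) / 6)))
  # emergency segment (4 of 6) mean exceeds the global mean and theta1
  seg <- attr(tr0, "segment_boundaries")
  sel <- tr0$timestamps >= seg[4] & tr0$timestamps < seg[5]
  expect_equal(mean(tr0$values[sel]), 5 / 6)
  means <- vapply(1:20, function(i) {
    tr <- make_stress_profile(p, seed = i)
    sel <- tr$timestamps >= seg[4] & tr$timestamps < seg[5]
    c(mean(tr$values[sel]), mean(tr$values))
  }, numeric(2))
  expect_true(all(means[1, ] > 1 / 3))
  expect_true(all(means[1, ] >= means[2, ]))
})

test_that("channels honour their native rates and zero-noise calibration", {
  p <- generator_params(n_subjects = 1L, session_duration = 300,
                        hr_noise_sd = 0, temp_noise_sd = 0, temp_drift_sd = 0,
                        eda_noise_sd = 0, scr_rate = c(0, 0, 0) + 1e-9,
                        jitter_sd = 0, missing_rate = 0, seed = 2L)
  flat <- stress_trace(p$start_time + (0:(300 * 4 - 1)) / 4, rep(0, 300 * 4))
  hr <- synth_channel(flat, "HR", p, seed = 1)
  expect_equal(hr$rate, 1)
  expect_equal(length(hr$samples), 300L)
  expect_true(all(hr$samples == 82.23))   # level-0 target, no noise
  temp <- synth_channel(flat, "TEMP", p, seed = 1)
  expect_equal(temp$rate, 4)
  expect_true(all(abs(temp$samples - 31.81) < 1e-9))
  eda <- synth_channel(flat, "EDA", p, seed = 1)
  expect_equal(eda$rate, 4)
  # essentially zero SCR rate and no noise: no detectable peaks downstream
  pk <- eda_peak_features(eda$samples[1:40], feature_config())
  expect_equal(unname(pk[1]), 0)
  # determinism
  expect_identical(synth_channel(flat, "EDA", p, seed = 9)$samples,
                   synth_channel(flat, "EDA", p, seed = 9)$samples)
})

test_that("higher stress raises the empirical SCR count (same seed)", {
  p <- generator_params(n_subjects = 1L, session_duration = 600,
                        jitter_sd = 0, missing_rate = 0, seed = 2L)
  n <- 600 * 4
  ts <- p$start_time + (0:(n - 1)) / 4
  lo <- stress_trace(ts, rep(1 / 6, n))
  hi <- stress_trace(ts, rep(5 / 6, n))
  count_peaks <- function(tr, seed) {
    eda <- synth_channel(tr, "EDA", p, seed = seed)$samples
    sum(vapply(seq(1, n - 39, by = 40), function(s)
      eda_peak_features(eda[s:(s + 39)], feature_config())[1], numeric(1)))
  }
  counts <- vapply(1:5, function(s) c(count_peaks(lo, s), count_peaks(hi, s)),
                   numeric(2))
  expect_true(all(counts[2, ] > counts[1, ]))
})

test_that("missingness injection matches its nominal rate", {
  rec <- channel_recording("EDA", 0, 4, rep(1, 1e6))
  expect_identical(inject_missing(rec, 0, seed = 1)$samples, rec$samples)
  out <- inject_missing(rec, 0.0102, seed = 7)
  phat <- mean(is.na(out$samples))
  tol <- 3 * sqrt(0.0102 * (1 - 0.0102) / 1e6)
  expect_lt(abs(phat - 0.0102), tol)
  expect_identical(inject_missing(rec, 0.0102, seed = 7)$samples, out$samples)
})

test_that("cohorts are reproducible and monotone in stress effects", {
  p <- generator_params(n_subjects = 2L, session_duration = 600, seed = 13L)
  c1 <- generate_cohort(p)
  c2 <- generate_cohort(p)
  expect_identical(c1[[1]]$session$channels$EDA$samples,
                   c2[[1]]$session$channels$EDA$samples)
  expect_identical(c1[[2]]$trace$values, c2[[2]]$trace$values)
  expect_equal(length(c1), 2L)
  # paired-seed monotone effects: HR/EDA rise 0 -> 1, TEMP falls 0 -> 1 -> 2
  n <- 600 * 4
  ts <- p$start_time + (0:(n - 1)) / 4
  lv <- lapply(c(1, 3, 5) / 6, function(s) stress_trace(ts, rep(s, n)))
  for (seed in 1:3) {
    hr <- vapply(lv, function(tr) mean(synth_channel(tr, "HR", p, seed)$samples),
                 numeric(1))
    te <- vapply(lv, function(tr) mean(synth_channel(tr, "TEMP", p, seed)$samples),
                 numeric(1))
    ed <- vapply(lv, function(tr) mean(synth_channel(tr, "EDA", p, seed)$samples),
                 numeric(1))
    expect_gt(hr[2], hr[1])
    expect_true(all(diff(te) < 0))
    expect_gt(ed[2], ed[1]); expect_gt(ed[3], ed[1])
  }
})

test_that("pipeline labels on generated data recover the ground truth", {
  fx <- small_cohort_fixture()
  gt <- do.call(rbind, lapply(fx$cohort, function(el) {
    g <- el$ground_truth
    g$subject_id <- el$session$subject_id
    g
  }))
  key_ds <- paste(fx$dataset$subject_id, round(fx$dataset$window_start_time, 3))
  key_gt <- paste(gt$subject_id, round(gt$window_start_time, 3))
  m <- match(key_ds, key_gt)
  expect_false(anyNA(m))
  expect_gt(mean(fx$dataset$labels == gt$true_class[m]), 0.9)
})

test_that("cohorts round-trip through E4-style artifacts on disk", {
  p <- generator_params(n_subjects = 2L, session_duration = 300, seed = 19L)
  coh <- generate_cohort(p)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_setequal(list.files(file.path(dir, "S01")),
                  c("EDA.csv", "HR.csv", "TEMP.csv", "ground_truth.csv",
                    "meta.csv", "stress.csv"))
  back <- read_channel_csv(file.path(dir, "S02", "HR.csv"), "HR")
  expect_equal(back$samples, coh[[2]]$session$channels$HR$samples,
               tolerance = 1e-12)
  tr <- read_stress_trace(file.path(dir, "S01", "stress.csv"))
  expect_equal(tr$values, coh[[1]]$trace$values, tolerance = 1e-12)
})
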