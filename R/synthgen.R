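# Synthetic cohort generator.
#
# Emulates the statistical structure the analysis assumes: 12 subjects, two
# hours each, six scenario segments with one emergency segment forced to
# high stress; EDA/TEMP at 4 Hz and HR at 1 Hz; stress-dependent effects
# with heart rate up, skin temperature down, and EDA tonic level and phasic
# peak rate up with stress; about 1% of samples missing at random; and a
# matching continuous stress trace. Channel levels are calibrated to the
# observed per-level group means (HR 82.23/86.30/84.79 bpm, TEMP
# 31.81/31.49/31.23 degC, EDA 0.68/2.09/1.87 uS); note the calibration
# follows the observed values, including HR's level-2 mean sitting below
# level 1, rather than a monotone idealization. The signal models
# themselves (AR(1) heart-rate noise, bi-exponential skin-conductance-
# response kernel with Poisson arrivals, slow temperature drift) supply
# realistic short-term structure around those levels.

# Stress values at the centers of the three label bands.
LEVEL_CENTERS <- c(1, 3, 5) / 6

#' Generator parameters for synthetic cohorts
#'
#' @param n_subjects Number of subjects (default 12).
#' @param session_duration Session length in seconds (default 7200).
#' @param n_segments Scenario segments per session (default 6).
#' @param emergency_segment Segment forced to high stress (default 4).
#' @param start_time Session start, seconds since epoch.
#' @param hr_means,temp_means,eda_means Per-level target channel means
#'   (levels 0, 1, 2) in bpm, degC and microsiemens.
#' @param scr_rate Skin-conductance-response rate per minute at each level
#'   (increasing with stress; default 1, 4, 8).
#' @param hr_noise_sd,hr_ar Marginal SD (bpm) and AR(1) coefficient of the
#'   heart-rate noise.
#' @param temp_noise_sd,temp_drift_sd Measurement-noise and slow-drift SDs
#'   for temperature (degC).
#' @param eda_noise_sd Smooth EDA measurement-noise SD (microsiemens).
#' @param scr_amp_mean Mean SCR amplitude (microsiemens).
#' @param jitter_sd SD of the smooth stress-profile jitter around the
#'   per-segment base level.
#' @param missing_rate Probability a sample is missing (default 0.0102).
#' @param seed Master seed; per-subject seeds derive from it.
#' @return A `generator_params` object.
#' @export
generator_params <- function(n_subjects = 12L, session_duration = 7200,
                             n_segments = 6L, emergency_segment = 4L,
                             start_time = 1.6e9,
                             hr_means = c(82.23, 86.30, 84.79),
                             temp_means = c(31.81, 31.49, 31.23),
                             eda_means = c(0.68, 2.09, 1.87),
                             scr_rate = c(1, 4, 8),
                             hr_noise_sd = 2, hr_ar = 0.95,
                             temp_noise_sd = 0.05, temp_drift_sd = 0.08,
                             eda_noise_sd = 0.003, scr_amp_mean = 0.3,
                             jitter_sd = 0.04, missing_rate = 0.0102,
                             seed = 1L) {
  if (session_duration <= 0) sw_abort("session_duration must be > 0", "sw_validation_error")
  if (missing_rate < 0 || missing_rate >= 1)
    sw_abort("missing_rate must be in [0, 1)", "sw_validation_error")
  if (hr_means[2L] <= hr_means[1L])
    sw_abort("HR target means must rise from level 0 to level 1", "sw_validation_error")
  if (any(diff(temp_means) >= 0))
    sw_abort("TEMP target means must decrease with level", "sw_validation_error")
  if (any(eda_means[2:3] <= eda_means[1L]))
    sw_abort("EDA target means must be higher at levels 1-2 than level 0",
             "sw_validation_error")
  if (emergency_segment < 1L || emergency_segment > n_segments)
    sw_abort("emergency_segment must be one of the segments", "sw_validation_error")
  structure(as.list(environment()), class = "generator_params")
}

# Smooth AR(1) series with given marginal SD.
ar1_noise <- function(n, phi, marginal_sd) {
  if (marginal_sd <= 0 || n == 0L) return(numeric(n))
  innov_sd <- marginal_sd * sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                           method = "recursive")) +
    stats::rnorm(1, 0, marginal_sd) * phi^seq_len(n)
}

# Piecewise-linear map from stress in [0, 1] to a per-level calibrated
# quantity, interpolating between the band centers and flat beyond them.
level_interp <- function(stress, targets) {
  stats::approx(LEVEL_CENTERS, targets, xout = pmin(pmax(stress, 0), 1),
                rule = 2)$y
}

#' Simulate a session's continuous stress profile
#'
#' Piecewise-constant base level per segment, drawn uniformly from
#' {low, medium, high} band centers with the emergency segment forced high,
#' plus smooth bounded AR(1) jitter; clipped to `[0, 1]`. Sampled at 4 Hz.
#'
#' @param params A [generator_params()].
#' @param seed Subject-level seed.
#' @return A [stress_trace()] with attributes `base_levels` (per segment)
#'   and `segment_boundaries`.
#' @export
make_stress_profile <- function(params, seed = params$seed) {
  n <- as.integer(params$session_duration * 4)
  seg_len <- params$session_duration / params$n_segments
  with_rng(seed, {
    lv <- sample(1:3, params$n_segments, replace = TRUE)
    lv[params$emergency_segment] <- 3L
    ts <- params$start_time + (0:(n - 1L)) / 4
    seg <- pmin(floor((ts - params$start_time) / seg_len) + 1L, params$n_segments)
    base <- LEVEL_CENTERS[lv[seg]]
    jitter <- ar1_noise(n, 0.995, params$jitter_sd)
    values <- pmin(pmax(base + jitter, 0), 1)
    tr <- stress_trace(ts, values)
    attr(tr, "base_levels") <- lv - 1L
    attr(tr, "segment_boundaries") <- params$start_time + seg_len * (0:params$n_segments)
    tr
  })
}

#' Simulate one sensor channel from a stress trace
#'
#' HR (1 Hz) is the level-interpolated target mean plus AR(1) noise; TEMP
#' (4 Hz) is the target mean plus slow drift and measurement noise; EDA
#' (4 Hz) is a tonic level tracking the target mean plus phasic
#' skin-conductance responses -- a Poisson process whose rate increases
#' with stress, convolved with a bi-exponential kernel (rise 0.75 s,
#' decay 2 s) -- plus smooth noise, floored at 0.
#'
#' @param trace A [stress_trace()] at 4 Hz.
#' @param channel `"EDA"`, `"HR"` or `"TEMP"`.
#' @param params A [generator_params()].
#' @param seed Channel-level seed.
#' @return A [channel_recording()] at the channel's native rate.
#' @export
synth_channel <- function(trace, channel, params, seed = params$seed) {
  channel <- match.arg(channel, CHANNELS)
  n4 <- length(trace$values)
  with_rng(seed, {
    samples <- switch(channel,
      HR = {
        s1 <- trace$values[seq(1L, n4, by = 4L)]
        level_interp(s1, params$hr_means) +
          ar1_noise(length(s1), params$hr_ar, params$hr_noise_sd)
      },
      TEMP = {
        level_interp(trace$values, params$temp_means) +
          ar1_noise(n4, 0.999, params$temp_drift_sd) +
          stats::rnorm(n4, 0, params$temp_noise_sd)
      },
      EDA = {
        tonic <- level_interp(trace$values, params$eda_means)
        rate_per_sample <- level_interp(trace$values, params$scr_rate) / 60 / 4
        events <- stats::rbinom(n4, 1L, pmin(rate_per_sample, 1)) *
          stats::rgamma(n4, shape = 4, scale = params$scr_amp_mean / 4)
        tker <- seq(0, 10, by = 0.25)
        ker <- exp(-tker / 2) - exp(-tker / 0.75)
        ker <- ker / max(ker)
        phasic <- stats::convolve(events, rev(ker), type = "open")[seq_len(n4)]
        pmax(tonic + phasic + ar1_noise(n4, 0.98, params$eda_noise_sd), 0)
      }
    )
    rate <- if (channel == "HR") 1 else 4
    channel_recording(channel, trace$timestamps[1L], rate, samples)
  })
}

#' Replace samples by missing values at random
#'
#' Each sample is independently replaced by the missing marker with the
#' given probability (missing completely at random).
#'
#' @param rec A [channel_recording()].
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The recording with a random subset of samples set missing.
#' @export
inject_missing <- function(rec, rate = 0.0102, seed = 1L) {
  if (rate < 0 || rate >= 1) sw_abort("rate must be in [0, 1)", "sw_validation_error")
  if (rate == 0) return(rec)
  with_rng(seed, {
    mask <- stats::runif(length(rec$samples)) < rate
    rec$samples[mask] <- NA_real_
    rec
  })
}

#' Generate a synthetic cohort
#'
#' Produces `n_subjects` sessions of `session_duration` seconds each, with
#' per-subject seeds derived deterministically from the master seed. Each
#' element bundles the session recording (with missing samples injected),
#' the emitted stress trace, and a ground-truth table giving every
#' window's true class (under the default window and label configuration)
#' and scenario segment.
#'
#' @param params A [generator_params()].
#' @return A `synthetic_cohort`: list of `list(session, trace, ground_truth)`.
#' @export
generate_cohort <- function(params = generator_params()) {
  lapply_out <- lapply(seq_len(params$n_subjects), function(i) {
    sseed <- derive_seed(params$seed, 1000L, i)
    trace <- make_stress_profile(params, seed = derive_seed(sseed, 1L))
    channels <- list()
    for (ch in CHANNELS) {
      rec <- synth_channel(trace, ch, params,
                           seed = derive_seed(sseed, 2L, match(ch, CHANNELS)))
      channels[[ch]] <- inject_missing(rec, params$missing_rate,
                                       seed = derive_seed(sseed, 3L, match(ch, CHANNELS)))
    }
    boundaries <- attr(trace, "segment_boundaries")
    frac_high <- mean(trace$values >= 2 / 3)
    success <- if (frac_high > 0.25) FALSE else
      with_rng(derive_seed(sseed, 4L), stats::runif(1) < 0.6)
    session <- session_recording(sprintf("S%02d", i), channels,
                                 segment_boundaries = boundaries,
                                 success = success)
    gt <- cohort_ground_truth(trace, channels, boundaries)
    list(session = session, trace = trace, ground_truth = gt)
  })
  structure(lapply_out, class = "synthetic_cohort", params = params)
}

# True class and segment id of every window the pipeline will form on the
# aligned 4 Hz grid, derived from the emitted trace under the default
# window and label configuration.
cohort_ground_truth <- function(trace, channels, boundaries,
                                feature_cfg = feature_config(),
                                label_cfg = label_config()) {
  starts <- vapply(channels, function(r) r$start_time, numeric(1))
  ends <- vapply(channels, channel_end_time, numeric(1))
  anchor <- max(starts)
  span <- min(ends) - anchor
  n_aligned <- floor(span * 4 + 1e-9) + 1
  win <- make_windows(as.integer(n_aligned), feature_cfg)
  t0 <- anchor + (win$start - 1L) / 4
  lo <- findInterval(t0 - 1e-9, trace$timestamps) + 1L
  hi <- findInterval(t0 + feature_cfg$window_size / 4 - 1e-9, trace$timestamps)
  cs <- c(0, cumsum(trace$values))
  m <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  true_class <- ifelse(m < label_cfg$theta1, 0L, ifelse(m < label_cfg$theta2, 1L, 2L))
  segment <- pmin(findInterval(t0, boundaries), length(boundaries) - 1L)
  data.frame(window_start_time = t0, true_class = true_class,
             segment_id = segment)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<synthetic_cohort> %d subjects x %g s (total %g s), seed %d\n",
              length(x), p$session_duration,
              length(x) * p$session_duration, p$seed))
  invisible(x)
}

#' Write a cohort to disk as E4-style artifacts
#'
#' One directory per subject holding `EDA.csv`, `HR.csv`, `TEMP.csv` (E4
#' export dialect), `stress.csv` (two-column trace) and
#' `ground_truth.csv`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (el in cohort) {
    sdir <- file.path(dir, el$session$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    for (ch in CHANNELS)
      write_channel_csv(el$session$channels[[ch]],
                        file.path(sdir, paste0(ch, ".csv")))
    write_stress_trace(el$trace, file.path(sdir, "stress.csv"))
    utils::write.csv(el$ground_truth, file.path(sdir, "ground_truth.csv"),
                     row.names = FALSE)
    meta <- data.frame(subject_id = el$session$subject_id,
                       success = el$session$success)
    utils::write.csv(meta, file.path(sdir, "meta.csv"), row.names = FALSE)
  }
  invisible(dir)
}
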