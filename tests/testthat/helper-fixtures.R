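# Shared fixtures, memoised so expensive cohorts are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Full-scale default cohort (12 subjects x 7200 s) with features and labels.
default_cohort_fixture <- function() {
  memoise_fixture("default_cohort", function() {
    cohort <- generate_cohort(generator_params(seed = 42L))
    tabs <- lapply(cohort, function(el) {
      tab <- extract_window_features(align_session(el$session))
      b <- el$session$segment_boundaries
      tab$segment_id <- pmin(pmax(findInterval(tab$window_start_time, b), 1L),
                             length(b) - 1L)
      tab
    })
    features <- add_lags(do.call(rbind, tabs))
    traces <- stats::setNames(
      lapply(cohort, function(el) el$trace),
      vapply(cohort, function(el) el$session$subject_id, character(1)))
    dataset <- label_dataset(features, traces)
    list(cohort = cohort, features = features, dataset = dataset)
  })
}

# Small cohort for fast modeling tests (6 subjects x 900 s, ~1000 windows).
small_cohort_fixture <- function() {
  memoise_fixture("small_cohort", function() {
    cohort <- generate_cohort(generator_params(n_subjects = 6L,
                                               session_duration = 900,
                                               seed = 11L))
    tabs <- lapply(cohort, function(el)
      extract_window_features(align_session(el$session)))
    features <- add_lags(do.call(rbind, tabs))
    traces <- stats::setNames(
      lapply(cohort, function(el) el$trace),
      vapply(cohort, function(el) el$session$subject_id, character(1)))
    dataset <- label_dataset(features, traces)
    list(cohort = cohort, features = features, dataset = dataset)
  })
}

# Tiny perfectly separable dataset: class determined by one feature, with
# wide margins so held-out points never fall between a learned split and
# the true boundary.
separable_dataset <- function(n = 150L, seed = 5L) {
  withr::with_seed(seed, {
    y <- sample(0:2, n, replace = TRUE)
    lo <- c(0, 0.37, 0.7)[y + 1L]
    hi <- c(0.3, 0.63, 1)[y + 1L]
    feats <- data.frame(EDA_Mean = runif(n, lo, hi), HR_Mean = runif(n),
                        TEMP_Mean = runif(n))
    labeled_dataset(feats, y)
  })
}

# Stratified row subsample of a labeled dataset (proportional per class).
subsample_stratified <- function(ds, n, seed = 1L) {
  frac <- n / length(ds$labels)
  keep <- integer(0)
  withr::with_seed(seed, {
    for (cl in unique(ds$labels)) {
      idx <- which(ds$labels == cl)
      keep <- c(keep, sample(idx, max(5L, round(length(idx) * frac))))
    }
  })
  stresswear:::ld_subset(ds, sort(keep))
}

rf_config_default <- function() {
  list(n_estimators = 100L, max_depth = 15L, max_features = "sqrt",
       min_samples_split = 2L, min_samples_leaf = 1L, bootstrap = TRUE)
}

gb_config_default <- function() {
  list(n_estimators = 100L, max_depth = 5L, learning_rate = 0.1)
}
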