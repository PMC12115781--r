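# Orchestration: run the full analysis from a configuration list or YAML
# file, writing every artifact plus a manifest to an output directory.

#' Default pipeline configuration
#'
#' @param seed Master seed; every stage derives its own seed from it.
#' @param synthetic Generate a synthetic cohort (`TRUE`) or read sessions
#'   from `data_dir` (one sub-directory per subject holding EDA.csv, HR.csv,
#'   TEMP.csv and stress.csv).
#' @param data_dir Input directory when `synthetic = FALSE`.
#' @param generator List of [generator_params()] overrides.
#' @param features List of [feature_config()] overrides.
#' @param labels List of [label_config()] overrides.
#' @param protocol List: `test_fraction` (default 0.2), `k` (folds, 5),
#'   `n_iterations` (randomized-search draws, 100), `max_rows` (optional
#'   stratified row cap applied before model selection).
#' @param report List: `alpha` (0.001), `emergency_segment` (4),
#'   `flag_threshold` (0.25).
#' @param models Character subset of `c("rf","gb","stack","lr","svm","knn","ada")`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, synthetic = TRUE, data_dir = NULL,
                            generator = list(), features = list(),
                            labels = list(), protocol = list(),
                            report = list(),
                            models = c("rf", "gb", "stack")) {
  proto <- utils::modifyList(list(test_fraction = 0.2, k = 5L,
                                  n_iterations = 100L, max_rows = NULL),
                             protocol)
  rep_opts <- utils::modifyList(list(alpha = 0.001, emergency_segment = 4L,
                                     flag_threshold = 0.25), report)
  structure(list(seed = as.integer(seed), synthetic = isTRUE(synthetic),
                 data_dir = data_dir, generator = generator,
                 features = features, labels = labels, protocol = proto,
                 report = rep_opts, models = tolower(models)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

# Read one subject directory (EDA.csv/HR.csv/TEMP.csv + stress.csv [+ meta]).
read_session_dir <- function(sdir) {
  channels <- list()
  for (ch in CHANNELS) {
    f <- file.path(sdir, paste0(ch, ".csv"))
    if (!file.exists(f))
      sw_abort(sprintf("sensor_io: missing channel file %s", f), "sw_format_error")
    channels[[ch]] <- read_channel_csv(f, ch)
  }
  trace <- read_stress_trace(file.path(sdir, "stress.csv"))
  meta_f <- file.path(sdir, "meta.csv")
  success <- if (file.exists(meta_f)) utils::read.csv(meta_f)$success[1L] else NA
  session <- session_recording(basename(sdir), channels, success = success)
  list(session = session, trace = trace)
}

#' Run the full analysis pipeline
#'
#' Stage order: simulate (optional) -> read -> preprocess -> features ->
#' label -> train/evaluate -> interpret. Writes feature tables, CV results,
#' classification reports, importance tables, level statistics and a
#' manifest (configuration hash and seeds) under `out_dir`.
#'
#' @param config A `pipeline_config`, or the path to a YAML file.
#' @param out_dir Output directory for artifacts.
#' @return Invisibly, a list with every intermediate and final result.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("sw_run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  fcfg <- do.call(feature_config, config$features)
  lcfg <- do.call(label_config, config$labels)

  # ---- data ----
  if (config$synthetic) {
    gp <- do.call(generator_params,
                  utils::modifyList(config$generator, list(seed = seed)))
    cohort <- generate_cohort(gp)
  } else {
    if (is.null(config$data_dir))
      sw_abort("sensor_io: data_dir required when synthetic = FALSE", "sw_format_error")
    sdirs <- list.dirs(config$data_dir, recursive = FALSE)
    if (length(sdirs) == 0L)
      sw_abort(sprintf("sensor_io: no subject directories under %s", config$data_dir),
               "sw_format_error")
    cohort <- lapply(sdirs, read_session_dir)
  }

  # ---- preprocess + features + segments ----
  tables <- lapply(cohort, function(el) {
    aligned <- align_session(el$session)
    tab <- extract_window_features(aligned, fcfg)
    b <- el$session$segment_boundaries
    tab$segment_id <- if (!is.null(b))
      pmin(pmax(findInterval(tab$window_start_time, b), 1L), length(b) - 1L)
    else NA_integer_
    tab
  })
  features_all <- do.call(rbind, tables)
  features_lagged <- add_lags(features_all, fcfg)
  write_feature_table(features_lagged, file.path(out_dir, "features.csv"))

  # ---- label ----
  traces <- stats::setNames(lapply(cohort, function(el) el$trace),
                            vapply(cohort, function(el) el$session$subject_id,
                                   character(1)))
  ds <- label_dataset(features_lagged, traces, lcfg, fcfg)
  utils::write.csv(data.frame(subject_id = ds$subject_id,
                              window_start_time = ds$window_start_time,
                              segment_id = ds$segment_id, label = ds$labels),
                   file.path(out_dir, "labels.csv"), row.names = FALSE)

  # ---- optional stratified row cap to bound model-selection cost ----
  ds_model <- ds
  if (!is.null(config$protocol$max_rows) &&
      length(ds$labels) > config$protocol$max_rows) {
    frac <- config$protocol$max_rows / length(ds$labels)
    keep <- integer(0)
    with_rng(derive_seed(seed, 400L), {
      for (cl in unique(ds$labels)) {
        idx <- which(ds$labels == cl)
        keep <- c(keep, sample(idx, max(2L, round(length(idx) * frac))))
      }
    })
    ds_model <- ld_subset(ds, sort(keep))
  }

  # ---- split, select, evaluate ----
  split <- stratified_split(ds_model$labels, config$protocol$test_fraction,
                            seed = derive_seed(seed, 401L))
  train <- ld_subset(ds_model, split$train)
  test <- ld_subset(ds_model, split$test)
  results <- list(config = config, dataset = ds, train = train, test = test)
  n_it <- config$protocol$n_iterations

  cv <- list(); reports <- list(); models <- list()
  scaled <- minmax_scale(train$features, list(test$features))
  train_s <- train; train_s$features <- scaled$train
  test_s <- test; test_s$features <- scaled$others[[1L]]

  if ("rf" %in% config$models) {
    cv$rf <- nested_cv(train, rf_space(n_it), seed = derive_seed(seed, 402L))
    models$rf <- train_learner("RF", best_configuration(cv$rf), train_s,
                               seed = derive_seed(seed, 403L))
    reports$rf <- evaluate(models$rf, test_s)
  }
  if ("gb" %in% config$models) {
    cv$gb <- nested_cv(train, gb_space(n_it), seed = derive_seed(seed, 404L))
    models$gb <- train_learner("GB", best_configuration(cv$gb), train_s,
                               seed = derive_seed(seed, 405L))
    reports$gb <- evaluate(models$gb, test_s)
  }
  if ("stack" %in% config$models) {
    if (is.null(models$rf) || is.null(models$gb))
      sw_abort("modeling: stacking requires rf and gb", "sw_validation_error")
    models$stack <- train_stacking(train_s, models$rf$config, models$gb$config,
                                   seed = derive_seed(seed, 406L))
    reports$stack <- evaluate(models$stack, test_s)
  }
  grid_spaces <- list(lr = lr_grid, svm = svm_grid, knn = knn_grid, ada = ada_grid)
  for (nm in intersect(names(grid_spaces), config$models)) {
    gs <- grid_search_cv(train, grid_spaces[[nm]](),
                         seed = derive_seed(seed, 407L, match(nm, names(grid_spaces))))
    cv[[nm]] <- list(best_accuracy = gs$best_accuracy, n_fits = gs$n_fits,
                     best_config = gs$best_config)
    test_g <- test; test_g$features <- minmax_apply(test$features, gs$scaler)
    models[[nm]] <- gs$model
    reports[[nm]] <- evaluate(gs$model, test_g)
  }
  results$cv <- cv; results$models <- models; results$reports <- reports

  for (nm in names(reports)) {
    rep <- reports[[nm]]
    jsonlite::write_json(
      list(per_class = rep$per_class, accuracy = rep$accuracy,
           macro = c(rep$macro_precision, rep$macro_recall, rep$macro_f1),
           weighted = c(rep$weighted_precision, rep$weighted_recall, rep$weighted_f1)),
      file.path(out_dir, sprintf("report_%s.json", nm)),
      auto_unbox = TRUE, digits = NA)
    writeLines(utils::capture.output(print(rep)),
               file.path(out_dir, sprintf("report_%s.txt", nm)))
  }
  for (nm in names(cv)) {
    jsonlite::write_json(unclass(cv[[nm]]),
                         file.path(out_dir, sprintf("cv_%s.json", nm)),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  # ---- interpret ----
  interp <- list()
  if (!is.null(models$rf)) {
    interp$importance_rf <- mdi_importance(models$rf)
    utils::write.csv(interp$importance_rf,
                     file.path(out_dir, "importance_rf.csv"), row.names = FALSE)
  }
  if (!is.null(models$gb)) {
    interp$importance_gb <- mdi_importance(models$gb)
    utils::write.csv(interp$importance_gb,
                     file.path(out_dir, "importance_gb.csv"), row.names = FALSE)
  }
  interp$correlations <- feature_correlations(
    features_lagged[c("window_start_time", "subject_id",
                      grep("^(EDA|HR|TEMP)_", names(features_lagged),
                           value = TRUE))])
  utils::write.csv(as.data.frame(interp$correlations),
                   file.path(out_dir, "feature_correlations.csv"))
  interp$level_tests <- level_comparison_tests(ds$features, ds$labels,
                                               alpha = config$report$alpha)
  jsonlite::write_json(list(means = as.data.frame(interp$level_tests$means),
                            tests = interp$level_tests$tests),
                       file.path(out_dir, "level_tests.json"),
                       auto_unbox = TRUE, digits = NA)
  success <- vapply(cohort, function(el) {
    s <- el$session$success
    if (is.null(s) || is.na(s)) NA else isTRUE(s)
  }, logical(1))
  names(success) <- vapply(cohort, function(el) el$session$subject_id, character(1))
  interp$level_summary <- time_in_levels(ds$labels, ds$subject_id,
                                         success = success,
                                         flag_threshold = config$report$flag_threshold)
  utils::write.csv(interp$level_summary, file.path(out_dir, "level_summary.csv"),
                   row.names = FALSE)
  if (!all(is.na(ds$segment_id))) {
    interp$segment_validation <- segment_validation(
      ds$labels, ds$segment_id, ds$subject_id,
      emergency_segment = config$report$emergency_segment)
    utils::write.csv(interp$segment_validation,
                     file.path(out_dir, "segment_validation.csv"),
                     row.names = FALSE)
  }
  results$interpret <- interp

  # ---- manifest ----
  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  manifest <- list(config_hash = unname(tools::md5sum(cfg_json)),
                   seed = seed,
                   n_subjects = length(cohort),
                   n_windows = length(ds$labels),
                   models = names(reports),
                   written = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  results$out_dir <- out_dir
  invisible(results)
}
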