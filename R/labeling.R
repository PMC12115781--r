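# Convert the continuous observer stress trace into 3 classes per window.
#
# Class 0 = no stress, 1 = medium, 2 = high. The class of a window is the
# thresholded mean of the trace values falling in the window (left-closed
# intervals: mean == theta1 is class 1). The thresholds default to the
# tertile cut points 1/3 and 2/3 of the [0, 1] annotation scale and are
# fully configurable.

#' Labeling configuration
#'
#' @param theta1,theta2 Class thresholds with `0 < theta1 < theta2 < 1`
#'   (defaults 1/3 and 2/3). Window means below `theta1` are class 0, in
#'   `[theta1, theta2)` class 1, at or above `theta2` class 2.
#' @return A `label_config` object.
#' @export
label_config <- function(theta1 = 1 / 3, theta2 = 2 / 3) {
  if (!is_scalar_number(theta1) || !is_scalar_number(theta2) ||
      theta1 <= 0 || theta2 >= 1 || theta1 >= theta2)
    sw_abort("need 0 < theta1 < theta2 < 1", "sw_validation_error")
  structure(list(theta1 = theta1, theta2 = theta2), class = "label_config")
}

#' Stress class of one window
#'
#' @param trace A [stress_trace()].
#' @param window_start,window_end Window span in seconds; trace points with
#'   timestamps in `[window_start, window_end)` are averaged.
#' @param cfg A [label_config()].
#' @return Integer class 0, 1 or 2.
#' @export
label_window <- function(trace, window_start, window_end, cfg = label_config()) {
  stopifnot(inherits(trace, "stress_trace"))
  sel <- trace$timestamps >= window_start & trace$timestamps < window_end
  if (!any(sel))
    sw_abort(sprintf("no stress-trace points in window [%g, %g)",
                     window_start, window_end), "sw_coverage_error")
  m <- mean(trace$values[sel])
  if (m < cfg$theta1) 0L else if (m < cfg$theta2) 1L else 2L
}

#' Label every window of a feature table
#'
#' Each feature row's window span is `[window_start_time, window_start_time
#' + window_size / rate)`; its class is the thresholded mean of the trace
#' over that span.
#'
#' @param features Feature table with a `window_start_time` column.
#' @param trace A [stress_trace()] covering all windows (one trace for all
#'   rows, or a named list of traces indexed by `subject_id`).
#' @param cfg A [label_config()].
#' @param feature_cfg The [feature_config()] used to build `features`
#'   (supplies the window size).
#' @param rate Grid rate in Hz (default 4).
#' @return A `labeled_dataset`: list with `features` (the table), integer
#'   `labels` in `{0, 1, 2}`, and per-row `subject_id`, `segment_id`
#'   (NA when absent), `window_start_time`.
#' @export
label_dataset <- function(features, trace, cfg = label_config(),
                          feature_cfg = feature_config(), rate = 4) {
  if (!"window_start_time" %in% names(features))
    sw_abort("features lack window_start_time", "sw_schema_error")
  dur <- feature_cfg$window_size / rate
  subj <- features$subject_id %||% rep("all", nrow(features))
  labels <- integer(nrow(features))
  for (s in unique(subj)) {
    tr <- if (inherits(trace, "stress_trace")) trace else trace[[s]]
    if (is.null(tr))
      sw_abort(sprintf("no stress trace for subject %s", s), "sw_coverage_error")
    ridx <- which(subj == s)
    starts <- features$window_start_time[ridx]
    # points with timestamp in [start, start + dur): resolved with cumulative
    # sums so labeling stays linear in the trace length
    lo <- findInterval(starts - 1e-9, tr$timestamps) + 1L
    hi <- findInterval(starts + dur - 1e-9, tr$timestamps)
    if (any(hi < lo)) {
      bad <- ridx[which(hi < lo)[1L]]
      sw_abort(sprintf("window %d (subject %s, start %g) has no stress-trace points",
                       bad, s, features$window_start_time[bad]), "sw_coverage_error")
    }
    cs <- c(0, cumsum(tr$values))
    m <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    labels[ridx] <- ifelse(m < cfg$theta1, 0L, ifelse(m < cfg$theta2, 1L, 2L))
  }
  labeled_dataset(features, labels,
                  subject_id = subj,
                  segment_id = features$segment_id %||% rep(NA_integer_, nrow(features)))
}

#' Bundle features and labels into a labeled dataset
#'
#' @param features Feature table (metadata columns allowed).
#' @param labels Integer vector in `{0, 1, 2}`, one per feature row.
#' @param subject_id,segment_id Optional per-row identifiers.
#' @return A `labeled_dataset` object.
#' @export
labeled_dataset <- function(features, labels, subject_id = NULL, segment_id = NULL) {
  labels <- as.integer(labels)
  if (length(labels) != nrow(features))
    sw_abort("labels length must equal feature rows", "sw_validation_error")
  if (length(labels) > 0L && !all(labels %in% 0:2))
    sw_abort("labels must be in {0, 1, 2}", "sw_validation_error")
  structure(
    list(features = features, labels = labels,
         subject_id = subject_id %||% features$subject_id %||% rep("all", nrow(features)),
         segment_id = segment_id %||% features$segment_id %||% rep(NA_integer_, nrow(features)),
         window_start_time = features$window_start_time %||% rep(NA_real_, nrow(features))),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:2))
  cat(sprintf("<labeled_dataset> %d rows x %d features; class counts 0/1/2 = %d/%d/%d\n",
              nrow(x$features), length(feature_columns(x$features)),
              tab[1L], tab[2L], tab[3L]))
  invisible(x)
}

# Row subset of a labeled dataset.
ld_subset <- function(ds, idx) {
  labeled_dataset(ds$features[idx, , drop = FALSE], ds$labels[idx],
                  ds$subject_id[idx], ds$segment_id[idx])
}

# Numeric model matrix of the feature columns.
ld_matrix <- function(ds) {
  as.matrix(ds$features[feature_columns(ds$features)])
}
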