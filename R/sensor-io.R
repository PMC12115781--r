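# Domain types and on-disk formats for wrist-sensor sessions.
#
# Channel files follow the Empatica E4 export convention: row 1 is the UNIX
# start time in seconds, row 2 the sampling rate in Hz, every following row
# one sample. One file per channel (EDA.csv / HR.csv / TEMP.csv). Missing
# samples are an empty field or the literal "NaN" on disk and NA in memory.

CHANNELS <- c("EDA", "HR", "TEMP")
CHANNEL_UNITS <- c(EDA = "microsiemens", HR = "beats/min", TEMP = "degC")

#' Construct a single-channel sensor recording
#'
#' @param channel One of `"EDA"`, `"HR"`, `"TEMP"`.
#' @param start_time Recording start, seconds since epoch.
#' @param rate Sampling rate in Hz (positive).
#' @param samples Numeric vector of samples; `NA` marks a missing sample.
#'   EDA samples are in microsiemens, HR in beats/min, TEMP in degrees C.
#' @return A `channel_recording` object.
#' @export
channel_recording <- function(channel, start_time, rate, samples) {
  channel <- match.arg(channel, CHANNELS)
  stopifnot_scalar(start_time, "start_time")
  stopifnot_scalar(rate, "rate")
  if (rate <= 0) sw_abort("sampling rate must be positive", "sw_validation_error")
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    sw_abort("a channel recording needs at least one sample", "sw_validation_error")
  if (any(!is.na(samples) & !is.finite(samples)))
    sw_abort("non-missing samples must be finite", "sw_validation_error")
  if (channel == "EDA" && any(samples < 0, na.rm = TRUE))
    sw_abort("EDA samples (skin conductance) cannot be negative", "sw_validation_error")
  structure(
    list(channel = channel, start_time = as.numeric(start_time),
         rate = as.numeric(rate), samples = samples,
         units = unname(CHANNEL_UNITS[channel])),
    class = "channel_recording"
  )
}

#' @export
print.channel_recording <- function(x, ...) {
  cat(sprintf("<channel_recording> %s: %d samples @ %g Hz (%s), %d missing\n",
              x$channel, length(x$samples), x$rate, x$units, sum(is.na(x$samples))))
  invisible(x)
}

# End of the sampled interval, seconds since epoch.
channel_end_time <- function(rec) rec$start_time + (length(rec$samples) - 1) / rec$rate

#' Construct a continuous stress-annotation trace
#'
#' The trace is an observer-rated stress metric on `[0, 1]` (0 = low,
#' 1 = high) sampled at strictly increasing timestamps.
#'
#' @param timestamps Seconds since epoch, strictly increasing.
#' @param values Stress ratings in `[0, 1]`, same length as `timestamps`.
#' @return A `stress_trace` object.
#' @export
stress_trace <- function(timestamps, values) {
  timestamps <- as.numeric(timestamps)
  values <- as.numeric(values)
  if (length(timestamps) != length(values))
    sw_abort("timestamps and values must have the same length", "sw_validation_error")
  if (length(timestamps) < 1L)
    sw_abort("a stress trace needs at least one point", "sw_validation_error")
  if (any(diff(timestamps) <= 0))
    sw_abort("stress-trace timestamps must be strictly increasing", "sw_ordering_error")
  if (any(!is.finite(values)) || any(values < 0 | values > 1))
    sw_abort("stress values must lie in [0, 1]", "sw_range_error")
  structure(list(timestamps = timestamps, values = values), class = "stress_trace")
}

#' @export
print.stress_trace <- function(x, ...) {
  cat(sprintf("<stress_trace> %d points over %.1f s, mean %.3f\n",
              length(x$values), diff(range(x$timestamps)), mean(x$values)))
  invisible(x)
}

#' Construct a full session (all three channels plus metadata)
#'
#' @param subject_id Subject identifier.
#' @param channels Named list with elements `EDA`, `HR`, `TEMP`, each a
#'   [channel_recording()].
#' @param segment_boundaries Optional vector of 7 strictly increasing
#'   timestamps delimiting the six scenario segments.
#' @param success Optional logical treatment-success flag.
#' @return A `session_recording` object.
#' @export
session_recording <- function(subject_id, channels, segment_boundaries = NULL,
                              success = NA) {
  if (!all(CHANNELS %in% names(channels)))
    sw_abort("channels must contain all of EDA, HR, TEMP", "sw_validation_error")
  for (ch in CHANNELS) {
    if (!inherits(channels[[ch]], "channel_recording"))
      sw_abort(sprintf("channel %s is not a channel_recording", ch), "sw_validation_error")
    if (channels[[ch]]$channel != ch)
      sw_abort(sprintf("channel slot %s holds a %s recording", ch, channels[[ch]]$channel),
               "sw_validation_error")
  }
  starts <- vapply(channels[CHANNELS], function(r) r$start_time, numeric(1))
  ends <- vapply(channels[CHANNELS], channel_end_time, numeric(1))
  if (max(starts) >= min(ends))
    sw_abort("channel time spans do not overlap", "sw_alignment_error")
  if (!is.null(segment_boundaries)) {
    segment_boundaries <- as.numeric(segment_boundaries)
    if (length(segment_boundaries) != 7L || any(diff(segment_boundaries) <= 0))
      sw_abort("segment_boundaries must be 7 strictly increasing timestamps",
               "sw_validation_error")
  }
  structure(
    list(subject_id = as.character(subject_id), channels = channels[CHANNELS],
         segment_boundaries = segment_boundaries, success = success),
    class = "session_recording"
  )
}

#' Read one E4-style channel CSV
#'
#' Row 1 must be the numeric UNIX start time, row 2 a positive sampling rate
#' in Hz, and every later row one sample (blank field or `NaN` = missing).
#'
#' @param path Path to the channel file.
#' @param channel Which channel the file holds (`"EDA"`, `"HR"`, `"TEMP"`).
#' @return A [channel_recording()].
#' @export
read_channel_csv <- function(path, channel) {
  channel <- match.arg(channel, CHANNELS)
  if (!file.exists(path)) sw_abort(sprintf("file not found: %s", path), "sw_format_error")
  lines <- trimws(readLines(path, warn = FALSE))
  if (length(lines) < 3L)
    sw_abort(sprintf("%s: need a 2-row header plus at least one sample", path),
             "sw_format_error")
  start_time <- suppressWarnings(as.numeric(lines[1L]))
  if (is.na(start_time))
    sw_abort(sprintf("%s: line 1 ('%s') is not a numeric start time", path, lines[1L]),
             "sw_format_error")
  rate <- suppressWarnings(as.numeric(lines[2L]))
  if (is.na(rate))
    sw_abort(sprintf("%s: line 2 ('%s') is not a numeric sampling rate", path, lines[2L]),
             "sw_format_error")
  if (rate <= 0)
    sw_abort(sprintf("%s: sampling rate must be positive, got %g", path, rate),
             "sw_validation_error")
  raw <- lines[-(1:2)]
  samples <- rep(NA_real_, length(raw))
  filled <- !(raw == "" | toupper(raw) == "NAN" | toupper(raw) == "NA")
  vals <- suppressWarnings(as.numeric(raw[filled]))
  if (any(is.na(vals))) {
    bad <- which(filled)[which(is.na(vals))[1L]] + 2L
    sw_abort(sprintf("%s: line %d ('%s') is not numeric", path, bad, raw[bad - 2L]),
             "sw_format_error")
  }
  samples[filled] <- vals
  channel_recording(channel, start_time, rate, samples)
}

#' Write a channel recording in the E4 export dialect
#'
#' @param rec A [channel_recording()].
#' @param path Output path. Missing samples are written as empty fields.
#' @export
write_channel_csv <- function(rec, path) {
  stopifnot(inherits(rec, "channel_recording"))
  vals <- ifelse(is.na(rec$samples), "", format(rec$samples, digits = 15, trim = TRUE,
                                               scientific = FALSE))
  writeLines(c(format(rec$start_time, digits = 15, scientific = FALSE),
               format(rec$rate, digits = 15, scientific = FALSE), vals), path)
  invisible(path)
}

#' Read a continuous stress trace from a two-column CSV
#'
#' Columns are timestamp (seconds) and stress value in `[0, 1]`. Values
#' outside the unit interval are rejected, not clipped; non-increasing
#' timestamps are an error.
#'
#' @param path Path to the trace file (header optional).
#' @return A [stress_trace()].
#' @export
read_stress_trace <- function(path) {
  if (!file.exists(path)) sw_abort(sprintf("file not found: %s", path), "sw_format_error")
  first <- strsplit(readLines(path, n = 1L, warn = FALSE), ",")[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  df <- utils::read.csv(path, header = has_header)
  if (ncol(df) < 2L)
    sw_abort(sprintf("%s: expected two columns (timestamp, value)", path), "sw_format_error")
  stress_trace(df[[1L]], df[[2L]])
}

#' Write a stress trace as a two-column CSV
#'
#' @param trace A [stress_trace()].
#' @param path Output path.
#' @export
write_stress_trace <- function(trace, path) {
  stopifnot(inherits(trace, "stress_trace"))
  utils::write.csv(data.frame(timestamp = trace$timestamps, value = trace$values),
                   path, row.names = FALSE)
  invisible(path)
}

# Metadata columns a feature table may carry in addition to features.
FEATURE_META_COLS <- c("window_start_time", "subject_id", "segment_id", "label")

# Canonical feature-name pattern: EDA_Mean, HR_Std, TEMP_Max, EDA_Mean_lag3, ...
is_canonical_feature_name <- function(x) {
  grepl("^(EDA|HR|TEMP)_(Min|Max|Mean|Std|Skew|Kurtosis|Peaks|Amplitude|Duration|RMS)(_lag[0-9]+)?$",
        x)
}

#' Names of the feature columns of a feature table
#'
#' @param table A feature table (data frame).
#' @return Character vector of feature column names (metadata columns
#'   `window_start_time`, `subject_id`, `segment_id`, `label` excluded).
#' @export
feature_columns <- function(table) setdiff(names(table), FEATURE_META_COLS)

#' Write / read a feature table as headered CSV
#'
#' Round-trips are the identity up to floating-point representation
#' (values are written with 15 significant digits). The header carries the
#' canonical feature names.
#'
#' @param table Feature table (data frame with unique column names).
#' @param path File path.
#' @return `read_feature_table` returns the table; unknown (non-canonical,
#'   non-metadata) columns or a missing header raise a schema error.
#' @export
write_feature_table <- function(table, path) {
  if (anyDuplicated(names(table)))
    sw_abort("feature table column names must be unique", "sw_schema_error")
  utils::write.csv(format_df_full_precision(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

format_df_full_precision <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]))
      df[[j]] <- format(df[[j]], digits = 15, trim = TRUE, scientific = TRUE)
  }
  df
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) sw_abort(sprintf("file not found: %s", path), "sw_schema_error")
  first <- strsplit(readLines(path, n = 1L, warn = FALSE), ",")[[1L]]
  if (!any(is.na(suppressWarnings(as.numeric(first)))))
    sw_abort(sprintf("%s: missing header row", path), "sw_schema_error")
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  feats <- feature_columns(df)
  unknown <- feats[!is_canonical_feature_name(feats)]
  if (length(unknown) > 0L)
    sw_abort(sprintf("%s: unknown column(s): %s", path,
                     paste(unknown, collapse = ", ")), "sw_schema_error")
  if ("subject_id" %in% names(df)) df$subject_id <- as.character(df$subject_id)
  df
}
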