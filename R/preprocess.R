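# Bring the three channels onto a common 4 Hz grid and impute missing values.
#
# The wristband emits EDA/TEMP at 4 Hz and HR at 1 Hz; all channels are
# resampled (linear interpolation) to a unified 4 Hz grid so windows align
# across signals. HR is upsampled rather than EDA/TEMP downsampled to avoid
# discarding information. Missing samples propagate through resampling and
# are then replaced per channel by the channel's session median.

# Value of `rec` at grid times start + k/target_rate, k = 0..m (0-based
# original-sample position `pos` per grid point). Linear interpolation
# between the two bracketing original samples; if either bracket is missing
# the grid point stays missing.
resample_positions <- function(samples, pos) {
  n <- length(samples)
  i0 <- pmax(0, pmin(n - 1L, floor(pos + 1e-9)))
  i1 <- pmax(0, pmin(n - 1L, ceiling(pos - 1e-9)))
  out <- numeric(length(pos))
  same <- i0 == i1
  out[same] <- samples[i0[same] + 1L]
  if (any(!same)) {
    a <- samples[i0[!same] + 1L]
    b <- samples[i1[!same] + 1L]
    frac <- pos[!same] - i0[!same]
    out[!same] <- a + frac * (b - a)  # NA if either neighbour is NA
  }
  out
}

#' Resample a channel to a target rate
#'
#' Linear interpolation between non-missing neighbouring samples onto a grid
#' anchored at the recording start and truncated to the last full grid point.
#' Grid points falling inside runs of missing input remain missing.
#'
#' @param rec A [channel_recording()] with at least 2 non-missing samples.
#' @param target_rate Target rate in Hz (default 4, the unified pipeline rate).
#' @return A [channel_recording()] at `target_rate`.
#' @export
resample_channel <- function(rec, target_rate = 4) {
  stopifnot(inherits(rec, "channel_recording"))
  stopifnot_scalar(target_rate, "target_rate")
  if (sum(!is.na(rec$samples)) < 2L)
    sw_abort("resampling needs at least 2 non-missing samples", "sw_insufficient_data_error")
  span <- (length(rec$samples) - 1L) / rec$rate
  m <- floor(span * target_rate + 1e-9)
  pos <- (0:m) * (rec$rate / target_rate)
  channel_recording(rec$channel, rec$start_time, target_rate,
                    resample_positions(rec$samples, pos))
}

#' Replace missing entries by the vector median
#'
#' Every `NA` is replaced by the median of the non-missing entries;
#' non-missing entries are unchanged, so the operation is idempotent.
#'
#' @param values Numeric vector with possible `NA`s (at least one non-`NA`).
#' @return Numeric vector without `NA`s.
#' @export
impute_median <- function(values) {
  ok <- !is.na(values)
  if (!any(ok)) sw_abort("cannot impute an all-missing vector", "sw_insufficient_data_error")
  values[!ok] <- stats::median(values[ok])
  values
}

#' Align a session's channels on a common 4 Hz grid
#'
#' All three channels are resampled to 4 Hz on a grid anchored at the latest
#' channel start and truncated to the intersection of the channel time spans
#' (grid length `floor(span * 4) + 1`), then median-imputed per channel.
#'
#' @param session A [session_recording()].
#' @param grid_rate Common rate in Hz (default 4).
#' @return An `aligned_signals` object: equal-length `eda`, `hr`, `temp`
#'   vectors with no missing values, plus `grid_start` and `grid_rate`.
#' @export
align_session <- function(session, grid_rate = 4) {
  stopifnot(inherits(session, "session_recording"))
  starts <- vapply(session$channels, function(r) r$start_time, numeric(1))
  ends <- vapply(session$channels, channel_end_time, numeric(1))
  anchor <- max(starts)
  span <- min(ends) - anchor
  if (span <= 0)
    sw_abort("channel time spans have empty intersection", "sw_alignment_error")
  m <- floor(span * grid_rate + 1e-9)
  grid <- list()
  for (ch in CHANNELS) {
    rec <- session$channels[[ch]]
    if (sum(!is.na(rec$samples)) < 2L)
      sw_abort(sprintf("channel %s has fewer than 2 non-missing samples", ch),
               "sw_insufficient_data_error")
    pos <- ((anchor - rec$start_time) + (0:m) / grid_rate) * rec$rate
    grid[[ch]] <- impute_median(resample_positions(rec$samples, pos))
  }
  structure(
    list(subject_id = session$subject_id, grid_start = anchor,
         grid_rate = grid_rate, eda = grid$EDA, hr = grid$HR, temp = grid$TEMP),
    class = "aligned_signals"
  )
}

#' @export
print.aligned_signals <- function(x, ...) {
  cat(sprintf("<aligned_signals> subject %s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, length(x$eda), x$grid_rate,
              (length(x$eda) - 1) / x$grid_rate))
  invisible(x)
}
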