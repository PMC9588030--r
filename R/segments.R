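#' Sliding 2-hour analysis windows
#'
#' Partitions a record into sliding analysis windows of `window_s` seconds
#' stepping by `step_s` (default: 2-hour windows stepping by one 24-min
#' segment, so the management decision can be refreshed every 24 minutes).
#' The last partial window is dropped.
#'
#' @param record A [monitoring_record()], or a single number giving the
#'   record duration in seconds.
#' @param window_s Window length, seconds (default 7200).
#' @param step_s Window step, seconds (default 1440).
#' @return A `data.frame` with columns `window_id` (e.g. `"w0001"`) and
#'   `start_s`; zero rows (with a warning) if the record is shorter than one
#'   window.
#' @export
make_windows <- function(record, window_s = 7200, step_s = 1440) {
  duration <- if (inherits(record, "monitoring_record")) {
    length(record$t) * record$sample_period_s
  } else {
    as.numeric(record)
  }
  if (duration < window_s) {
    warning("record shorter than one analysis window; no windows produced")
    return(data.frame(window_id = character(0), start_s = numeric(0)))
  }
  starts <- seq(0, duration - window_s, by = step_s)
  data.frame(window_id = sprintf("w%04d", seq_along(starts)),
             start_s = starts)
}

#' Split a 2-hour window into five 24-minute segments
#'
#' @param window_start_s Window start time, seconds.
#' @param window_id Window identifier carried onto the segments.
#' @param window_s Window length, seconds (must be 5 x 1440 = 7200 by
#'   default; more generally five equal segments are produced).
#' @return A `data.frame` of 5 rows with `window_id`, `segment_index`
#'   (0..4), `start_s`, `end_s`; segments are half-open `[start_s, end_s)`
#'   and tile the window exactly.
#' @export
split_window <- function(window_start_s, window_id = "w0001", window_s = 7200) {
  seg_len <- window_s / 5
  idx <- 0:4
  data.frame(window_id = window_id,
             segment_index = idx,
             start_s = window_start_s + idx * seg_len,
             end_s = window_start_s + (idx + 1) * seg_len)
}

#' Segment table for a whole record
#'
#' Convenience wrapper: [make_windows()] then [split_window()] for each
#' window, returning one table of all (window, segment) rows.
#'
#' @inheritParams make_windows
#' @return A `data.frame` with `window_id`, `segment_index`, `start_s`,
#'   `end_s` (5 rows per window).
#' @export
segment_table <- function(record, window_s = 7200, step_s = 1440) {
  w <- make_windows(record, window_s, step_s)
  if (nrow(w) == 0)
    return(data.frame(window_id = character(0), segment_index = integer(0),
                      start_s = numeric(0), end_s = numeric(0)))
  do.call(rbind, lapply(seq_len(nrow(w)), function(i) {
    split_window(w$start_s[i], w$window_id[i], window_s)
  }))
}

# Map PRx sample end-times to segment indices within a window.
# A sample belongs to the segment containing the instant just before t_end,
# so a window ending exactly on a segment boundary counts toward the
# segment it closes.
prx_segment_index <- function(t_end, window_start_s, seg_len = 1440) {
  floor((t_end - window_start_s - 1e-9) / seg_len)
}
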