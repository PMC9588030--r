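#' Artifact-detection features (X1) for one segment
#'
#' Per channel (ABP, ICP), summaries of the pulse amplitude
#' `d = sys - dia`: its minimum and mean (mmHg), the mean absolute first
#' difference per second (mmHg/s), and the fractions of segment time with
#' `d < 5` mmHg and `d < 10` mmHg. Damped or flushed arterial lines and
#' disconnections collapse the pulse amplitude, which these features target
#' directly.
#'
#' @param record A [monitoring_record()].
#' @param start_s,end_s Segment extent, half-open `[start_s, end_s)` seconds.
#' @param channels Channels to include (default both `"abp"` and `"icp"`).
#' @return A named numeric vector
#'   (`pulse_min_<ch>`, `pulse_mean_<ch>`, `pulse_deriv_<ch>`,
#'   `frac_below5_<ch>`, `frac_below10_<ch>` per channel). All values are
#'   `NA` if fewer than 50% of the segment's sys/dia samples are present in
#'   any requested channel.
#' @export
artifact_features <- function(record, start_s, end_s,
                              channels = c("abp", "icp")) {
  stopifnot(inherits(record, "monitoring_record"))
  idx <- segment_sample_index(record, start_s, end_s)
  out <- numeric(0)
  degraded <- FALSE
  for (ch in channels) {
    sys <- record[[paste0(ch, "_sys")]][idx]
    dia <- record[[paste0(ch, "_dia")]][idx]
    d <- sys - dia
    ok <- !is.na(d)
    if (mean(ok) < 0.5) degraded <- TRUE
    d_ok <- d[ok]
    dv <- abs(diff(d_ok)) / record$sample_period_s
    v <- c(pulse_min = if (length(d_ok)) min(d_ok) else NA_real_,
           pulse_mean = if (length(d_ok)) mean(d_ok) else NA_real_,
           pulse_deriv = if (length(dv)) mean(dv) else NA_real_,
           frac_below5 = mean(d_ok < 5),
           frac_below10 = mean(d_ok < 10))
    names(v) <- paste0(names(v), "_", ch)
    out <- c(out, v)
  }
  if (degraded) out[] <- NA_real_
  out
}

#' Informative-segment features (X2) for one segment
#'
#' Standard deviations of the mean ABP and ICP series after centered moving
#' averages of width 60, 120, 180 and 240 s (edges truncated), plus the
#' means of the raw series. Slow vasogenic B-waves survive these smoothing
#' filters while measurement noise does not, so segments with physiological
#' slow-wave activity show elevated filtered SDs.
#'
#' @inheritParams artifact_features
#' @param widths_s Moving-average widths, seconds.
#' @return A named numeric vector (`sd_abp_<w>`, `sd_icp_<w>`, `mean_abp`,
#'   `mean_icp`); all `NA` if fewer than 50% of either mean series is
#'   present.
#' @export
informative_features <- function(record, start_s, end_s,
                                 widths_s = c(60, 120, 180, 240)) {
  stopifnot(inherits(record, "monitoring_record"))
  idx <- segment_sample_index(record, start_s, end_s)
  abp <- record$abp_mean[idx]
  icp <- record$icp_mean[idx]
  if (mean(!is.na(abp)) < 0.5 || mean(!is.na(icp)) < 0.5) {
    out <- rep(NA_real_, 2 * length(widths_s) + 2)
    names(out) <- c(paste0("sd_abp_", widths_s), paste0("sd_icp_", widths_s),
                    "mean_abp", "mean_icp")
    return(out)
  }
  dt <- record$sample_period_s
  sds <- function(x) {
    vapply(widths_s, function(w) {
      stats::sd(moving_average(x, round(w / dt)), na.rm = TRUE)
    }, numeric(1))
  }
  out <- c(sds(abp), sds(icp), mean(abp, na.rm = TRUE), mean(icp, na.rm = TRUE))
  names(out) <- c(paste0("sd_abp_", widths_s), paste0("sd_icp_", widths_s),
                  "mean_abp", "mean_icp")
  out
}

# Centered moving average over exactly w samples (split h1/h2 around the
# center for even w) with truncated (shrinking) edge windows; NAs are
# ignored within each window.
moving_average <- function(x, w) {
  n <- length(x)
  h1 <- floor((w - 1) / 2)
  h2 <- w - 1 - h1
  xs <- ifelse(is.na(x), 0, x)
  cnt <- as.numeric(!is.na(x))
  cs <- c(0, cumsum(xs))
  cc <- c(0, cumsum(cnt))
  lo <- pmax(0, seq_len(n) - 1 - h1)
  hi <- pmin(n, seq_len(n) + h2)
  tot <- cs[hi + 1] - cs[lo + 1]
  m <- cc[hi + 1] - cc[lo + 1]
  out <- tot / m
  out[m == 0] <- NA_real_
  out
}

segment_sample_index <- function(record, start_s, end_s) {
  which(record$t >= start_s & record$t < end_s)
}

#' Feature matrix for a table of segments
#'
#' @param record A [monitoring_record()].
#' @param segments A data.frame with `start_s` and `end_s` columns (e.g.
#'   from [segment_table()]).
#' @param type `"artifact"` for the X1 features, `"informative"` for X2.
#' @param ... Passed to [artifact_features()] / [informative_features()].
#' @return A numeric matrix, one row per segment, named feature columns.
#' @export
segment_feature_matrix <- function(record, segments,
                                   type = c("artifact", "informative"), ...) {
  type <- match.arg(type)
  f <- if (type == "artifact") artifact_features else informative_features
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    f(record, segments$start_s[i], segments$end_s[i], ...)
  })
  do.call(rbind, rows)
}
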