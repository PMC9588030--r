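#' Parameters for PRx computation
#'
#' PRx is the moving Pearson correlation between slow ABP and ICP
#' variations: the mean series are first averaged into `avg_interval_s`
#' bins to isolate slow waves, then correlated over a moving window of
#' `corr_window_s` stepping by `step_s`.
#'
#' @param avg_interval_s Averaging interval, seconds (default 10).
#' @param corr_window_s Correlation window length, seconds (default 300,
#'   i.e. the 5-minute moving window); must be a multiple of
#'   `avg_interval_s` covering at least 3 intervals.
#' @param step_s Window step, seconds; multiple of `avg_interval_s`.
#' @param min_valid_fraction Minimum fraction of non-missing samples for an
#'   averaging bin to be valid (default 0.75).
#' @return A validated list of class `prx_params`.
#' @export
prx_params <- function(avg_interval_s = 10, corr_window_s = 300,
                       step_s = 10, min_valid_fraction = 0.75) {
  p <- structure(list(avg_interval_s = avg_interval_s,
                      corr_window_s = corr_window_s,
                      step_s = step_s,
                      min_valid_fraction = min_valid_fraction),
                 class = "prx_params")
  if (p$avg_interval_s <= 0) stop("avg_interval_s must be positive")
  if (abs(p$corr_window_s / p$avg_interval_s -
          round(p$corr_window_s / p$avg_interval_s)) > 1e-9)
    stop("corr_window_s must be an integer multiple of avg_interval_s")
  if (p$corr_window_s < 3 * p$avg_interval_s)
    stop("corr_window_s must cover at least 3 averaging intervals")
  if (abs(p$step_s / p$avg_interval_s - round(p$step_s / p$avg_interval_s)) > 1e-9)
    stop("step_s must be an integer multiple of avg_interval_s")
  if (p$min_valid_fraction <= 0 || p$min_valid_fraction > 1)
    stop("min_valid_fraction must be in (0, 1]")
  p
}

#' Cerebral perfusion pressure series
#'
#' `CPP = ABP - ICP`, elementwise on the mean series; `NA` propagates.
#'
#' @param record A [monitoring_record()].
#' @return Numeric mmHg series of the same length as the record.
#' @export
compute_cpp <- function(record) {
  stopifnot(inherits(record, "monitoring_record"))
  record$abp_mean - record$icp_mean
}

# Average x into consecutive bins of `k` samples; a bin is NA unless at
# least `min_frac` of its samples are non-missing.
bin_average <- function(x, k, min_frac) {
  n_bins <- floor(length(x) / k)
  if (n_bins == 0) return(numeric(0))
  m <- matrix(x[seq_len(n_bins * k)], nrow = k)
  means <- colMeans(m, na.rm = TRUE)
  valid <- colSums(!is.na(m)) >= min_frac * k
  means[!valid] <- NA_real_
  means[is.nan(means)] <- NA_real_
  means
}

#' Compute the PRx series
#'
#' Averages the mean ABP and ICP series into `avg_interval_s` bins, then for
#' each right-aligned half-open window `(t_end - corr_window_s, t_end]`
#' stepping by `step_s` computes the Pearson correlation of the binned pair.
#' A window's PRx is missing if any bin inside it is invalid or if either
#' bin series has zero variance (PRx near zero amplitude is exactly the
#' ambiguity the informative-segment classifier addresses, so it is not
#' fabricated from 0/0). Per-window means of CPP, ABP, and ICP are
#' co-registered.
#'
#' @param record A [monitoring_record()].
#' @param params A [prx_params()].
#' @return A `data.frame` of class `prx_series` with columns `t_end`, `prx`,
#'   `cpp_mean`, `abp_mean`, `icp_mean`.
#' @export
compute_prx <- function(record, params = prx_params()) {
  stopifnot(inherits(record, "monitoring_record"))
  if (!inherits(params, "prx_params")) stop("params must be a prx_params object")
  dt <- record$sample_period_s
  k <- round(params$avg_interval_s / dt)
  if (abs(k * dt - params$avg_interval_s) > 1e-9)
    stop("avg_interval_s must be an integer multiple of the sampling period")
  nb_win <- round(params$corr_window_s / params$avg_interval_s)
  nb_step <- round(params$step_s / params$avg_interval_s)

  abp_b <- bin_average(record$abp_mean, k, params$min_valid_fraction)
  icp_b <- bin_average(record$icp_mean, k, params$min_valid_fraction)
  m <- length(abp_b)
  empty <- data.frame(t_end = numeric(0), prx = numeric(0),
                      cpp_mean = numeric(0), abp_mean = numeric(0),
                      icp_mean = numeric(0))
  class(empty) <- c("prx_series", "data.frame")
  if (m < nb_win) {
    warning("record shorter than one correlation window; empty PRx series")
    return(empty)
  }
  ends <- seq(nb_win, m, by = nb_step)
  prx <- rep(NA_real_, length(ends))
  abp_w <- rep(NA_real_, length(ends))
  icp_w <- rep(NA_real_, length(ends))
  for (j in seq_along(ends)) {
    idx <- (ends[j] - nb_win + 1):ends[j]
    x <- abp_b[idx]; y <- icp_b[idx]
    if (anyNA(x) || anyNA(y)) next
    sx <- stats::sd(x); sy <- stats::sd(y)
    abp_w[j] <- mean(x); icp_w[j] <- mean(y)
    if (sx == 0 || sy == 0) next
    prx[j] <- stats::cor(x, y)
  }
  out <- data.frame(t_end = record$t[1] + ends * params$avg_interval_s,
                    prx = prx,
                    cpp_mean = abp_w - icp_w,
                    abp_mean = abp_w,
                    icp_mean = icp_w)
  class(out) <- c("prx_series", "data.frame")
  out
}
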