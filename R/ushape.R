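#' Bin PRx against a driver axis
#'
#' Groups PRx samples into fixed-width bins of the driver variable (CPP,
#' ABP, or ICP), aligned to multiples of the bin width; bins with fewer than
#' `min_count` PRx samples are dropped.
#'
#' @param prx_series A `prx_series` from [compute_prx()] (or any data.frame
#'   with `prx`, `cpp_mean`, `abp_mean`, `icp_mean`).
#' @param axis One of `"cpp"`, `"abp"`, `"icp"`.
#' @param bin_width Bin width, mmHg (default 5).
#' @param min_count Minimum PRx samples per retained bin (default 5).
#' @return A `data.frame` with `center`, `mean_prx`, `count`, carrying
#'   attributes `axis` and `fit_possible` (`FALSE` when fewer than 3 bins
#'   survive, in which case a fit is impossible -- signalled, not an error).
#' @export
bin_prx <- function(prx_series, axis = c("cpp", "abp", "icp"),
                    bin_width = 5, min_count = 5) {
  axis <- match.arg(axis)
  x <- prx_series[[paste0(axis, "_mean")]]
  y <- prx_series$prx
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0) {
    out <- data.frame(center = numeric(0), mean_prx = numeric(0),
                      count = integer(0))
    attr(out, "axis") <- axis
    attr(out, "fit_possible") <- FALSE
    return(out)
  }
  lo <- floor(x / bin_width) * bin_width  # bin [lo, lo + width)
  agg <- tapply(y, lo, mean)
  cnt <- tapply(y, lo, length)
  keep <- cnt >= min_count
  out <- data.frame(center = as.numeric(names(agg))[keep] + bin_width / 2,
                    mean_prx = as.numeric(agg)[keep],
                    count = as.integer(cnt)[keep])
  out <- out[order(out$center), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "axis") <- axis
  attr(out, "fit_possible") <- nrow(out) >= 3
  out
}

#' Fit the U-shaped quadratic to binned PRx
#'
#' Weighted least squares (weights = bin counts) of mean bin PRx on
#' `(x^2, x, 1)`. The optimum is the vertex `-b/(2a)`, reported only when
#' the parabola opens upward (`a > 0`) and the vertex lies within the
#' observed bin range (extrapolated optima are not reported). The lower and
#' upper autoregulation limits (LLCA/ULCA) are the real roots of
#' `a x^2 + b x + (c0 - threshold) = 0` that fall within the bin range,
#' assigned as the crossings below/above the vertex; the default threshold
#' +0.3 is the PRx level above which autoregulation is considered impaired.
#' For the ICP axis only the upper (ascending-branch) crossing is
#' meaningful: it is reported as `ulca` and no optimum is reported.
#'
#' @param bins Output of [bin_prx()].
#' @param threshold PRx threshold for the autoregulation limits (default 0.3).
#' @param axis Driver axis; defaults to the `axis` attribute of `bins`.
#' @param min_bins Minimum number of bins (default 3).
#' @param min_span_mmhg Minimum spanned range of bin centers (default 10).
#' @param min_r2 Minimum weighted R^2 for the fit to be declared valid
#'   (default 0; R^2 is otherwise used only comparatively).
#' @return An object of class `ushape_fit`: list with `axis`, `a`, `b`,
#'   `c0`, `r_squared`, `opt_value`, `llca`, `ulca` (each `NA` when absent),
#'   `valid`, `fit_possible`, `threshold`, `n_bins`, `bins`.
#' @export
fit_ushape <- function(bins, threshold = 0.3, axis = attr(bins, "axis"),
                       min_bins = 3, min_span_mmhg = 10, min_r2 = 0) {
  if (is.null(axis)) axis <- "cpp"
  empty <- structure(list(axis = axis, a = NA_real_, b = NA_real_,
                          c0 = NA_real_, r_squared = NA_real_,
                          opt_value = NA_real_, llca = NA_real_,
                          ulca = NA_real_, valid = FALSE,
                          fit_possible = FALSE, threshold = threshold,
                          n_bins = nrow(bins), bins = bins),
                     class = "ushape_fit")
  if (nrow(bins) < min_bins) return(empty)
  span <- max(bins$center) - min(bins$center)
  if (span < min_span_mmhg) return(empty)

  x <- bins$center; y <- bins$mean_prx; w <- bins$count
  fit <- stats::lm(y ~ x + I(x^2), weights = w)
  cf <- stats::coef(fit)
  c0 <- unname(cf[1]); b <- unname(cf[2]); a <- unname(cf[3])
  if (anyNA(c(a, b, c0))) return(empty)
  yhat <- c0 + b * x + a * x^2
  wmean <- sum(w * y) / sum(w)
  ss_tot <- sum(w * (y - wmean)^2)
  ss_res <- sum(w * (y - yhat)^2)
  r2 <- if (ss_tot <= 0) 0 else max(0, min(1, 1 - ss_res / ss_tot))

  opt <- NA_real_; llca <- NA_real_; ulca <- NA_real_
  valid <- a > 0 && r2 >= min_r2
  if (a > 0) {
    vertex <- -b / (2 * a)
    in_range <- vertex >= min(x) && vertex <= max(x)
    if (axis != "icp" && in_range) opt <- vertex
    disc <- b^2 - 4 * a * (c0 - threshold)
    if (disc > 0) {
      r_lo <- (-b - sqrt(disc)) / (2 * a)
      r_hi <- (-b + sqrt(disc)) / (2 * a)
      if (axis == "icp") {
        if (r_hi >= min(x) && r_hi <= max(x)) ulca <- r_hi
      } else {
        if (r_lo >= min(x) && r_lo <= max(x)) llca <- r_lo
        if (r_hi >= min(x) && r_hi <= max(x)) ulca <- r_hi
      }
    }
  }
  structure(list(axis = axis, a = a, b = b, c0 = c0, r_squared = r2,
                 opt_value = opt, llca = llca, ulca = ulca,
                 valid = valid, fit_possible = TRUE, threshold = threshold,
                 n_bins = nrow(bins), bins = bins),
            class = "ushape_fit")
}

#' @export
print.ushape_fit <- function(x, ...) {
  cat(sprintf("U-shape fit, axis %s: ", toupper(x$axis)))
  if (!x$fit_possible) {
    cat("fit impossible (too few bins or span)\n")
    return(invisible(x))
  }
  cat(sprintf("PRx = %.4g x^2 + %.4g x + %.4g (R2 = %.3f, %d bins)\n",
              x$a, x$b, x$c0, x$r_squared, x$n_bins))
  fmt <- function(v) if (is.na(v)) "ND" else sprintf("%.1f mmHg", v)
  cat(sprintf("  opt = %s, LLCA = %s, ULCA = %s, valid = %s\n",
              fmt(x$opt_value), fmt(x$llca), fmt(x$ulca), x$valid))
  invisible(x)
}

#' Greedy R^2-driven segment inclusion and fit for one window
#'
#' The base set is the window's artifact-free *and* informative segments;
#' the U-shape is fitted on their PRx samples. Remaining artifact-free (but
#' noninformative) segments are then considered once each, in chronological
#' order, and permanently added if and only if refitting with the candidate
#' strictly increases R^2 and the fit remains valid. Artifact-distorted
#' segments never enter the calculation.
#'
#' @param segments A 5-row data.frame for one window with `segment_index`,
#'   `start_s`, `end_s`, `artifact_label`, `informative_label` (reference
#'   annotations or classifier predictions).
#' @param prx_series The window's PRx samples (a `prx_series`).
#' @param axis Driver axis: `"cpp"`, `"abp"`, or `"icp"`.
#' @param window_start_s Window start time (defaults to the smallest
#'   segment start).
#' @param bin_width,min_count,threshold,min_r2 Passed to [bin_prx()] /
#'   [fit_ushape()].
#' @return A list with `chosen` (integer segment indices used) and `fit`
#'   (a `ushape_fit`; `fit_possible = FALSE` with empty `chosen` when the
#'   window has no artifact-free informative segment).
#' @export
select_segments <- function(segments, prx_series, axis = "cpp",
                            window_start_s = min(segments$start_s),
                            bin_width = 5, min_count = 5, threshold = 0.3,
                            min_r2 = 0) {
  seg_len <- segments$end_s[1] - segments$start_s[1]
  seg_of <- prx_segment_index(prx_series$t_end, window_start_s, seg_len)
  in_window <- seg_of >= 0 & seg_of < nrow(segments)

  fit_for <- function(chosen_idx) {
    keep <- in_window & seg_of %in% chosen_idx
    bins <- bin_prx(prx_series[keep, , drop = FALSE], axis = axis,
                    bin_width = bin_width, min_count = min_count)
    fit_ushape(bins, threshold = threshold, axis = axis, min_r2 = min_r2)
  }

  clean <- segments$artifact_label == "artifact_free"
  base_idx <- segments$segment_index[clean & segments$informative_label == "informative"]
  if (length(base_idx) == 0) {
    empty_bins <- bin_prx(prx_series[0, , drop = FALSE], axis = axis)
    return(list(chosen = integer(0),
                fit = fit_ushape(empty_bins, threshold = threshold, axis = axis)))
  }
  chosen <- sort(base_idx)
  fit <- fit_for(chosen)
  base_r2 <- if (fit$fit_possible) fit$r_squared else -Inf

  candidates <- sort(segments$segment_index[clean & segments$informative_label != "informative"])
  cur_r2 <- base_r2
  for (s in candidates) {
    trial <- fit_for(sort(c(chosen, s)))
    if (trial$fit_possible && trial$valid && trial$r_squared > cur_r2) {
      chosen <- sort(c(chosen, s))
      fit <- trial
      cur_r2 <- trial$r_squared
    }
  }
  list(chosen = chosen, fit = fit)
}
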