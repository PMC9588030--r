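# Independent oracles used to verify the package implementations.
# These deliberately re-derive every quantity from first principles
# (explicit sums, normal equations, exhaustive evaluation) and share no
# code with the implementation under test.

# Pearson correlation from the definition, explicit sums
brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# PRx by nested loops: bin-average then correlate each window
brute_prx <- function(record, avg_s = 10, win_s = 300, step_s = 10,
                      min_frac = 0.75) {
  k <- round(avg_s / record$sample_period_s)
  nb <- floor(length(record$t) / k)
  abp_b <- icp_b <- rep(NA_real_, nb)
  for (j in seq_len(nb)) {
    idx <- ((j - 1) * k + 1):(j * k)
    a <- record$abp_mean[idx]; i <- record$icp_mean[idx]
    if (sum(!is.na(a)) >= min_frac * k) abp_b[j] <- mean(a, na.rm = TRUE)
    if (sum(!is.na(i)) >= min_frac * k) icp_b[j] <- mean(i, na.rm = TRUE)
  }
  nw <- round(win_s / avg_s)
  ns <- round(step_s / avg_s)
  ends <- seq(nw, nb, by = ns)
  prx <- rep(NA_real_, length(ends))
  for (w in seq_along(ends)) {
    idx <- (ends[w] - nw + 1):ends[w]
    x <- abp_b[idx]; y <- icp_b[idx]
    if (anyNA(x) || anyNA(y)) next
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    prx[w] <- brute_pearson(x, y)
  }
  list(t_end = ends * avg_s, prx = prx)
}

# weighted quadratic least squares via the normal equations
brute_quadfit <- function(x, y, w) {
  X <- cbind(1, x, x^2)
  A <- t(X) %*% (w * X)
  b <- t(X) %*% (w * y)
  cf <- solve(A, b)
  yhat <- X %*% cf
  wm <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * (y - yhat)^2) / sum(w * (y - wm)^2)
  list(c0 = cf[1], b = cf[2], a = cf[3], r2 = r2)
}

# binning by explicit comparison against bin edges
brute_bins <- function(x, y, width = 5, min_count = 5) {
  lo_all <- floor(min(x) / width) * width
  hi_all <- floor(max(x) / width) * width
  edges <- seq(lo_all, hi_all, by = width)
  out <- data.frame(center = numeric(0), mean_prx = numeric(0), count = integer(0))
  for (e in edges) {
    sel <- x >= e & x < e + width
    if (sum(sel) >= min_count)
      out <- rbind(out, data.frame(center = e + width / 2,
                                   mean_prx = mean(y[sel]),
                                   count = sum(sel)))
  }
  out
}

# trapezoidal AUC by explicit ROC construction (independent of the
# rank-based implementation)
brute_auc <- function(y, s) {
  ths <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  tpr <- fpr <- numeric(length(ths))
  P <- sum(y == 1); N <- sum(y == 0)
  for (i in seq_along(ths)) {
    tpr[i] <- sum(s >= ths[i] & y == 1) / P
    fpr[i] <- sum(s >= ths[i] & y == 0) / N
  }
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# a plain constant-signal record with optional overrides
toy_record <- function(n = 600, abp = 90, icp = 12, pulse_abp = 40,
                       pulse_icp = 8, abp_mean = NULL, icp_mean = NULL) {
  am <- if (is.null(abp_mean)) rep(abp, n) else abp_mean
  im <- if (is.null(icp_mean)) rep(icp, n) else icp_mean
  monitoring_record(
    patient_id = "toy", t = 0:(n - 1), sample_period_s = 1,
    abp_mean = am, abp_sys = am + pulse_abp / 2, abp_dia = am - pulse_abp / 2,
    icp_mean = im, icp_sys = im + pulse_icp / 2, icp_dia = im - pulse_icp / 2)
}

# synthetic prx_series whose 5-mmHg bin means lie exactly on a parabola
parabola_prx_series <- function(a = 0.002, x0 = 80, c0 = -0.2,
                                centers = seq(62.5, 97.5, by = 5),
                                per_bin = 6) {
  cpp <- rep(centers, each = per_bin)
  df <- data.frame(t_end = seq(300, by = 10, length.out = length(cpp)),
                   prx = a * (cpp - x0)^2 + c0,
                   cpp_mean = cpp, abp_mean = cpp + 10, icp_mean = 10)
  class(df) <- c("prx_series", "data.frame")
  df
}
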