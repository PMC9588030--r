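test_that("binning follows the fixed-edge convention and counting", {
  ps <- parabola_prx_series(centers = c(62, 68), per_bin = 6)
  ps$cpp_mean <- rep(c(62, 68), each = 6)
  b <- bin_prx(ps, "cpp")
  expect_equal(b$center, c(62.5, 67.5))  # bins [60,65) and [65,70)
  expect_equal(b$count, c(6L, 6L))
  # single surviving bin: fit impossible, flagged, not an exception
  one <- parabola_prx_series(centers = 62.5, per_bin = 10)
  bo <- bin_prx(one, "cpp")
  expect_false(attr(bo, "fit_possible"))
  expect_false(fit_ushape(bo)$fit_possible)
  # counting oracle on random series
  set.seed(5)
  rs <- data.frame(t_end = seq(300, by = 10, length.out = 400),
                   prx = runif(400, -1, 1), cpp_mean = runif(400, 50, 110))
  rs$abp_mean <- rs$cpp_mean + 10; rs$icp_mean <- 10
  bb <- bin_prx(rs, "cpp", min_count = 5)
  oracle <- brute_bins(rs$cpp_mean, rs$prx)
  expect_equal(bb$center, oracle$center)
  expect_equal(bb$count, oracle$count)
  expect_equal(bb$mean_prx, oracle$mean_prx, tolerance = 1e-12)
  expect_lte(sum(bb$count), 400)
})

test_that("a noiseless parabola is fitted exactly with closed-form limits", {
  ps <- parabola_prx_series(a = 0.002, x0 = 80, c0 = -0.2,
                            centers = seq(62.5, 97.5, 5))
  fit <- fit_ushape(bin_prx(ps, "cpp"))
  expect_equal(fit$a, 0.002, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$opt_value, 80, tolerance = 1e-6)
  expect_equal(fit$llca, 80 - sqrt(250), tolerance = 1e-9)
  expect_equal(fit$ulca, 80 + sqrt(250), tolerance = 1e-9)
  expect_lt(fit$llca, fit$opt_value); expect_gt(fit$ulca, fit$opt_value)
  # symmetric input: limits symmetric about the vertex
  expect_equal(fit$opt_value - fit$llca, fit$ulca - fit$opt_value,
               tolerance = 1e-9)
})

test_that("a curve that never dips under the threshold has no crossings", {
  ps <- parabola_prx_series(a = 0.002, x0 = 80, c0 = 0.4)
  fit <- fit_ushape(bin_prx(ps, "cpp"))
  expect_equal(fit$opt_value, 80, tolerance = 1e-6)
  expect_true(is.na(fit$llca))
  expect_true(is.na(fit$ulca))
})

test_that("downward-opening and out-of-range fits are recorded invalid", {
  ps <- parabola_prx_series(a = 0.002, x0 = 80, c0 = -0.2)
  ps$prx <- -ps$prx  # opens downward
  fit <- fit_ushape(bin_prx(ps, "cpp"))
  expect_false(fit$valid)
  expect_true(is.na(fit$opt_value))
  expect_true(is.na(fit$llca) && is.na(fit$ulca))
  # vertex outside the observed bins: no extrapolated optimum
  ps2 <- parabola_prx_series(a = 0.002, x0 = 80, c0 = -0.2,
                             centers = seq(87.5, 107.5, 5))
  fit2 <- fit_ushape(bin_prx(ps2, "cpp"))
  expect_true(is.na(fit2$opt_value))
  expect_false(is.na(fit2$ulca))  # the upper crossing is inside the range
})

test_that("ICP-axis fits report only the upper crossing and no optimum", {
  ps <- parabola_prx_series(a = 0.01, x0 = 20, c0 = -0.2,
                            centers = seq(12.5, 32.5, 5))
  ps$icp_mean <- ps$cpp_mean
  fit <- fit_ushape(bin_prx(ps, "icp"), axis = "icp")
  expect_true(is.na(fit$opt_value))
  expect_true(is.na(fit$llca))
  expect_equal(fit$ulca, 20 + sqrt(50), tolerance = 1e-9)
})

test_that("weighted fit agrees with the normal equations on random bins", {
  set.seed(77)
  for (i in 1:20) {
    nb <- sample(4:12, 1)
    centers <- 50 + 5 * seq_len(nb)
    bins <- data.frame(center = centers,
                       mean_prx = runif(nb, -0.8, 0.8),
                       count = sample(5:50, nb, replace = TRUE))
    attr(bins, "axis") <- "cpp"
    fit <- fit_ushape(bins)
    o <- brute_quadfit(bins$center, bins$mean_prx, bins$count)
    expect_equal(fit$a, unname(o$a), tolerance = 1e-10)
    expect_equal(fit$b, unname(o$b), tolerance = 1e-10)
    expect_equal(fit$c0, unname(o$c0), tolerance = 1e-10)
    expect_equal(fit$r_squared, max(0, min(1, o$r2)), tolerance = 1e-10)
  }
})

test_that("noisy simulated data recovers the ground-truth optimum", {
  sim <- simulate_monitoring(simulation_config(duration_s = 21600, seed = 29))
  fit <- fit_ushape(bin_prx(compute_prx(sim$record), "cpp"))
  expect_lt(abs(fit$opt_value - 80), 5)
})

# build a window's prx series from per-segment generators
window_prx <- function(seg_cpp, seg_prx, start = 0) {
  n_per <- length(seg_cpp[[1]])
  rows <- lapply(seq_along(seg_cpp), function(s) {
    data.frame(t_end = start + (s - 1) * 1440 + seq(10, by = 10, length.out = n_per),
               prx = seg_prx[[s]], cpp_mean = seg_cpp[[s]])
  })
  df <- do.call(rbind, rows)
  df$abp_mean <- df$cpp_mean + 10; df$icp_mean <- 10
  df
}

test_that("greedy inclusion only ever improves on the base fit", {
  set.seed(91)
  segs <- split_window(0)
  for (rep in 1:40) {
    labels <- data.frame(
      segs,
      artifact_label = sample(c("artifact_free", "artifact_distorted"), 5, TRUE,
                              prob = c(0.8, 0.2)),
      informative_label = sample(c("informative", "noninformative"), 5, TRUE))
    labels$artifact_label[1] <- "artifact_free"
    labels$informative_label[1] <- "informative"
    seg_cpp <- lapply(1:5, function(s) runif(60, 55, 105))
    seg_prx <- lapply(1:5, function(s)
      0.002 * (seg_cpp[[s]] - 80)^2 - 0.2 + rnorm(60, 0, 0.2))
    prx <- window_prx(seg_cpp, seg_prx)
    res <- select_segments(labels, prx, "cpp")
    base_idx <- labels$segment_index[labels$artifact_label == "artifact_free" &
                                       labels$informative_label == "informative"]
    keep <- floor((prx$t_end - 1e-9) / 1440) %in% base_idx
    base_fit <- fit_ushape(bin_prx(prx[keep, ], "cpp"))
    expect_true(all(base_idx %in% res$chosen))
    if (base_fit$fit_possible && res$fit$fit_possible)
      expect_gte(res$fit$r_squared, base_fit$r_squared - 1e-12)
    # artifact-distorted segments never enter
    expect_false(any(res$chosen %in%
                       labels$segment_index[labels$artifact_label ==
                                              "artifact_distorted"]))
  }
})

test_that("a pure-noise noninformative segment is excluded by the r2 rule", {
  set.seed(19)
  segs <- split_window(0)
  labels <- data.frame(segs,
                       artifact_label = rep("artifact_free", 5),
                       informative_label = c("informative", "informative",
                                             "informative", "informative",
                                             "noninformative"))
  seg_cpp <- lapply(1:4, function(s) runif(80, 55, 105))
  seg_prx <- lapply(1:4, function(s)
    0.002 * (seg_cpp[[s]] - 80)^2 - 0.2 + rnorm(80, 0, 0.05))
  # the noninformative segment carries uncorrelated noise over a narrow range
  seg_cpp[[5]] <- runif(80, 70, 90)
  seg_prx[[5]] <- runif(80, -1, 1)
  prx <- window_prx(seg_cpp, seg_prx)
  res <- select_segments(labels, prx, "cpp")
  expect_equal(res$chosen, 0:3)
})

test_that("greedy decisions match an independent exhaustive oracle", {
  set.seed(47)
  segs <- split_window(0)
  for (rep in 1:25) {
    labels <- data.frame(segs,
                         artifact_label = rep("artifact_free", 5),
                         informative_label = sample(c("informative", "noninformative"),
                                                    5, TRUE, prob = c(0.5, 0.5)))
    labels$informative_label[sample(5, 1)] <- "informative"
    seg_cpp <- lapply(1:5, function(s) runif(50, 55, 105))
    seg_prx <- lapply(1:5, function(s)
      0.002 * (seg_cpp[[s]] - 80)^2 - 0.2 + rnorm(50, 0, runif(1, 0.05, 0.5)))
    prx <- window_prx(seg_cpp, seg_prx)
    res <- select_segments(labels, prx, "cpp")

    # oracle: independent greedy pass using brute binning + normal equations
    oracle_r2 <- function(chosen) {
      keep <- floor((prx$t_end - 1e-9) / 1440) %in% chosen
      x <- prx$cpp_mean[keep]; y <- prx$prx[keep]
      b <- brute_bins(x, y)
      if (nrow(b) < 3 || max(b$center) - min(b$center) < 10) return(NULL)
      f <- brute_quadfit(b$center, b$mean_prx, b$count)
      list(r2 = max(0, min(1, f$r2)), a = f$a)
    }
    base <- sort(labels$segment_index[labels$informative_label == "informative"])
    chosen <- base
    cur <- oracle_r2(chosen)
    cur_r2 <- if (is.null(cur)) -Inf else cur$r2
    for (s in sort(setdiff(0:4, base))) {
      trial <- oracle_r2(sort(c(chosen, s)))
      if (!is.null(trial) && trial$a > 0 && trial$r2 > cur_r2) {
        chosen <- sort(c(chosen, s)); cur_r2 <- trial$r2
      }
    }
    expect_equal(res$chosen, chosen)
    if (is.finite(cur_r2) && res$fit$fit_possible)
      expect_equal(res$fit$r_squared, cur_r2, tolerance = 1e-10)
  }
})
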