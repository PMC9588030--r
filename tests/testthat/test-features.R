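test_that("pulse-amplitude features behave on degenerate segments", {
  # sys == dia: zero pulse everywhere
  rec <- toy_record(n = 1440, pulse_abp = 0, pulse_icp = 0)
  f <- artifact_features(rec, 0, 1440)
  expect_equal(unname(f["pulse_mean_abp"]), 0)
  expect_equal(unname(f["frac_below5_abp"]), 1)
  expect_equal(unname(f["frac_below10_abp"]), 1)
  # constant d = 40: no derivative, nothing below the thresholds
  rec2 <- toy_record(n = 1440, pulse_abp = 40)
  f2 <- artifact_features(rec2, 0, 1440)
  expect_equal(unname(f2["pulse_deriv_abp"]), 0)
  expect_equal(unname(f2[c("frac_below5_abp", "frac_below10_abp")]), c(0, 0))
  expect_lte(f2["pulse_min_abp"], f2["pulse_mean_abp"])
})

test_that("damped-pulse artifact segments show elevated frac_below5", {
  cfg <- simulation_config(duration_s = 43200, seed = 17, artifact_rate_per_h = 1,
                           artifact_kinds = "damped_pulse")
  sim <- simulate_monitoring(cfg)
  segs <- data.frame(start_s = seq(0, 43200 - 1440, by = 1440))
  segs$end_s <- segs$start_s + 1440
  labs <- truth_segment_labels(sim$truth, segs)
  X <- segment_feature_matrix(sim$record, segs, type = "artifact")
  art <- labs$artifact_label == "artifact_distorted"
  expect_gt(sum(art), 2)
  # oracle: direct counting on the simulator's artifact mask
  for (i in which(art)[1:3]) {
    idx <- (segs$start_s[i] + 1):segs$end_s[i]
    frac_true <- mean((sim$record$abp_sys - sim$record$abp_dia)[idx] < 5)
    expect_equal(unname(X[i, "frac_below5_abp"]), frac_true, tolerance = 1e-12)
  }
  expect_gt(min(X[art, "frac_below5_abp"]), max(X[!art, "frac_below5_abp"]))
})

test_that("moving-average SD features vanish for constants and full-period sines", {
  rec <- toy_record(n = 1440)
  f <- informative_features(rec, 0, 1440)
  expect_equal(unname(f[1:8]), rep(0, 8))
  expect_equal(unname(f["mean_abp"]), 90)
  expect_equal(unname(f["mean_icp"]), 12)
  # 60-s sinusoid is annihilated by the 60-s filter but not by the raw SD
  wav <- 4 * sin(2 * pi * (0:1439) / 60)
  rec2 <- toy_record(n = 1440, abp_mean = 90 + wav)
  f2 <- informative_features(rec2, 0, 1440)
  # interior windows cancel exactly; only truncated edge windows leak
  expect_lt(unname(f2["sd_abp_60"]), 0.15 * sd(rec2$abp_mean))
  expect_gt(sd(rec2$abp_mean), 2)
})

test_that("B-wave segments show larger filtered-SD than flat segments", {
  cfg <- simulation_config(duration_s = 43200, seed = 19, artifact_rate_per_h = 0,
                           bwave_on_fraction = 0.5,
                           abp_drift = data.frame(t_s = c(0, 43200),
                                                  offset_mmhg = c(0, 0)))
  sim <- simulate_monitoring(cfg)
  segs <- data.frame(start_s = seq(0, 43200 - 1440, by = 1440))
  segs$end_s <- segs$start_s + 1440
  labs <- truth_segment_labels(sim$truth, segs)
  X <- segment_feature_matrix(sim$record, segs, type = "informative")
  on <- labs$informative_label == "informative"
  expect_gt(sum(on), 3); expect_gt(sum(!on), 3)
  expect_gt(mean(X[on, "sd_icp_60"]), 2 * mean(X[!on, "sd_icp_60"]))
  expect_gt(mean(X[on, "sd_abp_60"]), mean(X[!on, "sd_abp_60"]))
})

test_that("features scale with the channels and are finite and order-stable", {
  sim <- simulate_monitoring(simulation_config(duration_s = 14400, seed = 23,
                                               artifact_rate_per_h = 0.5))
  rec <- sim$record
  segs <- segment_table(rec)[1:5, ]
  X1 <- segment_feature_matrix(rec, segs, type = "artifact")
  X2 <- segment_feature_matrix(rec, segs, type = "informative")
  expect_true(all(is.finite(X1)))
  expect_true(all(is.finite(X2)))
  # permutation invariance per segment
  X1p <- segment_feature_matrix(rec, segs[5:1, ], type = "artifact")
  expect_equal(X1p, X1[5:1, ])
  # scaling both channels by k scales mmHg features by k, fractions unchanged
  k <- 2
  rec2 <- rec
  for (s in c("abp_mean", "abp_sys", "abp_dia", "icp_mean", "icp_sys", "icp_dia"))
    rec2[[s]] <- rec[[s]] * k
  Y1 <- segment_feature_matrix(rec2, segs, type = "artifact")
  mm <- grepl("pulse", colnames(Y1))
  expect_equal(Y1[, mm], k * X1[, mm], tolerance = 1e-12)
  # fractions compare d to fixed 5/10 mmHg thresholds; the clean ABP pulse
  # (d = 40) stays above both thresholds under doubling
  fr_abp <- grepl("frac", colnames(Y1)) & grepl("abp", colnames(Y1))
  expect_equal(Y1[, fr_abp], X1[, fr_abp], tolerance = 1e-12)
  Y2 <- segment_feature_matrix(rec2, segs, type = "informative")
  sd_cols <- grepl("^sd_", colnames(Y2))
  expect_equal(Y2[, sd_cols], k * X2[, sd_cols], tolerance = 1e-10)
})

test_that("segments with too many missing samples get flagged feature vectors", {
  rec <- toy_record(n = 1440)
  rec$abp_sys[1:800] <- NA
  expect_true(all(is.na(artifact_features(rec, 0, 1440))))
  rec$abp_mean[1:800] <- NA
  expect_true(all(is.na(informative_features(rec, 0, 1440))))
})
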