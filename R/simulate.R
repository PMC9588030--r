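#' Configuration for the synthetic monitoring simulator
#'
#' Builds the parameter set for [simulate_monitoring()]. The simulator
#' emulates the features of multimodal neuromonitoring that the analysis
#' pipeline consumes: a slowly drifting ABP baseline that sweeps cerebral
#' perfusion pressure (CPP) across the autoregulation curve, intermittent
#' slow vasogenic B-waves (0.5--2 cycles/min) present only in "informative"
#' segments, an autoregulation-state-dependent ABP-to-ICP coupling that
#' realizes a known ground-truth PRx(CPP) parabola, pulse components
#' (systolic/diastolic around the mean), and injected artifact episodes
#' (damped pulse amplitude or signal dropout).
#'
#' The ground-truth curve is
#' `rho(CPP) = clip(a_true * (CPP - x_opt_true)^2 + c_true, -0.99, 0.99)`,
#' so the true optimum is `x_opt_true` and the true lower/upper
#' autoregulation limits are `x_opt_true -/+ sqrt((0.3 - c_true)/a_true)`
#' (defined only when `c_true < 0.3`).
#'
#' @param duration_s Total record duration in seconds (>= 7200).
#' @param seed Integer seed; fixes the full simulator output.
#' @param abp_baseline Mean ABP baseline, mmHg.
#' @param icp_baseline Mean ICP baseline, mmHg.
#' @param abp_drift `data.frame(t_s, offset_mmhg)` piecewise-linear
#'   breakpoints added to the ABP baseline, used to sweep CPP over a chosen
#'   range. Default: a triangular sweep of +/- 25 mmHg with a 4-hour period
#'   (so every 2-hour window sees a wide CPP span, CPP covering 55--105 mmHg
#'   with the default baselines).
#' @param bwave_amp B-wave amplitude, mmHg (in "on" segments).
#' @param bwave_period_range_s Range the per-segment B-wave period is drawn
#'   from, seconds (default 30--120 s, i.e. 0.5--2 cycles/min).
#' @param bwave_on_fraction Probability that a 24-min segment carries
#'   B-waves; such segments are the ground-truth "informative" ones.
#' @param slow_noise_sd SD of the always-present slow (10-s lattice) ABP
#'   fluctuation, mmHg.
#' @param noise_sd SD of the 1 Hz white measurement noise on mean ABP, mmHg.
#' @param noise_sd_icp SD of the 1 Hz white measurement noise on mean ICP, mmHg.
#' @param pulse_amp_abp,pulse_amp_icp Pulse amplitudes (systolic minus
#'   diastolic), mmHg.
#' @param a_true,x_opt_true,c_true Ground-truth parabola parameters
#'   (curvature per mmHg^-2, vertex mmHg, vertex PRx). Require `a_true > 0`
#'   and `c_true` in `[-1, 0.3)`.
#' @param icp_slow_sd SD of the ICP slow-wave component in informative
#'   segments, mmHg.
#' @param artifact_rate_per_h Expected number of artifact episodes per hour.
#' @param artifact_duration_range_s Range artifact durations are drawn from.
#' @param artifact_kinds Subset of `c("damped_pulse", "dropout")`; each
#'   episode's kind is drawn uniformly from this set.
#' @param sample_period_s Sampling period of the output record, seconds.
#'
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(duration_s = 172800, seed = 1L,
                              abp_baseline = 90, icp_baseline = 10,
                              abp_drift = NULL,
                              bwave_amp = 3, bwave_period_range_s = c(30, 120),
                              bwave_on_fraction = 0.75,
                              slow_noise_sd = 0.5, noise_sd = 1.5,
                              noise_sd_icp = 0.3,
                              pulse_amp_abp = 40, pulse_amp_icp = 8,
                              a_true = 0.002, x_opt_true = 80, c_true = -0.2,
                              icp_slow_sd = 2,
                              artifact_rate_per_h = 0.15,
                              artifact_duration_range_s = c(60, 300),
                              artifact_kinds = c("damped_pulse", "dropout"),
                              sample_period_s = 1) {
  if (is.null(abp_drift)) {
    # triangular CPP sweep, 4-h period, +/- 25 mmHg
    half <- 7200
    tb <- seq(0, duration_s + 2 * half, by = half)
    off <- rep(c(-25, 25), length.out = length(tb))
    abp_drift <- data.frame(t_s = tb, offset_mmhg = off)
  }
  cfg <- structure(list(
    duration_s = duration_s, seed = as.integer(seed),
    abp_baseline = abp_baseline, icp_baseline = icp_baseline,
    abp_drift = abp_drift,
    bwave_amp = bwave_amp, bwave_period_range_s = bwave_period_range_s,
    bwave_on_fraction = bwave_on_fraction,
    slow_noise_sd = slow_noise_sd, noise_sd = noise_sd,
    noise_sd_icp = noise_sd_icp,
    pulse_amp_abp = pulse_amp_abp, pulse_amp_icp = pulse_amp_icp,
    a_true = a_true, x_opt_true = x_opt_true, c_true = c_true,
    icp_slow_sd = icp_slow_sd,
    artifact_rate_per_h = artifact_rate_per_h,
    artifact_duration_range_s = artifact_duration_range_s,
    artifact_kinds = artifact_kinds,
    sample_period_s = sample_period_s), class = "simulation_config")
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$duration_s < 7200) stop("duration_s must be >= 7200 (one 2-h window)")
  if (cfg$a_true <= 0) stop("a_true must be > 0 (upward-opening parabola)")
  if (cfg$c_true < -1 || cfg$c_true >= 0.3)
    stop("c_true must lie in [-1, 0.3): with c_true >= 0.3 the ground-truth ",
         "autoregulation limits (crossings of PRx = 0.3) are undefined")
  if (cfg$bwave_on_fraction < 0 || cfg$bwave_on_fraction > 1)
    stop("bwave_on_fraction must be in [0, 1]")
  if (!all(cfg$artifact_kinds %in% c("damped_pulse", "dropout")))
    stop("artifact_kinds must be a subset of c('damped_pulse', 'dropout')")
  stopifnot(all(c("t_s", "offset_mmhg") %in% names(cfg$abp_drift)))
  cfg
}

#' Ground-truth PRx expectation at a given CPP
#'
#' Evaluates the simulator's autoregulation curve
#' `clip(a_true * (cpp - x_opt_true)^2 + c_true, -0.99, 0.99)`.
#'
#' @param cpp CPP value(s), mmHg.
#' @param config A [simulation_config()].
#' @return Dimensionless expected PRx, same length as `cpp`.
#' @export
truth_prx_expectation <- function(cpp, config) {
  validate_simulation_config(config)
  rho <- config$a_true * (cpp - config$x_opt_true)^2 + config$c_true
  pmin(pmax(rho, -0.99), 0.99)
}

# Run expr with a private RNG stream seeded from `seed`, restoring the
# caller's RNG state afterwards.
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a multimodal monitoring record with known ground truth
#'
#' Generates a [monitoring_record()] according to a [simulation_config()]
#' together with the ground truth needed to test every downstream stage.
#'
#' Construction (deterministic given `config$seed`):
#' * The slow ABP component lives on a 10-s lattice: a per-segment sinusoidal
#'   B-wave (period drawn from `bwave_period_range_s`, random phase), present
#'   only in segments drawn "informative", plus an always-present lattice
#'   fluctuation of SD `slow_noise_sd`. It is held piecewise-constant at 1 Hz
#'   so that 10-s re-averaging (the first PRx step) recovers the lattice
#'   exactly.
#' * The ICP slow component is built by correlation injection:
#'   `icp_slow = s_icp * (rho * z_abp + sqrt(1 - rho^2) * eps)` where `z_abp`
#'   is the ABP slow lattice normalized by its process SD, `eps` is unit
#'   white noise on the lattice, `rho = rho(CPP)` is the ground-truth curve
#'   evaluated at the drift-level CPP, and `s_icp` is `icp_slow_sd` in
#'   informative segments, scaled down in proportion to the slow-wave
#'   amplitude otherwise. The moving Pearson correlation of 10-s means then
#'   has expectation `rho(CPP)` (up to mild attenuation by measurement noise).
#' * `sys`/`dia` are `mean +/- pulse_amp/2`. Artifact episodes arrive as a
#'   Poisson process on the ABP channel: `damped_pulse` decays the pulse
#'   amplitude exponentially to a 2 mmHg floor; `dropout` freezes all three
#'   ABP values at the episode-start mean.
#'
#' @param config A [simulation_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{record}{the simulated [monitoring_record()]}
#'     \item{truth}{a list of class `ground_truth`: per-sample logical
#'       `artifact`, per-segment logical `informative_segment` with
#'       `segment_start_s`, and `x_opt_true`, `llca_true`, `ulca_true`}
#'   }
#' @export
simulate_monitoring <- function(config) {
  cfg <- validate_simulation_config(config)
  with_private_seed(cfg$seed, {
    dt <- cfg$sample_period_s
    n <- floor(cfg$duration_s / dt)
    t <- (seq_len(n) - 1) * dt

    seg_len <- 1440
    n_seg <- ceiling(cfg$duration_s / seg_len)
    seg_start <- (seq_len(n_seg) - 1) * seg_len
    informative <- stats::runif(n_seg) < cfg$bwave_on_fraction
    if (cfg$bwave_amp <= 0) informative[] <- FALSE

    # 10-s slow-wave lattice
    lat_step <- 10
    n_lat <- ceiling(cfg$duration_s / lat_step)
    t_lat <- (seq_len(n_lat) - 1) * lat_step
    seg_of_lat <- pmin(floor(t_lat / seg_len) + 1, n_seg)

    # B-wave with per-segment period but continuous phase, so windows that
    # straddle segment boundaries see no artificial discontinuity
    period <- stats::runif(n_seg, cfg$bwave_period_range_s[1],
                           cfg$bwave_period_range_s[2])
    phase0 <- stats::runif(1, 0, 2 * pi)
    phase <- phase0 + cumsum(2 * pi * lat_step / period[seg_of_lat])
    on_lat <- informative[seg_of_lat]
    slow_abp <- stats::rnorm(n_lat, 0, cfg$slow_noise_sd)
    slow_abp[on_lat] <- slow_abp[on_lat] +
      cfg$bwave_amp * sin(phase[on_lat])

    # deterministic normalization of the slow ABP lattice: dividing by the
    # process SD (not an empirical per-segment estimate) keeps z exactly
    # proportional to the observed slow component within each segment
    sd_on <- sqrt(cfg$bwave_amp^2 / 2 + cfg$slow_noise_sd^2)
    sd_ref_lat <- ifelse(on_lat, sd_on, cfg$slow_noise_sd)
    z_abp <- ifelse(sd_ref_lat > 0, slow_abp / sd_ref_lat, 0)
    s_ratio <- ifelse(informative, 1,
                      if (sd_on > 0) min(1, cfg$slow_noise_sd / sd_on) else 1)

    # drift-level CPP drives the autoregulation state
    drift_lat <- stats::approx(cfg$abp_drift$t_s, cfg$abp_drift$offset_mmhg,
                               xout = t_lat, rule = 2)$y
    cpp_lat <- cfg$abp_baseline + drift_lat - cfg$icp_baseline
    rho <- truth_prx_expectation(cpp_lat, cfg)
    eps <- stats::rnorm(n_lat)
    s_icp <- cfg$icp_slow_sd * s_ratio[seg_of_lat]
    icp_slow <- s_icp * (rho * z_abp + sqrt(1 - rho^2) * eps)

    # hold lattice values constant over each 10-s interval at 1 Hz
    lat_idx <- pmin(floor(t / lat_step) + 1, n_lat)
    drift <- stats::approx(cfg$abp_drift$t_s, cfg$abp_drift$offset_mmhg,
                           xout = t, rule = 2)$y
    abp_mean <- cfg$abp_baseline + drift + slow_abp[lat_idx] +
      stats::rnorm(n, 0, cfg$noise_sd)
    icp_mean <- cfg$icp_baseline + icp_slow[lat_idx] +
      stats::rnorm(n, 0, cfg$noise_sd_icp)

    d_abp <- rep(cfg$pulse_amp_abp, n)
    d_icp <- rep(cfg$pulse_amp_icp, n)

    # artifact episodes (Poisson arrivals, ABP channel)
    artifact <- rep(FALSE, n)
    n_art <- stats::rpois(1, cfg$artifact_rate_per_h * cfg$duration_s / 3600)
    if (cfg$artifact_rate_per_h <= 0) n_art <- 0
    frozen <- rep(NA_real_, n)
    if (n_art > 0) {
      starts <- sort(stats::runif(n_art, 0, cfg$duration_s))
      durs <- stats::runif(n_art, cfg$artifact_duration_range_s[1],
                           cfg$artifact_duration_range_s[2])
      kinds <- sample(cfg$artifact_kinds, n_art, replace = TRUE)
      for (a in seq_len(n_art)) {
        i0 <- max(1, floor(starts[a] / dt) + 1)
        i1 <- min(n, floor((starts[a] + durs[a]) / dt))
        if (i1 < i0) next
        idx <- i0:i1
        artifact[idx] <- TRUE
        if (kinds[a] == "damped_pulse") {
          tau <- 10
          d_abp[idx] <- pmax(2, cfg$pulse_amp_abp * exp(-(t[idx] - t[i0]) / tau))
        } else {
          # dropout: all three ABP values collapse to the episode-start mean
          # plus residual transducer noise (shared by sys/mean/dia, so the
          # pulse amplitude is exactly zero but the channel is not silent --
          # the surviving jitter correlates with nothing and is what makes
          # such episodes poison the PRx curve rather than censor it)
          frozen[idx] <- abp_mean[i0] + stats::rnorm(length(idx), 0, 0.3)
        }
      }
    }

    abp_sys <- abp_mean + d_abp / 2
    abp_dia <- abp_mean - d_abp / 2
    icp_sys <- icp_mean + d_icp / 2
    icp_dia <- icp_mean - d_icp / 2
    drop_idx <- !is.na(frozen)
    abp_mean[drop_idx] <- frozen[drop_idx]
    abp_sys[drop_idx] <- frozen[drop_idx]
    abp_dia[drop_idx] <- frozen[drop_idx]

    record <- monitoring_record(
      patient_id = sprintf("sim-seed%d", cfg$seed),
      t = t, sample_period_s = dt,
      abp_mean = abp_mean, abp_sys = abp_sys, abp_dia = abp_dia,
      icp_mean = icp_mean, icp_sys = icp_sys, icp_dia = icp_dia)

    half_width <- sqrt((0.3 - cfg$c_true) / cfg$a_true)
    truth <- structure(list(
      artifact = artifact,
      informative_segment = informative,
      segment_start_s = seg_start,
      x_opt_true = cfg$x_opt_true,
      llca_true = cfg$x_opt_true - half_width,
      ulca_true = cfg$x_opt_true + half_width), class = "ground_truth")

    list(record = record, truth = truth)
  })
}

#' Derive reference segment labels from simulator ground truth
#'
#' Converts the simulator's per-sample artifact mask and per-segment
#' informative flags into the annotation vocabulary for a set of segments
#' (as produced by [split_window()] or for the plain 24-min tiling).
#'
#' @param truth A `ground_truth` object from [simulate_monitoring()].
#' @param segments A data.frame with `start_s`, `end_s` (and optionally
#'   `window_id`, `segment_index`) describing segment extents.
#' @param sample_period_s Sampling period of the underlying record.
#' @param min_artifact_s Minimum artifact-flagged time (seconds) for a
#'   segment to be labeled `artifact_distorted` (default 30 s).
#' @return `segments` with `artifact_label` and `informative_label` columns
#'   added.
#' @export
truth_segment_labels <- function(truth, segments, sample_period_s = 1,
                                 min_artifact_s = 30) {
  stopifnot(inherits(truth, "ground_truth"))
  n <- length(truth$artifact)
  art <- character(nrow(segments))
  inf <- character(nrow(segments))
  seg_len <- diff(truth$segment_start_s[1:2])
  if (is.na(seg_len)) seg_len <- 1440
  for (i in seq_len(nrow(segments))) {
    i0 <- floor(segments$start_s[i] / sample_period_s) + 1
    i1 <- min(n, floor(segments$end_s[i] / sample_period_s))
    art_time <- sum(truth$artifact[i0:i1]) * sample_period_s
    art[i] <- if (art_time >= min_artifact_s) "artifact_distorted" else "artifact_free"
    # informative if the majority of the segment overlaps "on" truth tiles
    mids <- (segments$start_s[i] + segments$end_s[i]) / 2
    k <- min(length(truth$informative_segment), floor(mids / seg_len) + 1)
    inf[i] <- if (truth$informative_segment[k]) "informative" else "noninformative"
  }
  segments$artifact_label <- art
  segments$informative_label <- inf
  segments
}
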