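#' Train the artifact and informative segment classifiers
#'
#' Builds the X1 (artifact) and X2 (informative) feature matrices over the
#' non-overlapping 24-min tiling of a labeled record and trains the two
#' binary RBF SVMs by exponential grid search. Labels follow the reference
#' convention: positive class 1 is `artifact_distorted` for the artifact
#' model and `informative` for the informative model.
#'
#' @param record A [monitoring_record()].
#' @param labels A data.frame with `start_s`, `end_s`, `artifact_label`,
#'   `informative_label` (e.g. from [truth_segment_labels()] or
#'   [read_annotations()] joined to segment extents).
#' @param seed Seed for the CV fold assignment.
#' @param ... Passed to [grid_search_train()].
#' @return A list with `artifact_model`, `informative_model` (class
#'   `prx_svm`) and the two `svm_grid_result`s.
#' @export
train_segment_classifiers <- function(record, labels, seed = 1L, ...) {
  X1 <- segment_feature_matrix(record, labels, type = "artifact")
  X2 <- segment_feature_matrix(record, labels, type = "informative")
  y1 <- as.integer(labels$artifact_label == "artifact_distorted")
  y2 <- as.integer(labels$informative_label == "informative")
  a <- grid_search_train(X1, y1, seed = seed, ...)
  b <- grid_search_train(X2, y2, seed = seed + 1L, ...)
  list(artifact_model = a$model, artifact_grid = a$grid,
       informative_model = b$model, informative_grid = b$grid)
}

# Predicted annotation labels for a segment table. Segments whose feature
# vector is missing are classified artifact-distorted by policy (they are
# unusable either way).
predict_segment_labels <- function(record, segments, models) {
  X1 <- segment_feature_matrix(record, segments, type = "artifact")
  X2 <- segment_feature_matrix(record, segments, type = "informative")
  p1 <- svm_predict(models$artifact_model, X1)
  p2 <- svm_predict(models$informative_model, X2)
  segments$artifact_label <- ifelse(is.na(p1$label) | p1$label == 1,
                                    "artifact_distorted", "artifact_free")
  segments$informative_label <- ifelse(!is.na(p2$label) & p2$label == 1,
                                       "informative", "noninformative")
  segments
}

#' Run the full short-episode identification workflow
#'
#' The end-to-end pipeline: PRx computation, sliding 2-hour windows of five
#' 24-min segments, segment classification (artifact removal, then
#' informative-segment detection), R^2-driven conditional inclusion of
#' artifact-free noninformative segments, triple-axis U-shape fits
#' (PRx = f(CPP), f(ABP), f(ICP)), the per-window five-way management
#' decision, and the percentage-time yield report.
#'
#' @param record A [monitoring_record()].
#' @param models Classifier pair from [train_segment_classifiers()];
#'   required unless `use_ml = FALSE`.
#' @param use_ml If `FALSE`, no classifiers are applied: every segment is
#'   treated as artifact-free and informative, i.e. all data enter every
#'   fit (the conventional, non-learning reference variant).
#' @param prx_parameters A [prx_params()].
#' @param window_s,step_s Window length and step, seconds.
#' @param bin_width,min_count,threshold,min_r2 U-shape settings, see
#'   [bin_prx()] / [fit_ushape()].
#' @return A list of class `prxopt_run` with elements `prx` (the
#'   `prx_series`), `windows`, `segments` (with the labels used), `fits`
#'   (per window: named list for the three axes), `chosen` (per window:
#'   segment indices used for the CPP-axis fit), `decisions`,
#'   `decision_table` (one row per window), and `yield`.
#' @export
run_pipeline <- function(record, models = NULL, use_ml = TRUE,
                         prx_parameters = prx_params(),
                         window_s = 7200, step_s = 1440,
                         bin_width = 5, min_count = 5, threshold = 0.3,
                         min_r2 = 0) {
  if (use_ml && is.null(models))
    stop("models are required when use_ml = TRUE")
  prx <- compute_prx(record, prx_parameters)
  windows <- make_windows(record, window_s, step_s)
  segs <- segment_table(record, window_s, step_s)
  if (use_ml) {
    segs <- predict_segment_labels(record, segs, models)
  } else {
    segs$artifact_label <- "artifact_free"
    segs$informative_label <- "informative"
  }
  fits <- vector("list", nrow(windows))
  chosen <- vector("list", nrow(windows))
  decisions <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    wseg <- segs[segs$window_id == windows$window_id[i], , drop = FALSE]
    in_w <- prx$t_end > windows$start_s[i] &
      prx$t_end <= windows$start_s[i] + window_s
    wprx <- prx[in_w, , drop = FALSE]
    f <- lapply(c(cpp = "cpp", abp = "abp", icp = "icp"), function(ax) {
      select_segments(wseg, wprx, axis = ax,
                      window_start_s = windows$start_s[i],
                      bin_width = bin_width, min_count = min_count,
                      threshold = threshold, min_r2 = min_r2)
    })
    fits[[i]] <- lapply(f, `[[`, "fit")
    chosen[[i]] <- f$cpp$chosen
    decisions[[i]] <- classify_window(fits[[i]], wprx, threshold = threshold,
                                      bin_width = bin_width,
                                      min_count = min_count)
  }
  decision_table <- do.call(rbind, lapply(seq_along(decisions), function(i) {
    d <- decisions[[i]]
    data.frame(window_id = windows$window_id[i],
               cpp_guided = d$cpp_guided, abp_guided = d$abp_guided,
               icp_guided = d$icp_guided, intact = d$intact,
               critical = d$critical,
               primary_situation = d$primary_situation,
               cppopt = fits[[i]]$cpp$opt_value,
               llca = fits[[i]]$cpp$llca, ulca = fits[[i]]$cpp$ulca,
               abpopt = fits[[i]]$abp$opt_value,
               icp_ulca = fits[[i]]$icp$ulca)
  }))
  structure(list(prx = prx, windows = windows, segments = segs,
                 fits = fits, chosen = chosen, decisions = decisions,
                 decision_table = decision_table,
                 yield = yield_report(decisions, fits)),
            class = "prxopt_run")
}

#' Per-window features for the management-recognition models
#'
#' The five management-recognition models (CPP-, ABP-, ICP-guided,
#' critical, intact) are binary SVMs over per-window features: the mean of
#' the five segments' X2 (informative) feature vectors concatenated with
#' PRx summaries -- mean PRx, its 10th and 90th percentiles, and the CPP
#' range covered by the window.
#'
#' @param record A [monitoring_record()].
#' @param windows Output of [make_windows()].
#' @param prx A `prx_series` for the whole record.
#' @param window_s Window length, seconds.
#' @return A numeric matrix, one row per window.
#' @export
window_management_features <- function(record, windows, prx, window_s = 7200) {
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    segs <- split_window(windows$start_s[i], windows$window_id[i], window_s)
    X2 <- segment_feature_matrix(record, segs, type = "informative")
    in_w <- prx$t_end > windows$start_s[i] &
      prx$t_end <= windows$start_s[i] + window_s
    p <- prx$prx[in_w]
    cpp <- prx$cpp_mean[in_w]
    q <- if (any(!is.na(p))) stats::quantile(p, c(0.1, 0.9), na.rm = TRUE,
                                             names = FALSE) else c(NA_real_, NA_real_)
    c(colMeans(X2, na.rm = TRUE),
      prx_mean = mean(p, na.rm = TRUE), prx_p10 = q[1], prx_p90 = q[2],
      cpp_range = if (any(!is.na(cpp))) diff(range(cpp, na.rm = TRUE)) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Train the five management-recognition models
#'
#' One binary RBF SVM per clinical situation, trained on
#' [window_management_features()] with labels taken from per-window
#' [classify_window()] decisions (the positive class is the situation
#' itself).
#'
#' @param features Matrix from [window_management_features()].
#' @param decisions List of `management_decision` objects, same length.
#' @param seed Seed for fold assignment.
#' @param ... Passed to [grid_search_train()].
#' @return A named list of `prx_svm` models (entries are skipped with a
#'   message when a situation has a single class in the training windows).
#' @export
train_management_models <- function(features, decisions, seed = 1L, ...) {
  situations <- c("cpp_guided", "abp_guided", "icp_guided", "intact", "critical")
  out <- list()
  for (k in seq_along(situations)) {
    s <- situations[k]
    y <- vapply(decisions, function(d) as.integer(isTRUE(d[[s]])), integer(1))
    if (length(unique(y)) < 2) {
      message("situation '", s, "' has a single class; model skipped")
      next
    }
    out[[s]] <- grid_search_train(features, y, seed = seed + k, ...)$model
  }
  out
}
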