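#' Exponential grid for SVM hyperparameter search
#'
#' The base values (cost `C = 1`, kernel width `gamma = 1/d` with `d` the
#' number of input variables) are scaled by exponentially growing factors
#' 1/32, 1/16, 1/8, 1/4, 1/2, 1, 2, 4, 8, 16, 32, giving an 11 x 11 = 121
#' cell Cartesian grid.
#'
#' @param n_features Number of input variables `d`.
#' @param base_c Base cost (default 1).
#' @param base_gamma Base kernel width (default `1/n_features`).
#' @param factors Multiplicative factors (default `2^(-5:5)`).
#' @return A `data.frame` with columns `C` and `gamma`, one row per cell.
#' @export
svm_grid <- function(n_features, base_c = 1, base_gamma = 1 / n_features,
                     factors = 2^(-5:5)) {
  expand.grid(C = base_c * factors, gamma = base_gamma * factors,
              KEEP.OUT.ATTRS = FALSE)
}

# Deterministic stratified fold assignment, invariant to row order:
# rows are put in a canonical order (class, then lexicographic features),
# shuffled with the private seed, and dealt round-robin within each class.
stratified_folds <- function(X, y, folds, seed) {
  n <- length(y)
  ord <- do.call(order, c(list(y), lapply(seq_len(ncol(X)), function(j) X[, j])))
  with_private_seed(seed, {
    sh <- ord[sample.int(n)]
    fold <- integer(n)
    for (cl in unique(y)) {
      members <- sh[y[sh] == cl]
      fold[members] <- rep_len(seq_len(folds), length(members))
    }
    fold
  })
}

zscore_stats <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  list(center = center, scale = scale, keep = which(scale > 0))
}

apply_zscore <- function(X, st) {
  sweep(sweep(X[, st$keep, drop = FALSE], 2, st$center[st$keep], "-"),
        2, st$scale[st$keep], "/")
}

fit_rbf_svm <- function(Xs, yf, C, gamma, class_weights = NULL) {
  e1071::svm(x = Xs, y = yf, type = "C-classification", kernel = "radial",
             cost = C, gamma = gamma, scale = FALSE,
             class.weights = class_weights)
}

#' Train a binary RBF-kernel SVM with exponential grid search
#'
#' Selects the cost `C` and kernel width `gamma` over the 121-cell
#' exponential grid of [svm_grid()] by stratified tenfold cross-validated
#' accuracy, then refits on all data at the best cell. Features are z-scored
#' using statistics of the training rows only (fold-wise during CV, so the
#' held-out fold never leaks into standardization or fitting); zero-variance
#' features are dropped and recorded. Ties between cells are broken by
#' smallest `C`, then smallest `gamma`. Deterministic given `seed` and
#' invariant to row order.
#'
#' @param X Numeric feature matrix (named columns) or data.frame.
#' @param y Binary labels in `{0, 1}` (positive class `1`).
#' @param seed Integer seed controlling fold assignment.
#' @param folds Number of CV folds (default 10); reduced with a warning if
#'   the smaller class has fewer members.
#' @param base_c,base_gamma,factors Grid construction, see [svm_grid()].
#' @param class_weights Optional named class weights passed to the
#'   underlying fit (default none).
#' @return A list with elements `model` (class `prx_svm`; see
#'   [svm_predict()]) and `grid` (class `svm_grid_result`: the per-cell CV
#'   accuracies and the best cell).
#' @export
grid_search_train <- function(X, y, seed = 1L, folds = 10,
                              base_c = 1, base_gamma = NULL,
                              factors = 2^(-5:5), class_weights = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.integer(y)
  keep_rows <- stats::complete.cases(X) & !is.na(y)
  if (!all(keep_rows)) {
    warning(sum(!keep_rows), " row(s) with missing values dropped before training")
    X <- X[keep_rows, , drop = FALSE]
    y <- y[keep_rows]
  }
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  n_min <- min(table(y))
  if (n_min < folds) {
    warning("reducing CV folds from ", folds, " to ", n_min,
            " (smaller class size)")
    folds <- max(2, n_min)
  }
  if (is.null(base_gamma)) base_gamma <- 1 / ncol(X)
  grid <- svm_grid(ncol(X), base_c, base_gamma, factors)

  fold <- stratified_folds(X, y, folds, seed)
  yf <- factor(y, levels = c(0, 1))
  # fold-wise standardized splits are hyperparameter-independent
  splits <- lapply(seq_len(folds), function(f) {
    tr <- fold != f
    st <- zscore_stats(X[tr, , drop = FALSE])
    list(Xtr = apply_zscore(X[tr, , drop = FALSE], st),
         Xte = apply_zscore(X[!tr, , drop = FALSE], st),
         ytr = yf[tr], yte = yf[!tr])
  })
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    correct <- 0L; total <- 0L
    for (sp in splits) {
      m <- fit_rbf_svm(sp$Xtr, sp$ytr, grid$C[i], grid$gamma[i], class_weights)
      p <- stats::predict(m, sp$Xte)
      correct <- correct + sum(p == sp$yte)
      total <- total + length(sp$yte)
    }
    correct / total
  }, numeric(1))
  grid$accuracy <- acc
  # best: max accuracy, ties by smallest C then smallest gamma
  best <- order(-grid$accuracy, grid$C, grid$gamma)[1]

  st <- zscore_stats(X)
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)), st$keep)]
  Xs <- apply_zscore(X, st)
  m <- fit_rbf_svm(Xs, yf, grid$C[best], grid$gamma[best], class_weights)
  # orientation: which class e1071's positive decision value refers to
  dv <- attr(stats::predict(m, Xs[1:min(2, nrow(Xs)), , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  pos_class <- strsplit(colnames(dv)[1], "/")[[1]][1]
  orient <- if (pos_class == "1") 1 else -1

  model <- structure(list(
    schema_version = 1L,
    feature_names = colnames(X)[st$keep],
    dropped_features = dropped,
    center = unname(st$center[st$keep]),
    scale = unname(st$scale[st$keep]),
    sv = unname(as.matrix(m$SV)),
    coefs = as.numeric(m$coefs),
    rho = as.numeric(m$rho),
    orient = orient,
    C = grid$C[best], gamma = grid$gamma[best],
    labels = c(0L, 1L)), class = "prx_svm")

  grid_result <- structure(list(
    factors = factors, base_c = base_c, base_gamma = base_gamma,
    grid = grid,
    best = list(C = grid$C[best], gamma = grid$gamma[best],
                accuracy = grid$accuracy[best])), class = "svm_grid_result")
  list(model = model, grid = grid_result)
}

#' Predict with a trained RBF SVM
#'
#' Applies the stored training standardization (never the new batch's own
#' statistics), evaluates the RBF decision function
#' `f(x) = sum_i coef_i exp(-gamma ||x - sv_i||^2) - rho` oriented so that
#' positive values mean class 1, and thresholds at zero.
#'
#' @param model A `prx_svm` from [grid_search_train()] or [load_model()].
#' @param X Feature matrix or data.frame; columns must include the model's
#'   feature names (unknown situations, i.e. missing model features, error).
#' @return A `data.frame` with `label` (integer 0/1; `NA` for rows with
#'   missing features) and `decision` (signed distance-like score for ROC).
#' @export
svm_predict <- function(model, X) {
  stopifnot(inherits(model, "prx_svm"))
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X) == length(model$feature_names))
    colnames(X) <- model$feature_names
  missing_f <- setdiff(model$feature_names, colnames(X))
  if (length(missing_f) > 0)
    stop("feature column(s) absent from new data: ",
         paste(missing_f, collapse = ", "))
  Xm <- X[, model$feature_names, drop = FALSE]
  ok <- stats::complete.cases(Xm)
  dec <- rep(NA_real_, nrow(Xm))
  if (any(ok)) {
    Xs <- sweep(sweep(Xm[ok, , drop = FALSE], 2, model$center, "-"),
                2, model$scale, "/")
    # squared distances to support vectors
    d2 <- outer(rowSums(Xs^2), rowSums(model$sv^2), "+") -
      2 * Xs %*% t(model$sv)
    d2[d2 < 0] <- 0
    K <- exp(-model$gamma * d2)
    dec[ok] <- model$orient * (as.numeric(K %*% model$coefs) - model$rho)
  }
  data.frame(label = ifelse(is.na(dec), NA_integer_, as.integer(dec > 0)),
             decision = dec)
}

#' Save and load trained SVM models as JSON
#'
#' The on-disk schema (version 1) stores feature names, training
#' standardization, support vectors, dual coefficients, bias, orientation
#' and hyperparameters; `load_model(save_model(m))` reproduces decision
#' values to better than 1e-9.
#'
#' @param model A `prx_svm`.
#' @param path Output/input JSON path.
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   reconstructed `prx_svm`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "prx_svm"))
  if (length(model$feature_names) == 0) stop("model has no features")
  obj <- unclass(model)
  obj$sv <- as.data.frame(obj$sv)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$schema_version) || obj$schema_version != 1L)
    stop("unsupported model schema version: ",
         if (is.null(obj$schema_version)) "none" else obj$schema_version)
  obj$sv <- as.matrix(obj$sv)
  dimnames(obj$sv) <- NULL
  obj$schema_version <- as.integer(obj$schema_version)
  obj$labels <- as.integer(obj$labels)
  if (length(obj$dropped_features) == 0) obj$dropped_features <- character(0)
  structure(obj, class = "prx_svm")
}
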