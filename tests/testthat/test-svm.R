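# two-class Gaussian blobs, optionally separated
make_blobs <- function(n = 200, sep = 6, d = 4, seed = 101) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * d), n, d) + sep * y
  colnames(X) <- paste0("f", 1:d)
  list(X = X, y = y)
}

test_that("the exponential hyperparameter grid has 121 cells", {
  g <- svm_grid(10)
  expect_equal(nrow(g), 121)
  expect_equal(sort(unique(g$C)), sort(2^(-5:5)))
  expect_equal(sort(unique(g$gamma)), sort(2^(-5:5) / 10))
})

test_that("well-separated blobs reach near-perfect CV and training accuracy", {
  b <- make_blobs(n = 200, sep = 6)
  res <- grid_search_train(b$X, b$y, seed = 1)
  expect_gte(res$grid$best$accuracy, 0.99)
  pred <- svm_predict(res$model, b$X)
  expect_gte(mean(pred$label == b$y), 0.99)
  # reference implementation agrees on held-out style data
  skip_if_not_installed("kernlab")
  km <- kernlab::ksvm(b$X, factor(b$y), kernel = "rbfdot", C = res$model$C,
                      kpar = list(sigma = res$model$gamma), scaled = TRUE)
  agree <- mean(as.integer(as.character(kernlab::predict(km, b$X))) == pred$label)
  expect_gte(agree, 0.99)
})

test_that("labels independent of features give chance-level CV accuracy", {
  b <- make_blobs(n = 200, sep = 0, seed = 33)
  res <- grid_search_train(b$X, b$y, seed = 2)
  # best-of-121 selection optimism keeps this above 0.5 but well below signal
  expect_gte(res$grid$best$accuracy, 0.35)
  expect_lte(res$grid$best$accuracy, 0.65)
})

test_that("standardization uses stored training statistics, not the batch's", {
  b <- make_blobs(n = 120, sep = 5, seed = 7)
  res <- grid_search_train(b$X, b$y, seed = 1)
  base <- svm_predict(res$model, b$X)
  # batch composition must not matter: row-by-row equals whole-batch
  solo <- vapply(1:10, function(i)
    svm_predict(res$model, b$X[i, , drop = FALSE])$decision, numeric(1))
  expect_equal(solo, base$decision[1:10], tolerance = 1e-12)
  # a uniformly shifted batch must change decisions (self-standardizing the
  # new batch would reproduce the unshifted predictions exactly)
  shifted <- svm_predict(res$model, b$X + 2)
  expect_false(isTRUE(all.equal(shifted$decision, base$decision)))
  expect_gte(mean(shifted$label), mean(base$label))
})

test_that("degenerate inputs are rejected or degraded gracefully", {
  b <- make_blobs(n = 60, sep = 5)
  expect_error(grid_search_train(b$X, rep(1, 60)), "single class")
  expect_warning(grid_search_train(b$X[1:15, ], b$y[c(1:8, 31:37)], seed = 1,
                                   factors = c(1, 2)), "folds")
  # zero-variance feature is dropped and recorded
  X <- cbind(b$X, dead = 0)
  res <- grid_search_train(X, b$y, seed = 1, factors = c(0.5, 1, 2))
  expect_equal(res$model$dropped_features, "dead")
  expect_false("dead" %in% res$model$feature_names)
})

test_that("model JSON round-trip reproduces decision values to 1e-9", {
  b <- make_blobs(n = 100, sep = 3, seed = 11)
  res <- grid_search_train(b$X, b$y, seed = 1, factors = c(0.5, 1, 2))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(res$model, path)
  back <- load_model(path)
  expect_equal(back$feature_names, res$model$feature_names)
  d1 <- svm_predict(res$model, b$X)$decision
  d2 <- svm_predict(back, b$X)$decision
  expect_lt(max(abs(d1 - d2)), 1e-9)
  # schema version is enforced
  obj <- jsonlite::fromJSON(path)
  obj$schema_version <- 99
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(path), "schema")
  # models without features cannot be persisted
  empty <- res$model
  empty$feature_names <- character(0)
  expect_error(save_model(empty, path), "features")
})

test_that("grid search is deterministic and invariant to row order", {
  b <- make_blobs(n = 80, sep = 2, seed = 13)
  f <- c(0.25, 1, 4)
  r1 <- grid_search_train(b$X, b$y, seed = 5, factors = f)
  r2 <- grid_search_train(b$X, b$y, seed = 5, factors = f)
  expect_identical(r1$grid$grid$accuracy, r2$grid$grid$accuracy)
  perm <- sample(nrow(b$X))
  r3 <- grid_search_train(b$X[perm, ], b$y[perm], seed = 5, factors = f)
  expect_equal(r1$grid$grid$accuracy, r3$grid$grid$accuracy, tolerance = 1e-12)
  expect_equal(r1$grid$best, r3$grid$best)
})

test_that("prediction errors on unknown feature columns", {
  b <- make_blobs(n = 60, sep = 5)
  res <- grid_search_train(b$X, b$y, seed = 1, factors = 1)
  X <- b$X
  colnames(X)[2] <- "other"
  expect_error(svm_predict(res$model, X), "f2")
})
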