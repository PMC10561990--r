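# Independent oracle: a literal re-implementation of the prediction chain
# (feed new X to every fold model, average per learner, feed to the meta
# model), written against the adapters directly rather than the package's
# prediction path.
naive_stacking_predict <- function(newX, model) {
  nfold <- model$base$folds$nfold
  L <- length(model$base$configs)
  raw <- matrix(NA_real_, nrow(newX), nfold * L)
  k <- 0
  for (l in seq_len(L)) {
    adapter <- get_learner(model$base$configs[[l]]$method, model$task)
    for (f in seq_len(nfold)) {
      k <- k + 1
      raw[, k] <- adapter$predict(model$base$models[[f, l]], newX)
    }
  }
  agg <- sapply(seq_len(L), function(l) {
    rowMeans(raw[, (l - 1) * nfold + seq_len(nfold), drop = FALSE])
  })
  agg <- matrix(agg, nrow = nrow(newX))
  colnames(agg) <- paste0("L", seq_len(L))
  design <- agg[, model$meta$which_to_use, drop = FALSE]
  meta_adapter <- get_learner(model$meta$meta_method$method, model$task)
  preds <- sapply(model$meta$fitted_states, function(s) meta_adapter$predict(s, design))
  rowMeans(matrix(preds, nrow = nrow(newX)))
}

test_that("constant learners propagate through raw and aggregated predictions", {
  d <- make_dummy_regression(n = 10)
  folds <- assign_folds(10, 2, seed = 1)
  configs <- expand_base_learners(list(
    method_spec("dummy_const", data.frame(value = c(1, 2, 3)))))
  bt <- train_base_models(d$X, d$Y, folds, configs)
  raw <- predict_base(d$X[1:4, ], bt$base)
  expect_equal(dim(raw), c(4L, 6L))  # 2 folds x 3 learners
  expect_equal(unname(raw[1, ]), c(1, 1, 2, 2, 3, 3))
  agg <- aggregate_per_learner(raw)
  expect_equal(dim(agg), c(4L, 3L))
  expect_equal(unname(agg[2, ]), c(1, 2, 3))
})

test_that("regression aggregation is the fold mean and lies within fold range", {
  raw <- cbind(`L1.f1` = c(1, 5), `L1.f2` = c(3, 7))
  expect_equal(unname(aggregate_per_learner(raw, nfold = 2)[, 1]), c(2, 6))
  set.seed(12)
  raw2 <- matrix(rnorm(40), 10, 4,
                 dimnames = list(NULL, c("L1.f1", "L1.f2", "L2.f1", "L2.f2")))
  agg2 <- aggregate_per_learner(raw2, nfold = 2)
  for (l in 1:2) {
    block <- raw2[, (l - 1) * 2 + 1:2]
    expect_true(all(agg2[, l] >= apply(block, 1, min) - 1e-12))
    expect_true(all(agg2[, l] <= apply(block, 1, max) + 1e-12))
  }
})

test_that("classification aggregation takes the modal label, ties lexicographic", {
  raw <- matrix(c("A", "A", "B", "A", "B",
                  "B", "A", "B", "A", "A"), nrow = 2, byrow = TRUE)
  colnames(raw) <- paste0("L1.f", 1:5)
  agg <- aggregate_per_learner(raw, task = "classification", nfold = 5)
  expect_equal(unname(agg[1, ]), "A")  # A:3 B:2
  raw_tie <- matrix(c("B", "A"), nrow = 1)
  colnames(raw_tie) <- paste0("L1.f", 1:2)
  expect_equal(unname(aggregate_per_learner(raw_tie, task = "classification",
                                            nfold = 2)[1, ]), "A")
})

test_that("predict_stacking equals the naive step-by-step oracle", {
  d <- make_dummy_regression(n = 12, p = 4, seed = 21)
  fit <- stack_train(d$X, d$Y,
    base_learners = list(
      method_spec("dummy_mean"),
      method_spec("dummy_slope", data.frame(col = c(1, 2)))),
    meta_learner = method_spec("linear"), nfold = 2, seed = 8)
  new <- make_dummy_regression(n = 7, p = 4, seed = 22)
  expect_equal(unname(predict_stacking(new$X, fit)),
               naive_stacking_predict(new$X, fit), tolerance = 1e-12)

  # per-fold meta mode against the same oracle (oracle averages meta fits);
  # no dummy_mean here: its meta column is constant within a fold, which
  # makes the per-fold meta fit rank-deficient by construction
  fit2 <- stack_train(d$X, d$Y,
    base_learners = list(
      method_spec("dummy_slope", data.frame(col = c(1, 2, 3)))),
    meta_learner = method_spec("linear"), nfold = 2, seed = 8,
    train_each_fold = TRUE)
  expect_length(fit2$meta$fitted_states, 2L)
  expect_equal(unname(predict_stacking(new$X, fit2)),
               naive_stacking_predict(new$X, fit2), tolerance = 1e-12)
})

test_that("a perfectly predictive learner passes through an identity meta-model", {
  # dummy_slope on column 1 with Y = X1 exactly: every fold model is y = x1
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("V", 1:3)))
  Y <- X[, 1]
  fit <- stack_train(X, Y,
    base_learners = list(method_spec("dummy_slope", data.frame(col = 1))),
    meta_learner = method_spec("linear"), nfold = 2, seed = 3)
  newX <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, paste0("V", 1:3)))
  expect_equal(unname(predict_stacking(newX, fit)), newX[, 1], tolerance = 1e-8)
})

test_that("predictions are equivariant to row permutation of newX", {
  d <- make_dummy_regression(n = 16, seed = 2)
  fit <- stack_train(d$X, d$Y,
    base_learners = list(method_spec("dummy_slope", data.frame(col = c(1, 2)))),
    meta_learner = method_spec("linear"), nfold = 4, seed = 1)
  new <- make_dummy_regression(n = 9, seed = 12)
  p <- predict_stacking(new$X, fit)
  perm <- c(4, 1, 9, 2, 8, 3, 7, 5, 6)
  expect_equal(predict_stacking(new$X[perm, ], fit), p[perm], tolerance = 1e-12)
})

test_that("feature columns are matched by name and mismatches rejected", {
  d <- make_dummy_regression(n = 14)
  fit <- stack_train(d$X, d$Y,
    base_learners = list(method_spec("dummy_slope", data.frame(col = 1))),
    meta_learner = method_spec("linear"), nfold = 2, seed = 1)
  new <- make_dummy_regression(n = 5)
  shuffled <- new$X[, c(3, 1, 4, 2)]
  expect_equal(predict_stacking(shuffled, fit), predict_stacking(new$X, fit))
  bad <- new$X; colnames(bad)[2] <- "W9"
  expect_error(predict_stacking(bad, fit), "missing: \\[V2\\]")
})

test_that("empty newX yields an empty prediction with intact structure", {
  d <- make_dummy_regression(n = 10)
  fit <- stack_train(d$X, d$Y,
    base_learners = list(method_spec("dummy_mean")),
    meta_learner = method_spec("linear"), nfold = 2, seed = 1)
  empty <- d$X[0, , drop = FALSE]
  raw <- predict_base(empty, fit$base)
  expect_equal(dim(raw), c(0L, 2L))
  expect_length(predict_stacking(empty, fit), 0L)
})

test_that("classification end-to-end: modal aggregation and majority-vote meta", {
  sim <- simulate_classification(n = 90, p = 6, n_causal = 4, n_classes = 3, seed = 14)
  fit <- stack_train(sim$X, sim$Y,
    base_learners = list(method_spec("dummy_centroid"), method_spec("dummy_mode")),
    meta_learner = method_spec("dummy_centroid"), nfold = 3, seed = 2,
    task = "classification")
  new <- simulate_classification(n = 30, p = 6, n_causal = 4, n_classes = 3, seed = 15)
  p <- predict_stacking(new$X, fit)
  expect_s3_class(p, "factor")
  expect_equal(levels(p), c("C1", "C2", "C3"))
  expect_length(p, 30L)
  # per-fold variant votes across meta models and stays in the label set
  fit2 <- stack_train(sim$X, sim$Y,
    base_learners = list(method_spec("dummy_centroid")),
    meta_learner = method_spec("dummy_mode"), nfold = 3, seed = 2,
    train_each_fold = TRUE, task = "classification")
  p2 <- predict_stacking(new$X, fit2)
  expect_true(all(as.character(p2) %in% c("C1", "C2", "C3")))
})

test_that("a saved and reloaded model predicts identically", {
  d <- make_dummy_regression(n = 15)
  fit <- stack_train(d$X, d$Y,
    base_learners = list(method_spec("dummy_slope", data.frame(col = c(1, 2)))),
    meta_learner = method_spec("linear"), nfold = 3, seed = 7)
  path <- tempfile(fileext = ".stk")
  save_stacked_model(fit, path)
  restored <- load_stacked_model(path)
  new <- make_dummy_regression(n = 6, seed = 77)
  expect_identical(predict_stacking(new$X, restored), predict_stacking(new$X, fit))
  expect_equal(restored$manifest$package, "stackle")
  unlink(path)
})
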