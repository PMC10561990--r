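make_meta_table <- function(values, fold_of_row, task = "regression",
                            y_levels = NULL, seed = 1L) {
  L <- ncol(values)
  configs <- expand_base_learners(
    lapply(seq_len(L), function(i) method_spec(
      if (task == "regression") "dummy_const" else "dummy_mode",
      if (task == "regression") data.frame(value = i) else NULL)))
  structure(list(values = values, fold_of_row = fold_of_row, configs = configs,
                 task = task, dropped_learners = integer(), seed = seed,
                 y_levels = y_levels),
            class = "meta_feature_table")
}

test_that("regression meta design passes selected columns through unchanged", {
  v <- matrix(rnorm(30), 10, 3)
  mt <- make_meta_table(v, rep(1:2, 5))
  expect_equal(unname(build_meta_design(mt)), v)
  expect_equal(unname(build_meta_design(mt, which_to_use = c(3, 1))), v[, c(3, 1)])
  expect_error(build_meta_design(mt, which_to_use = integer()), "non-empty")
  expect_error(build_meta_design(mt, which_to_use = c(1, 1)), "duplicate-free")
})

test_that("classification meta design expands to nlevels-1 indicators per column", {
  v <- matrix(c("A", "B", "C", "A", "B", "A"), ncol = 1)
  mt <- make_meta_table(v, rep(1:2, 3), task = "classification",
                        y_levels = c("A", "B", "C"))
  d <- build_meta_design(mt)
  expect_equal(ncol(d), 2L)  # 3 levels - reference
  expect_equal(colnames(d), c("L1.B", "L1.C"))
  expect_equal(d[, "L1.B"], c(0, 1, 0, 0, 1, 0))
  expect_equal(d[, "L1.C"], c(0, 0, 1, 0, 0, 0))
  # unseen label encodes as all-zero with a warning
  mt$values[1, 1] <- "Z"
  expect_warning(d2 <- build_meta_design(mt), "outside the training level set")
  expect_equal(unname(d2[1, ]), c(0, 0))
})

test_that("pooled mode fits once; per-fold mode fits once per fold on its own rows", {
  d <- make_dummy_regression(n = 24)
  folds <- assign_folds(24, 3, seed = 5)
  bt <- train_base_models(d$X, d$Y, folds, expand_base_learners(list(
    method_spec("dummy_mean"), method_spec("dummy_slope", data.frame(col = 1)))))
  pooled <- train_meta_model(bt$meta_features, d$Y, method_spec("linear"))
  expect_length(pooled$fitted_states, 1L)
  expect_false(pooled$train_each_fold)

  perfold <- train_meta_model(bt$meta_features, d$Y, method_spec("linear"),
                              train_each_fold = TRUE)
  expect_length(perfold$fitted_states, 3L)
  # partition property: each row used in exactly one per-fold fit
  rows_used <- lapply(1:3, function(f) which(bt$meta_features$fold_of_row == f))
  expect_equal(sort(unlist(rows_used)), 1:24)
  expect_equal(sum(lengths(rows_used)), 24L)
  # fold f meta-fit reproduces an lm on exactly those rows
  design <- build_meta_design(bt$meta_features)
  for (f in 1:3) {
    ref <- lm(y ~ ., data = data.frame(y = d$Y[rows_used[[f]]],
                                       design[rows_used[[f]], , drop = FALSE]))
    got <- perfold$fitted_states[[f]]$model
    expect_equal(unname(coef(got)), unname(coef(ref)))
  }
})

test_that("an exact-copy meta-feature gives an identity linear meta-model", {
  Y <- rnorm(30)
  v <- cbind(Y, rnorm(30))
  mt <- make_meta_table(v, rep(1:2, 15))
  meta <- train_meta_model(mt, Y, method_spec("linear"), which_to_use = 1L)
  cf <- coef(meta$fitted_states[[1]]$model)
  expect_equal(unname(cf), c(0, 1), tolerance = 1e-10)
})

test_that("pooled meta predictions are invariant to joint row permutation", {
  set.seed(31)
  Y <- rnorm(20)
  v <- cbind(Y + rnorm(20, sd = .1), Y + rnorm(20, sd = .2))
  mt <- make_meta_table(v, rep(1:2, 10))
  perm <- sample(20)
  mtp <- make_meta_table(v[perm, ], rep(1:2, 10)[perm])
  m1 <- train_meta_model(mt, Y, method_spec("linear"))
  m2 <- train_meta_model(mtp, Y[perm], method_spec("linear"))
  newd <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("L1", "L2")))
  a1 <- get_learner("linear")$predict(m1$fitted_states[[1]], newd)
  a2 <- get_learner("linear")$predict(m2$fitted_states[[1]], newd)
  expect_equal(a1, a2, tolerance = 1e-8)
})

test_that("constant meta-features give constant meta predictions (degenerate input)", {
  Y <- rnorm(12)
  v <- matrix(3.5, 12, 1)
  mt <- make_meta_table(v, rep(1:2, 6))
  meta <- train_meta_model(mt, Y, method_spec("linear"))
  p <- get_learner("linear")$predict(meta$fitted_states[[1]],
                                     matrix(3.5, 4, 1, dimnames = list(NULL, "L1")))
  expect_equal(p, rep(mean(Y), 4), tolerance = 1e-8)
})

test_that("learner columns with failed cells are excluded from the meta design", {
  Y <- rnorm(12)
  v <- cbind(Y, NA_real_)
  mt <- make_meta_table(v, rep(1:2, 6))
  expect_warning(meta <- train_meta_model(mt, Y, method_spec("linear")),
                 "failed out-of-fold cells")
  expect_equal(meta$which_to_use, 1L)
  v2 <- matrix(NA_real_, 12, 1)
  mt2 <- make_meta_table(v2, rep(1:2, 6))
  expect_error(suppressWarnings(train_meta_model(mt2, Y, method_spec("linear"))),
               "no usable learner columns")
})
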