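test_that("pearson_correlation matches hand arithmetic and the +/-1 cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(-x, x), -1)
  # hand computation for pred=(1,2,3,4), truth=(1,2,3,10):
  # centered pred (-1.5,-.5,.5,1.5), centered truth (-3,-2,-1,6),
  # sum of products = 4.5+1-0.5+9 = 14, sums of squares 5 and 50
  expect_equal(pearson_correlation(x, c(1, 2, 3, 10)), 14 / sqrt(5 * 50))
  expect_error(pearson_correlation(c(1, 1, 1), x[1:3]), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
  expect_error(pearson_correlation(1:4, 1:5), "lengths differ")
})

test_that("pearson_correlation is invariant to positive affine maps", {
  set.seed(44)
  for (rep in 1:8) {
    a <- rnorm(20); b <- rnorm(20)
    r <- pearson_correlation(a, b)
    expect_equal(pearson_correlation(2.5 * a + 7, b), r, tolerance = 1e-12)
    expect_equal(pearson_correlation(a, 0.3 * b - 2), r, tolerance = 1e-12)
    expect_equal(pearson_correlation(-a, b), -r, tolerance = 1e-12)
  }
})

test_that("cohen_kappa reproduces the closed form on a 2x2 contingency table", {
  # table [[20,5],[10,15]]: po = 35/50 = 0.7,
  # pe = 0.5*0.6 + 0.5*0.4 = 0.5, kappa = (0.7-0.5)/0.5 = 0.4
  truth <- rep(c("x", "x", "y", "y"), times = c(20, 5, 10, 15))
  pred <- rep(c("x", "y", "x", "y"), times = c(20, 5, 10, 15))
  expect_equal(cohen_kappa(pred, truth), 0.4)
})

test_that("kappa agrees with an independent implementation on random tables", {
  skip_if_not_installed("e1071")
  set.seed(17)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    n <- 200
    truth <- sample(letters[1:k], n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.6, truth, sample(letters[1:k], n, replace = TRUE))
    expect_equal(cohen_kappa(pred, truth),
                 e1071::classAgreement(table(pred, truth))$kappa,
                 tolerance = 1e-12)
  }
})

test_that("kappa is symmetric, relabeling-invariant, and 1 only for identity", {
  set.seed(23)
  truth <- sample(c("A", "B", "C"), 60, replace = TRUE)
  pred <- sample(c("A", "B", "C"), 60, replace = TRUE)
  expect_equal(cohen_kappa(pred, truth), cohen_kappa(truth, pred))
  relabel <- c(A = "Q", B = "R", C = "S")
  expect_equal(cohen_kappa(relabel[pred], relabel[truth]),
               cohen_kappa(pred, truth))
  expect_equal(cohen_kappa(truth, truth), 1)
  almost <- truth; almost[1] <- setdiff(c("A", "B", "C"), truth[1])[1]
  expect_lt(cohen_kappa(almost, truth), 1)
  expect_error(cohen_kappa(rep("A", 5), rep("A", 5)), "undefined")
})

test_that("kappa of an independent relabeling is near zero", {
  set.seed(3)
  truth <- sample(c("A", "B"), 4000, replace = TRUE, prob = c(.7, .3))
  pred <- sample(truth)  # marginals preserved, pairing destroyed
  expect_lt(abs(cohen_kappa(pred, truth)), 0.05)
})

test_that("a degenerate benchmark with a perfect learner hits the ceiling, deterministically", {
  scen <- benchmark_scenario(
    base_learners = list(method_spec("dummy_slope", data.frame(col = 1))),
    meta_learner = method_spec("linear"),
    n_train = 60, n_test = 60, p = 4, n_causal = 1, snr = 100, nfold = 3)
  r1 <- run_benchmark(scen, replicates = 2, seed = 5)
  expect_equal(nrow(r1), 4L)  # (stacking + 1 method) x 2 replicates
  expect_true(all(c("stacking", "dummy_slope") %in% r1$method))
  # n_causal = 1 has no interactions: Y = X1 + small noise, so the single-
  # feature regression and its stacking are both near the snr ceiling
  expect_true(all(r1$value > 0.98))
  r2 <- run_benchmark(scen, replicates = 2, seed = 5)
  expect_identical(r1, r2)
  s <- summary(r1)
  expect_setequal(s$method, c("stacking", "dummy_slope"))
})

test_that("a failing method marks its cells NA and the benchmark continues", {
  scen <- benchmark_scenario(
    base_learners = list(method_spec("dummy_slope", data.frame(col = 1)),
                         method_spec("dummy_broken")),
    meta_learner = method_spec("linear"),
    n_train = 40, n_test = 40, p = 3, n_causal = 1, snr = 50, nfold = 2)
  suppressWarnings(res <- run_benchmark(scen, replicates = 1, seed = 2))
  expect_true(is.na(res$value[res$method == "dummy_broken"]))
  expect_false(is.na(res$value[res$method == "stacking"]))
})
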