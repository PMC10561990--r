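# Deterministic toy adapters used across the suite. They make the stacking
# machinery's behaviour computable by hand: fits are closed-form, there is
# no RNG, and predictions depend on the training split in transparent ways.

register_learner("dummy_mean",
  fit = function(x, y, hyperparameters, seed) mean(y),
  predict = function(state, x) rep(state, nrow(x)),
  tasks = "regression")

# constant predictor: ignores the data entirely; hyperparameter `value`
register_learner("dummy_const",
  fit = function(x, y, hyperparameters, seed) hyperparameters$value,
  predict = function(state, x) rep(state, nrow(x)),
  tasks = "regression")

# least-squares on a single feature column (closed form, data-dependent)
register_learner("dummy_slope",
  fit = function(x, y, hyperparameters, seed) {
    j <- hyperparameters$col %||% 1L
    b <- stats::cov(x[, j], y) / stats::var(x[, j])
    c(a = mean(y) - b * mean(x[, j]), b = b, j = j)
  },
  predict = function(state, x) state["a"] + state["b"] * x[, state["j"]],
  tasks = "regression")

`%||%` <- function(a, b) if (is.null(a)) b else a

# modal training label, ties to the lexicographically smallest label
register_learner("dummy_mode",
  fit = function(x, y, hyperparameters, seed) {
    counts <- table(as.character(y))
    names(counts)[which.max(counts)]
  },
  predict = function(state, x) rep(state, nrow(x)),
  tasks = "classification")

# nearest class centroid on the feature means (deterministic, data-dependent)
register_learner("dummy_centroid",
  fit = function(x, y, hyperparameters, seed) {
    centroids <- do.call(rbind, lapply(split(seq_along(y), as.character(y)),
                                       function(i) colMeans(x[i, , drop = FALSE])))
    centroids
  },
  predict = function(state, x) {
    labs <- rownames(state)
    apply(x, 1L, function(row) {
      d <- rowSums(sweep(state, 2L, row)^2)
      labs[which.min(d)]
    })
  },
  tasks = "classification")

# always fails at fit time; exercises the failure policy
register_learner("dummy_broken",
  fit = function(x, y, hyperparameters, seed) stop("synthetic fit failure"),
  predict = function(state, x) stop("unreachable"))

make_dummy_regression <- function(n = 12, p = 4, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
  Y <- X[, 1] + 0.5 * X[, 2] + rnorm(n, sd = 0.1)
  list(X = X, Y = Y)
}
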