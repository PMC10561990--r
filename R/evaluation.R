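#' Pearson correlation between predictions and truth
#'
#' Standard product-moment correlation, the accuracy metric for regression
#' benchmarks. Zero variance in either argument is an error rather than a
#' silent zero.
#'
#' @param pred,truth Numeric vectors of equal length (at least 3).
#' @return Correlation in \[-1, 1\].
#' @export
pearson_correlation <- function(pred, truth) {
  pred <- as.numeric(pred); truth <- as.numeric(truth)
  if (length(pred) != length(truth)) stop("pred and truth lengths differ", call. = FALSE)
  if (length(pred) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(pred) || anyNA(truth)) stop("missing values in pred or truth", call. = FALSE)
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    stop("correlation undefined: zero variance in pred or truth", call. = FALSE)
  }
  stats::cor(pred, truth)
}

#' Cohen's kappa for categorical agreement
#'
#' Chance-corrected agreement kappa = (po - pe) / (1 - pe), where po is the
#' observed agreement rate and pe the agreement expected from the marginal
#' label frequencies of the two vectors. The label universe is the union of
#' observed labels. kappa = 1 iff the vectors are identical (with at least
#' two classes); independent labelings give kappa near 0.
#'
#' @param pred,truth Category vectors (factor or character) of equal length.
#' @return Kappa, at most 1.
#' @export
cohen_kappa <- function(pred, truth) {
  pred <- as.character(pred); truth <- as.character(truth)
  if (length(pred) != length(truth)) stop("pred and truth lengths differ", call. = FALSE)
  if (length(pred) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(pred) || anyNA(truth)) stop("missing values in pred or truth", call. = FALSE)
  labels <- sort(union(pred, truth))
  po <- mean(pred == truth)
  pe <- sum(vapply(labels, function(lab) mean(pred == lab) * mean(truth == lab), 0))
  if (pe >= 1) {
    stop("kappa undefined: both vectors constant with the same label", call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

metric_fn <- function(metric) {
  switch(metric,
         pearson_r = pearson_correlation,
         kappa = cohen_kappa,
         stop("unknown metric '", metric, "'", call. = FALSE))
}

#' Define a benchmark scenario
#'
#' Bundles a simulation design with a learner roster for
#' [run_benchmark()].
#'
#' @param base_learners List of [method_spec()] objects (the stacking roster
#'   and the standalone comparators).
#' @param meta_learner [method_spec()] for the stacking meta-learner.
#' @param n_train,n_test Sample sizes of the simulated training and test
#'   sets.
#' @param p,n_causal,snr Simulation design (see [simulate_regression()]).
#' @param nfold Cross-validation folds for stacking and for the
#'   comparators' hyperparameter selection.
#' @param task `"regression"` or `"classification"`.
#' @param n_classes Classes for classification scenarios.
#' @param train_each_fold Meta-training mode passed to [stack_train()].
#' @return A `benchmark_scenario` list.
#' @export
benchmark_scenario <- function(base_learners, meta_learner,
                               n_train = 400L, n_test = 400L, p = 100L,
                               n_causal = 20L, snr = 4, nfold = 5L,
                               task = c("regression", "classification"),
                               n_classes = 4L, train_each_fold = FALSE) {
  task <- match.arg(task)
  structure(list(base_learners = base_learners, meta_learner = meta_learner,
                 n_train = n_train, n_test = n_test, p = p,
                 n_causal = n_causal, snr = snr, nfold = nfold, task = task,
                 n_classes = n_classes, train_each_fold = train_each_fold,
                 metric = if (task == "regression") "pearson_r" else "kappa"),
            class = "benchmark_scenario")
}

# Standalone comparator: one method family fitted the ordinary way — pick
# the hyperparameter row by out-of-fold CV accuracy on the training set,
# refit that row on the full training data, predict the test set.
fit_standalone <- function(spec, train, test, nfold, task, seed) {
  metric <- if (task == "regression") pearson_correlation else cohen_kappa
  configs <- expand_base_learners(list(spec))
  Y <- as_response(train$Y, task)
  if (length(configs) > 1L) {
    folds <- assign_folds(nrow(train$X), nfold, seed)
    bt <- train_base_models(train$X, Y, folds, configs, task = task)
    scores <- vapply(seq_along(configs), function(l) {
      v <- bt$meta_features$values[, l]
      if (anyNA(v)) return(-Inf)
      tryCatch(metric(if (task == "regression") as.numeric(v) else v, Y),
               error = function(e) -Inf)
    }, 0)
    best <- configs[[which.max(scores)]]
  } else {
    best <- configs[[1L]]
  }
  adapter <- get_learner(best$method, task)
  sd <- cell_seed(seed, 0L, best$learner_index)
  set.seed(sd)
  state <- adapter$fit(train$X, Y, best$hyperparameters, sd)
  pred <- adapter$predict(state, test$X)
  metric(pred, as_response(test$Y, task))
}

#' Benchmark stacking against its base methods run standalone
#'
#' For each replicate, simulates fresh training and test data, trains the
#' full stacking pipeline, and additionally trains every base method
#' standalone on the full training set (its hyperparameter row chosen by
#' cross-validation on the training data when the spec has several rows).
#' The test-set metric (Pearson correlation for regression, Cohen's kappa
#' for classification) is recorded for every method and replicate; a method
#' failure marks its cell `NA` and the run continues.
#'
#' @param scenario A [benchmark_scenario()].
#' @param replicates Number of simulation replicates.
#' @param seed Integer master seed; replicate r derives its data and model
#'   seeds from it, and stacking and the comparators see identical data.
#' @param cores Worker processes for base-model fitting.
#' @return A `benchmark_result`: data frame with columns `replicate`,
#'   `method`, `metric`, `value`.
#' @export
run_benchmark <- function(scenario, replicates = 10L, seed = 1L, cores = 1L) {
  stopifnot(inherits(scenario, "benchmark_scenario"))
  metric_name <- scenario$metric
  simulate <- function(s) {
    if (scenario$task == "regression") {
      simulate_regression(scenario$n_train, scenario$p, scenario$n_causal,
                          scenario$snr, seed = s)
    } else {
      simulate_classification(scenario$n_train, scenario$p, scenario$n_causal,
                              scenario$n_classes, scenario$snr, seed = s)
    }
  }
  rows <- list()
  for (r in seq_len(replicates)) {
    seed_r <- as.integer((as.double(seed) + 7919 * r) %% .Machine$integer.max)
    train <- simulate(seed_r)
    test <- {
      sc <- scenario; s2 <- as.integer((seed_r + 3571) %% .Machine$integer.max)
      if (scenario$task == "regression") {
        simulate_regression(scenario$n_test, scenario$p, scenario$n_causal,
                            scenario$snr, seed = s2)
      } else {
        simulate_classification(scenario$n_test, scenario$p, scenario$n_causal,
                                scenario$n_classes, scenario$snr, seed = s2)
      }
    }
    met <- metric_fn(metric_name)
    stack_value <- tryCatch({
      fit <- stack_train(train$X, train$Y,
                         base_learners = scenario$base_learners,
                         meta_learner = scenario$meta_learner,
                         nfold = scenario$nfold,
                         train_each_fold = scenario$train_each_fold,
                         cores = cores, seed = seed_r, task = scenario$task)
      met(predict_stacking(test$X, fit), as_response(test$Y, scenario$task))
    }, error = function(e) {
      warning("stacking failed in replicate ", r, ": ", conditionMessage(e),
              call. = FALSE)
      NA_real_
    })
    rows[[length(rows) + 1L]] <- data.frame(
      replicate = r, method = "stacking", metric = metric_name,
      value = stack_value)
    for (spec in scenario$base_learners) {
      v <- tryCatch(
        fit_standalone(spec, train, test, scenario$nfold, scenario$task, seed_r),
        error = function(e) {
          warning("method '", spec$method, "' failed in replicate ", r, ": ",
                  conditionMessage(e), call. = FALSE)
          NA_real_
        })
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, method = spec$method, metric = metric_name, value = v)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("benchmark_result", "data.frame")
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Summarize a benchmark result
#'
#' @param object A `benchmark_result`.
#' @param ... Unused.
#' @return Data frame of per-method mean, sd, and replicate count, sorted by
#'   decreasing mean.
#' @export
summary.benchmark_result <- function(object, ...) {
  agg <- stats::aggregate(value ~ method, data = object,
                          FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                              sd = stats::sd(v)))
  out <- data.frame(method = agg$method,
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    replicates = as.vector(table(object$method)[agg$method]))
  out[order(-out$mean), ]
}

#' Built-in reduced regression benchmark scenario
#'
#' The package's default test bed: the simulation design at a reduced size
#' (400 training and 400 test samples, 100 features, 20 causal features,
#' signal-to-noise ratio 4) with a five-family base-learner roster on small
#' hyperparameter grids (random forest, gradient boosting, radial-kernel
#' SVM, elastic net, partial least squares; 12 base learners in all) and an
#' elastic-net meta-learner, 5-fold cross-validation. Used by the package's
#' own benchmark checks; pass overrides through `...` to
#' [benchmark_scenario()].
#'
#' @param ... Overrides for [benchmark_scenario()] arguments other than the
#'   learner roster.
#' @return A `benchmark_scenario`.
#' @export
default_regression_scenario <- function(...) {
  roster <- list(
    method_spec("random_forest", cartesian_grid(
      list(mtry = c(10, 33), num.trees = 300, min.node.size = 5))),
    method_spec("gradient_boosting", cartesian_grid(
      list(nrounds = 200, eta = c(0.05, 0.1), max_depth = 3, subsample = 0.8))),
    method_spec("svm_radial", cartesian_grid(list(C = c(1, 10), sigma = 0.01))),
    method_spec("elastic_net", cartesian_grid(
      list(alpha = c(0.5, 1), lambda = c(0.01, 0.1)))),
    method_spec("pls", cartesian_grid(list(ncomp = c(5, 20)))))
  meta <- method_spec("elastic_net", data.frame(alpha = 0.5))
  benchmark_scenario(roster, meta, n_train = 400L, n_test = 400L, p = 100L,
                     n_causal = 20L, snr = 4, nfold = 5L, ...)
}
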