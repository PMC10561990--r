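#' Train a stacked ensemble
#'
#' One-call interface to the full stacking training procedure: assign
#' cross-validation folds, fit every base learner on every fold complement,
#' collect out-of-fold predictions as meta-features, and train the
#' meta-learner on them (pooled across folds by default, or once per fold).
#' All fold models are kept; prediction averages over them rather than
#' refitting on the full data.
#'
#' @param X Numeric feature matrix (samples x features). Column names are
#'   retained and enforced at prediction time.
#' @param Y Response vector: numeric for regression, factor/character for
#'   classification (the task is inferred, or set via `task`).
#' @param base_learners List of [method_spec()] objects; each
#'   hyperparameter-table row is one base learner.
#' @param meta_learner A [method_spec()] naming the meta-learner (first row
#'   of its table used), or a method name string.
#' @param nfold Number of cross-validation folds (default 5).
#' @param train_each_fold `FALSE` (default): one pooled meta-fit; `TRUE`:
#'   one meta-fit per fold, averaged/voted at prediction.
#' @param which_to_use Indices of base learners used by the meta-learner;
#'   default all.
#' @param cores Worker processes for base-model fitting.
#' @param seed Integer seed controlling fold assignment and every model fit.
#' @param stratify For classification, stratify fold assignment by class
#'   (default `FALSE`).
#' @param task `"auto"` (default), `"regression"`, or `"classification"`.
#' @return An object of class `stacked_model`; use [predict_stacking()] or
#'   `predict()` on new data.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_regression(n = 120, p = 10, n_causal = 4, snr = 4, seed = 1)
#' fit <- stack_train(sim$X, sim$Y,
#'   base_learners = list(
#'     method_spec("elastic_net", data.frame(alpha = c(0.5, 1), lambda = 0.05)),
#'     method_spec("linear")),
#'   meta_learner = method_spec("linear"),
#'   nfold = 3, seed = 1)
#' new <- simulate_regression(n = 40, p = 10, n_causal = 4, snr = 4, seed = 2)
#' pearson_correlation(predict(fit, new$X), new$Y)
#' }
stack_train <- function(X, Y, base_learners, meta_learner, nfold = 5L,
                        train_each_fold = FALSE, which_to_use = NULL,
                        cores = 1L, seed = 1L, stratify = FALSE,
                        task = c("auto", "regression", "classification")) {
  task <- match.arg(task)
  if (task == "auto") task <- infer_task(Y)
  X <- check_xy(X, Y)
  Y <- as_response(Y, task)
  configs <- expand_base_learners(base_learners)
  folds <- assign_folds(nrow(X), nfold, seed,
                        stratify_labels = if (stratify && task == "classification") Y)
  bt <- train_base_models(X, Y, folds, configs, cores = cores, task = task)
  meta <- train_meta_model(bt$meta_features, Y, meta_learner,
                           train_each_fold = train_each_fold,
                           which_to_use = which_to_use)
  structure(list(base = bt$base,
                 meta = meta,
                 meta_features = bt$meta_features,
                 task = task,
                 feature_names = colnames(X),
                 nfold = folds$nfold,
                 seed = as.integer(seed),
                 manifest = run_manifest(configs, meta)),
            class = "stacked_model")
}

run_manifest <- function(configs, meta) {
  pkgs <- unique(c(vapply(configs, `[[`, "", "method"), meta$meta_method$method))
  list(package = "stackle",
       package_version = as.character(utils::packageVersion("stackle")),
       r_version = as.character(getRversion()),
       methods = pkgs,
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' @export
print.stacked_model <- function(x, ...) {
  L <- length(x$base$configs)
  cat("stacked_model (", x$task, ")\n", sep = "")
  cat("  base learners: ", L, " (",
      paste(unique(vapply(x$base$configs, `[[`, "", "method")), collapse = ", "),
      ")\n", sep = "")
  cat("  folds:", x$nfold, "-> fold models:", x$nfold * L, "\n")
  print(x$meta)
  if (nrow(x$base$failures)) {
    cat("  failed cells:", nrow(x$base$failures), "\n")
  }
  invisible(x)
}

#' Save / load a stacked model
#'
#' Serializes the complete model (fold models, meta-model, fold assignment,
#' configurations, and a manifest recording package and R versions) to a
#' single archive. Loading restores a model whose predictions are identical
#' to the original's.
#'
#' @param model A `stacked_model`.
#' @param path File path for the archive.
#' @return `save_stacked_model` returns `path` invisibly;
#'   `load_stacked_model` returns the restored `stacked_model`.
#' @export
save_stacked_model <- function(model, path) {
  stopifnot(inherits(model, "stacked_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_stacked_model
#' @export
load_stacked_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "stacked_model")) {
    stop("'", path, "' does not contain a stacked_model archive", call. = FALSE)
  }
  model
}
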