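# Adapter registry: maps method names to fit/predict adapters.
# Adapters are the pluggable boundary around third-party estimators; the
# stacking machinery itself never sees estimator internals.

.registry <- new.env(parent = emptyenv())

#' Register a base-learner adapter
#'
#' An adapter wraps one estimator family behind a uniform fit/predict
#' contract so that the stacking machinery can treat all learners alike.
#' `fit(x, y, hyperparameters, seed)` must return an opaque fitted state and
#' must honour `seed` so that refitting with the same arguments reproduces
#' the same state. `predict(state, x)` must return a numeric vector
#' (regression) or a character vector of class labels (classification) of
#' length `nrow(x)`.
#'
#' @param name Method name used in [method_spec()] and configuration files.
#' @param fit Function `(x, y, hyperparameters, seed)` returning a fitted
#'   state. `x` is a numeric matrix with column names, `y` a numeric vector
#'   (regression) or factor (classification), `hyperparameters` a named list
#'   holding one row of the method's hyperparameter table.
#' @param predict Function `(state, x)` returning predictions for the rows
#'   of `x`.
#' @param tasks Character vector, subset of `c("regression",
#'   "classification")`, naming the tasks the adapter supports.
#' @return `name`, invisibly.
#' @export
#' @examples
#' register_learner("grand_mean",
#'   fit = function(x, y, hyperparameters, seed) mean(y),
#'   predict = function(state, x) rep(state, nrow(x)),
#'   tasks = "regression")
#' "grand_mean" %in% registered_learners()
register_learner <- function(name, fit, predict, tasks = c("regression", "classification")) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.function(fit), is.function(predict))
  tasks <- match.arg(tasks, c("regression", "classification"), several.ok = TRUE)
  assign(name, list(name = name, fit = fit, predict = predict, tasks = tasks),
         envir = .registry)
  invisible(name)
}

#' List registered learner adapters
#'
#' @return Character vector of registered method names, sorted.
#' @export
registered_learners <- function() {
  sort(ls(envir = .registry))
}

#' Retrieve a registered adapter
#'
#' @param name Method name.
#' @param task Optional task; when given, an error is raised if the adapter
#'   does not support it.
#' @return The adapter, a list with elements `name`, `fit`, `predict`, `tasks`.
#' @export
get_learner <- function(name, task = NULL) {
  if (!is.character(name) || length(name) != 1L || !exists(name, envir = .registry)) {
    stop("unknown learner method '", name, "'; registered methods: ",
         paste(registered_learners(), collapse = ", "), call. = FALSE)
  }
  adapter <- get(name, envir = .registry)
  if (!is.null(task) && !task %in% adapter$tasks) {
    stop("learner '", name, "' does not support task '", task, "'", call. = FALSE)
  }
  adapter
}

require_pkg <- function(pkg, method) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop("learner '", method, "' needs package '", pkg, "', which is not installed",
         call. = FALSE)
  }
}

hp <- function(hyperparameters, name, default) {
  v <- hyperparameters[[name]]
  if (is.null(v)) default else v
}
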