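# Fold-wise base-learner training and out-of-fold meta-feature collection.
#
# For every (fold f, learner l) cell a model is fitted on all samples NOT in
# fold f; its predictions on fold f fill the out-of-fold meta-feature table.
# All Nfold x L cells are independent, so they can be trained in parallel;
# every cell seeds its own RNG from (global seed, f, l), which makes parallel
# and serial runs bit-identical.

cell_seed <- function(seed, fold, learner) {
  as.integer((as.double(seed) + 100003 * fold + 613 * learner) %% .Machine$integer.max)
}

check_xy <- function(X, Y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be a numeric matrix", call. = FALSE)
  if (anyNA(X)) stop("X contains missing values", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X))) stop("X has duplicate column names", call. = FALSE)
  if (nrow(X) != length(Y)) stop("nrow(X) must equal length(Y)", call. = FALSE)
  if (anyNA(Y)) stop("Y contains missing values", call. = FALSE)
  X
}

infer_task <- function(Y) {
  if (is.factor(Y) || is.character(Y) || is.logical(Y)) "classification" else "regression"
}

as_response <- function(Y, task) {
  if (task == "classification") factor(Y) else as.numeric(Y)
}

#' Train all base models fold-wise and collect out-of-fold meta-features
#'
#' Runs the cross-validation stage of stacking: for each of the L base
#' learners and each of the Nfold folds, fits the learner on the fold's
#' complement and predicts the held-out fold. The held-out predictions form
#' the n x L meta-feature table used to train the meta-learner; by
#' construction cell (i, l) was produced by a model that never saw sample i.
#'
#' A cell whose fit raises an error is recorded as failed and training
#' continues; its meta-feature entries are `NA`. A learner whose cells all
#' fail is dropped from the meta-feature table with a warning.
#'
#' @param X Numeric feature matrix, samples in rows.
#' @param Y Response: numeric vector (regression) or factor/character
#'   (classification).
#' @param folds A [assign_folds()] result for `nrow(X)` samples.
#' @param configs List of base-learner configurations from
#'   [expand_base_learners()].
#' @param cores Number of worker processes for fitting cells (forked via the
#'   parallel package; results are identical to `cores = 1`).
#' @param task `"regression"`, `"classification"`, or `"auto"` (inferred
#'   from `Y`).
#' @return List with components `base` (a `base_model_matrix`: the
#'   Nfold x L grid of fitted states plus metadata) and `meta_features` (a
#'   `meta_feature_table`).
#' @export
train_base_models <- function(X, Y, folds, configs, cores = 1L,
                              task = c("auto", "regression", "classification")) {
  task <- match.arg(task)
  if (task == "auto") task <- infer_task(Y)
  X <- check_xy(X, Y)
  Y <- as_response(Y, task)
  stopifnot(inherits(folds, "fold_assignment"),
            length(folds$fold_of_sample) == nrow(X))
  if (inherits(configs, "base_learner_config")) configs <- list(configs)
  if (length(configs) == 0L) stop("configs must be non-empty", call. = FALSE)
  if (cores < 1L) stop("cores must be at least 1", call. = FALSE)
  nfold <- folds$nfold
  L <- length(configs)
  n <- nrow(X)
  adapters <- lapply(configs, function(cf) get_learner(cf$method, task))

  cells <- expand.grid(fold = seq_len(nfold), learner = seq_len(L))
  fit_cell <- function(k) {
    f <- cells$fold[k]; l <- cells$learner[k]
    idx <- folds$fold_of_sample != f
    sd <- cell_seed(folds$seed, f, l)
    tryCatch({
      set.seed(sd)
      state <- adapters[[l]]$fit(X[idx, , drop = FALSE], Y[idx],
                                 configs[[l]]$hyperparameters, sd)
      oof <- adapters[[l]]$predict(state, X[!idx, , drop = FALSE])
      list(ok = TRUE, state = state, oof = oof)
    }, error = function(e) {
      list(ok = FALSE, message = conditionMessage(e))
    })
  }
  results <- if (cores > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(nrow(cells)), fit_cell, mc.cores = cores,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(nrow(cells)), fit_cell)
  }

  models <- matrix(vector("list", nfold * L), nrow = nfold, ncol = L)
  values <- matrix(if (task == "regression") NA_real_ else NA_character_,
                   nrow = n, ncol = L)
  failures <- data.frame(fold = integer(), learner = integer(),
                         method = character(), message = character())
  for (k in seq_len(nrow(cells))) {
    f <- cells$fold[k]; l <- cells$learner[k]
    r <- results[[k]]
    if (isTRUE(r$ok)) {
      models[[f, l]] <- r$state
      values[folds$fold_of_sample == f, l] <- r$oof
    } else {
      models[[f, l]] <- structure(list(message = r$message), class = "stackle_fit_failure")
      failures <- rbind(failures, data.frame(
        fold = f, learner = l, method = configs[[l]]$method,
        message = r$message))
    }
  }
  dropped <- integer()
  for (l in seq_len(L)) {
    if (sum(failures$learner == l) == nfold) {
      dropped <- c(dropped, l)
    }
  }
  if (length(dropped)) {
    warning("all ", nfold, " fold fits failed for learner(s) ",
            paste(vapply(configs[dropped], `[[`, "", "label"), collapse = ", "),
            "; dropped from the meta-feature table", call. = FALSE)
  }
  colnames(values) <- vapply(configs, function(cf) paste0("L", cf$learner_index), "")
  base <- structure(list(models = models, configs = configs, folds = folds,
                         task = task, feature_names = colnames(X),
                         failures = failures,
                         y_levels = if (task == "classification") levels(Y) else NULL),
                    class = "base_model_matrix")
  meta <- structure(list(values = values, fold_of_row = folds$fold_of_sample,
                         configs = configs, task = task,
                         dropped_learners = dropped, seed = folds$seed,
                         y_levels = base$y_levels),
                    class = "meta_feature_table")
  list(base = base, meta_features = meta)
}

#' @export
print.base_model_matrix <- function(x, ...) {
  cat("base_model_matrix:", x$folds$nfold, "folds x", length(x$configs),
      "learners =", x$folds$nfold * length(x$configs), "fitted cells (",
      nrow(x$failures), "failed )\n")
  invisible(x)
}

#' @export
print.meta_feature_table <- function(x, ...) {
  cat("meta_feature_table:", nrow(x$values), "samples x", ncol(x$values),
      "learners (", x$task, ")\n")
  invisible(x)
}
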