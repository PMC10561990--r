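# Meta-learner stage: the out-of-fold prediction table becomes the design
# matrix of a second-stage model. Regression meta-features pass through as
# numbers; classification meta-features are predicted class labels, expanded
# to indicator columns (reference level dropped) with the level set frozen
# at training time.

#' Build the meta-learner design matrix from out-of-fold predictions
#'
#' Selects the requested learner columns of a meta-feature table and encodes
#' them for the meta-learner. For regression the values pass through
#' unchanged. For classification each learner column is treated as a
#' categorical variable over the response's level set: each level except the
#' first (reference) becomes a 0/1 indicator column. Labels outside the
#' frozen level set encode as all zeros with a warning.
#'
#' @param meta_features A `meta_feature_table` from [train_base_models()],
#'   or a plain matrix (numeric, or character labels) for classification
#'   with `y_levels` supplied.
#' @param which_to_use Integer vector of learner column indices (1-based).
#'   Defaults to all columns.
#' @param task `"regression"` or `"classification"`; taken from the table
#'   when available.
#' @param y_levels Frozen label set for classification encoding; taken from
#'   the table when available.
#' @return Numeric design matrix with `length(which_to_use)` (regression) or
#'   `length(which_to_use) * (nlevels - 1)` (classification) columns.
#' @export
build_meta_design <- function(meta_features, which_to_use = NULL, task = NULL,
                              y_levels = NULL) {
  if (inherits(meta_features, "meta_feature_table")) {
    values <- meta_features$values
    if (is.null(task)) task <- meta_features$task
    if (is.null(y_levels)) y_levels <- meta_features$y_levels
  } else {
    values <- as.matrix(meta_features)
    if (is.null(task)) task <- if (is.numeric(values)) "regression" else "classification"
  }
  L <- ncol(values)
  if (is.null(which_to_use)) which_to_use <- seq_len(L)
  which_to_use <- as.integer(which_to_use)
  if (length(which_to_use) == 0L) stop("which_to_use must be non-empty", call. = FALSE)
  if (anyDuplicated(which_to_use) || any(which_to_use < 1L | which_to_use > L)) {
    stop("which_to_use must be duplicate-free indices in 1..", L, call. = FALSE)
  }
  sel <- values[, which_to_use, drop = FALSE]
  if (task == "regression") {
    storage.mode(sel) <- "double"
    colnames(sel) <- paste0("L", which_to_use)
    return(sel)
  }
  if (is.null(y_levels)) stop("y_levels required for classification encoding", call. = FALSE)
  if (length(y_levels) < 2L) stop("classification needs at least 2 levels", call. = FALSE)
  cols <- vector("list", length(which_to_use))
  unseen <- FALSE
  for (j in seq_along(which_to_use)) {
    lab <- sel[, j]
    known <- is.na(lab) | lab %in% y_levels
    if (!all(known)) unseen <- TRUE
    ind <- matrix(0, nrow = nrow(sel), ncol = length(y_levels) - 1L)
    colnames(ind) <- paste0("L", which_to_use[j], ".", y_levels[-1L])
    for (k in seq_along(y_levels[-1L])) {
      ind[, k] <- as.numeric(!is.na(lab) & lab == y_levels[-1L][k])
    }
    ind[is.na(lab), ] <- NA_real_
    cols[[j]] <- ind
  }
  if (unseen) {
    warning("meta-feature labels outside the training level set encoded as all-zero",
            call. = FALSE)
  }
  do.call(cbind, cols)
}

#' Train the meta-learner on out-of-fold base-learner predictions
#'
#' Two modes are supported. Pooled (`train_each_fold = FALSE`, the default):
#' the meta-learner is fitted once on all n out-of-fold rows. Per-fold
#' (`train_each_fold = TRUE`): one meta-model is fitted per fold, each using
#' only the rows belonging to that fold; at prediction time the per-fold
#' meta predictions are averaged (regression) or majority-voted
#' (classification).
#'
#' Learner columns containing failed (NA) cells cannot enter the design;
#' they are removed from `which_to_use` with a warning.
#'
#' @param meta_features `meta_feature_table` from [train_base_models()].
#' @param Y Training response aligned with the table rows.
#' @param meta_method A [method_spec()] (its first hyperparameter row is
#'   used) naming the meta-learner.
#' @param train_each_fold Logical mode switch, default `FALSE` (pooled).
#' @param which_to_use Learner column indices used as meta-features;
#'   default all.
#' @return An object of class `meta_model`.
#' @export
train_meta_model <- function(meta_features, Y, meta_method,
                             train_each_fold = FALSE, which_to_use = NULL) {
  stopifnot(inherits(meta_features, "meta_feature_table"))
  task <- meta_features$task
  Y <- as_response(Y, task)
  if (length(Y) != nrow(meta_features$values)) {
    stop("Y must align with the meta-feature rows", call. = FALSE)
  }
  if (inherits(meta_method, "method_spec")) {
    meta_config <- expand_base_learners(list(meta_method))[[1L]]
  } else if (inherits(meta_method, "base_learner_config")) {
    meta_config <- meta_method
  } else if (is.character(meta_method) && length(meta_method) == 1L) {
    meta_config <- expand_base_learners(list(method_spec(meta_method)))[[1L]]
  } else {
    stop("meta_method must be a method_spec, base_learner_config, or method name",
         call. = FALSE)
  }
  adapter <- get_learner(meta_config$method, task)
  L <- ncol(meta_features$values)
  if (is.null(which_to_use)) which_to_use <- seq_len(L)
  which_to_use <- setdiff(as.integer(which_to_use), meta_features$dropped_learners)
  bad <- which_to_use[apply(meta_features$values[, which_to_use, drop = FALSE], 2, anyNA)]
  if (length(bad)) {
    warning("learner column(s) ", paste0("L", bad, collapse = ", "),
            " contain failed out-of-fold cells; excluded from the meta design",
            call. = FALSE)
    which_to_use <- setdiff(which_to_use, bad)
  }
  if (length(which_to_use) == 0L) {
    stop("no usable learner columns remain for the meta-learner", call. = FALSE)
  }
  design <- build_meta_design(meta_features, which_to_use)
  fold_of_row <- meta_features$fold_of_row
  seed0 <- cell_seed(meta_features$seed %||% 0L, 0L, 0L)

  fit_one <- function(rows, tag) {
    if (length(rows) <= ncol(design)) {
      # not fatal for all methods, but warn when a per-fold slice is thin
      if (length(rows) < 2L) {
        stop("fold ", tag, " has too few rows (", length(rows),
             ") to train the meta-learner", call. = FALSE)
      }
    }
    sd <- cell_seed(seed0, tag, 0L)
    set.seed(sd)
    adapter$fit(design[rows, , drop = FALSE], Y[rows],
                meta_config$hyperparameters, sd)
  }
  if (isTRUE(train_each_fold)) {
    nfold <- max(fold_of_row)
    states <- lapply(seq_len(nfold), function(f) fit_one(which(fold_of_row == f), f))
  } else {
    states <- list(fit_one(seq_along(Y), 0L))
  }
  structure(list(fitted_states = states,
                 meta_method = meta_config,
                 train_each_fold = isTRUE(train_each_fold),
                 which_to_use = which_to_use,
                 task = task,
                 y_levels = meta_features$y_levels),
            class = "meta_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.meta_model <- function(x, ...) {
  cat("meta_model:", x$meta_method$label,
      if (x$train_each_fold) paste0("(", length(x$fitted_states), " per-fold fits)")
      else "(pooled fit)",
      "on", length(x$which_to_use), "learner column(s)\n")
  invisible(x)
}
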