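# Prediction path: new samples flow through every fold model of every base
# learner, predictions are aggregated per learner (mean for regression,
# modal category for classification), and the aggregated table is encoded
# exactly as at training time and fed to the meta-model(s).

align_features <- function(newX, feature_names) {
  if (!is.matrix(newX)) newX <- as.matrix(newX)
  if (is.null(colnames(newX))) {
    if (ncol(newX) == length(feature_names)) {
      colnames(newX) <- feature_names
    } else {
      stop("newX has no column names and its width (", ncol(newX),
           ") does not match the training features (", length(feature_names), ")",
           call. = FALSE)
    }
  }
  missing <- setdiff(feature_names, colnames(newX))
  extra <- setdiff(colnames(newX), feature_names)
  if (length(missing) || length(extra)) {
    stop("newX columns do not match training features; missing: [",
         paste(missing, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  }
  newX[, feature_names, drop = FALSE]
}

#' Raw predictions of every fold model of every base learner
#'
#' Feeds `newX` to all Nfold x L fitted base models. Columns are grouped by
#' learner, folds within learner (`L<l>.f<f>`). Failed cells yield NA
#' columns.
#'
#' @param newX Numeric matrix of new samples; columns are matched to the
#'   training features by name (order is normalized, mismatches rejected).
#' @param base A `base_model_matrix` from [train_base_models()].
#' @return m x (Nfold*L) matrix, numeric (regression) or character labels
#'   (classification).
#' @export
predict_base <- function(newX, base) {
  stopifnot(inherits(base, "base_model_matrix"))
  newX <- align_features(newX, base$feature_names)
  nfold <- base$folds$nfold
  L <- length(base$configs)
  m <- nrow(newX)
  out <- matrix(if (base$task == "regression") NA_real_ else NA_character_,
                nrow = m, ncol = nfold * L)
  cn <- character(nfold * L)
  k <- 0L
  for (l in seq_len(L)) {
    adapter <- get_learner(base$configs[[l]]$method, base$task)
    for (f in seq_len(nfold)) {
      k <- k + 1L
      cn[k] <- paste0("L", l, ".f", f)
      state <- base$models[[f, l]]
      if (!inherits(state, "stackle_fit_failure") && m > 0L) {
        out[, k] <- adapter$predict(state, newX)
      }
    }
  }
  colnames(out) <- cn
  out
}

modal_label <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L) return(NA_character_)
  counts <- table(labels)
  # ties broken by lexicographically smallest label (table is sorted)
  names(counts)[which.max(counts)]
}

#' Aggregate fold-model predictions per base learner
#'
#' Collapses the Nfold fold-model predictions of each learner to one value
#' per sample: the arithmetic mean for regression, the most frequent
#' category for classification (ties broken by the lexicographically
#' smallest label). Failed cells are skipped; a learner whose cells all
#' failed yields an NA column.
#'
#' @param raw Output of [predict_base()], columns grouped by learner.
#' @param task `"regression"` or `"classification"`; inferred from `raw`'s
#'   storage mode when omitted.
#' @param nfold Number of folds per learner; inferred from column names of
#'   the form `L<l>.f<f>` when omitted.
#' @return m x L matrix of aggregated predictions, columns `L1..LL`.
#' @export
aggregate_per_learner <- function(raw, task = NULL, nfold = NULL) {
  if (is.null(task)) task <- if (is.numeric(raw)) "regression" else "classification"
  if (is.null(nfold)) {
    f_ids <- sub("^L[0-9]+\\.f", "", colnames(raw))
    nfold <- max(as.integer(f_ids))
  }
  if (ncol(raw) %% nfold != 0L) {
    stop("raw prediction columns (", ncol(raw), ") not a multiple of nfold (",
         nfold, ")", call. = FALSE)
  }
  L <- ncol(raw) %/% nfold
  out <- matrix(if (task == "regression") NA_real_ else NA_character_,
                nrow = nrow(raw), ncol = L)
  for (l in seq_len(L)) {
    block <- raw[, (l - 1L) * nfold + seq_len(nfold), drop = FALSE]
    if (task == "regression") {
      out[, l] <- rowMeans(block, na.rm = TRUE)
      out[is.nan(out[, l]), l] <- NA_real_
    } else {
      out[, l] <- apply(block, 1L, modal_label)
    }
  }
  colnames(out) <- paste0("L", seq_len(L))
  out
}

predict_meta <- function(meta, design) {
  adapter <- get_learner(meta$meta_method$method, meta$task)
  preds <- lapply(meta$fitted_states, function(s) adapter$predict(s, design))
  if (length(preds) == 1L) {
    p <- preds[[1L]]
  } else if (meta$task == "regression") {
    p <- rowMeans(do.call(cbind, preds))
  } else {
    mat <- do.call(cbind, preds)
    p <- apply(mat, 1L, modal_label)
  }
  if (meta$task == "classification") factor(p, levels = meta$y_levels) else as.numeric(p)
}

#' Predict new samples with a stacked model
#'
#' Runs the full prediction chain: every fold model of every base learner
#' predicts `newX`; predictions are aggregated per learner (mean / modal
#' category); the aggregated table is encoded as at training time and fed
#' to the meta-model. With per-fold meta-training, the Nfold meta
#' predictions are averaged (regression) or majority-voted
#' (classification).
#'
#' @param newX Numeric matrix of new samples (feature columns matched by
#'   name to the training matrix).
#' @param model A `stacked_model` from [stack_train()].
#' @param return_meta_features If `TRUE`, also return the per-learner
#'   aggregated prediction table.
#' @return Numeric vector (regression) or factor (classification) of length
#'   `nrow(newX)`; with `return_meta_features = TRUE`, a list with
#'   `predictions` and `meta_features`.
#' @export
predict_stacking <- function(newX, model, return_meta_features = FALSE) {
  stopifnot(inherits(model, "stacked_model"))
  raw <- predict_base(newX, model$base)
  agg <- aggregate_per_learner(raw, task = model$task, nfold = model$base$folds$nfold)
  failed <- which(apply(agg, 2L, function(col) all(is.na(col))))
  if (length(intersect(failed, model$meta$which_to_use)) && nrow(agg) > 0L) {
    stop("learner(s) ", paste0("L", intersect(failed, model$meta$which_to_use),
                               collapse = ", "),
         " required by the meta-model produced no predictions", call. = FALSE)
  }
  design <- build_meta_design(agg, model$meta$which_to_use,
                              task = model$task, y_levels = model$meta$y_levels)
  p <- if (nrow(newX) == 0L) {
    if (model$task == "classification") factor(character(), levels = model$meta$y_levels)
    else numeric()
  } else {
    predict_meta(model$meta, design)
  }
  if (return_meta_features) list(predictions = p, meta_features = agg) else p
}

#' @export
predict.stacked_model <- function(object, newX, ...) {
  predict_stacking(newX, object, ...)
}
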