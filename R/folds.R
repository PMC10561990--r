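#' Assign samples to cross-validation folds
#'
#' Produces a reproducible random partition of `n` samples into `nfold`
#' disjoint folds whose sizes differ by at most one. When `stratify_labels`
#' is supplied, samples are dealt to folds within each label so that class
#' frequencies are approximately preserved per fold while overall fold
#' sizes still differ by at most one.
#'
#' @param n Number of samples.
#' @param nfold Number of folds, between 2 and `n`.
#' @param seed Integer seed; the assignment is a pure function of
#'   `(n, nfold, seed, stratify_labels)`.
#' @param stratify_labels Optional length-`n` vector of class labels.
#' @return An object of class `fold_assignment`: list with
#'   `fold_of_sample` (length-`n` integer vector of fold ids in `1:nfold`),
#'   `nfold`, and `seed`.
#' @export
#' @examples
#' f <- assign_folds(11, 5, seed = 1)
#' table(f$fold_of_sample)
assign_folds <- function(n, nfold, seed, stratify_labels = NULL) {
  stopifnot(length(n) == 1L, length(nfold) == 1L)
  n <- as.integer(n); nfold <- as.integer(nfold)
  if (is.na(nfold) || nfold < 2L) stop("nfold must be at least 2", call. = FALSE)
  if (nfold > n) stop("nfold (", nfold, ") exceeds the number of samples (", n, ")",
                      call. = FALSE)
  set.seed(as.integer(seed))
  fold <- integer(n)
  if (is.null(stratify_labels)) {
    fold <- sample(rep_len(seq_len(nfold), n))
  } else {
    if (length(stratify_labels) != n) {
      stop("stratify_labels must have length n", call. = FALSE)
    }
    # Deal fold ids cyclically over samples ordered by label (shuffled within
    # label, labels visited in random block order): per-class balance and
    # overall fold sizes differing by at most one.
    groups <- split(seq_len(n), as.character(stratify_labels))
    groups <- groups[sample(length(groups))]
    order <- unlist(lapply(groups, function(g) g[sample.int(length(g))]),
                    use.names = FALSE)
    start <- sample.int(nfold, 1L)
    ids <- ((start - 1L + seq_len(n) - 1L) %% nfold) + 1L
    fold[order] <- ids
  }
  structure(list(fold_of_sample = as.integer(fold), nfold = nfold,
                 seed = as.integer(seed)),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat("fold_assignment:", length(x$fold_of_sample), "samples in", x$nfold,
      "folds (seed", paste0(x$seed, ")"), "\n")
  print(table(fold = x$fold_of_sample))
  invisible(x)
}
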