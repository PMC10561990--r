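#' Declare a base-learner method with its hyperparameter table
#'
#' A method spec pairs a registered method name with a table of
#' hyperparameter settings. Every ROW of the table is one complete setting
#' and therefore one base learner; a method with G rows contributes G
#' members to the ensemble. Use [cartesian_grid()] to build a table holding
#' all combinations of per-parameter value lists.
#'
#' @param method Registered method name (see [registered_learners()]).
#' @param grid Data frame of hyperparameter settings, one row per base
#'   learner. A named list is accepted and converted. Defaults to a single
#'   all-default setting (a 1-row, 0-column table).
#' @return An object of class `method_spec`.
#' @seealso [expand_base_learners()], [cartesian_grid()]
#' @export
#' @examples
#' method_spec("elastic_net", cartesian_grid(list(alpha = c(0, 0.5, 1), lambda = 0.1)))
method_spec <- function(method, grid = NULL) {
  stopifnot(is.character(method), length(method) == 1L)
  get_learner(method)  # fails early on unknown methods
  if (is.null(grid)) grid <- data.frame(row.names = 1L)
  if (!is.data.frame(grid)) grid <- as.data.frame(grid, stringsAsFactors = FALSE)
  if (nrow(grid) < 1L) {
    stop("hyperparameter table for '", method, "' must have at least one row",
         call. = FALSE)
  }
  if (ncol(grid) > 0L && anyDuplicated(grid)) {
    stop("hyperparameter table for '", method, "' contains duplicate rows",
         call. = FALSE)
  }
  structure(list(method = method, grid = grid), class = "method_spec")
}

#' @export
print.method_spec <- function(x, ...) {
  cat("method_spec:", x$method, "with", nrow(x$grid), "setting(s)\n")
  if (ncol(x$grid) > 0L) print(x$grid)
  invisible(x)
}

#' All combinations of hyperparameter values
#'
#' Builds the full Cartesian product of per-parameter value lists, so that
#' multiple values given for several hyperparameters become one row per
#' combination — each row then counts as a distinct base learner when the
#' table is passed to [method_spec()].
#'
#' @param per_parameter_values Named list mapping hyperparameter names to
#'   non-empty vectors of candidate values.
#' @return Data frame with one row per combination. Row order is
#'   lexicographic in the order the parameters are given: the last parameter
#'   varies fastest.
#' @export
#' @examples
#' cartesian_grid(list(mtry = c(2, 4), num.trees = c(100, 500)))
cartesian_grid <- function(per_parameter_values) {
  if (!is.list(per_parameter_values) || length(per_parameter_values) == 0L ||
      is.null(names(per_parameter_values)) || any(!nzchar(names(per_parameter_values)))) {
    stop("per_parameter_values must be a non-empty named list", call. = FALSE)
  }
  lens <- lengths(per_parameter_values)
  if (any(lens == 0L)) {
    stop("empty value list for hyperparameter(s): ",
         paste(names(per_parameter_values)[lens == 0L], collapse = ", "),
         call. = FALSE)
  }
  # expand.grid varies the FIRST factor fastest; reverse twice to get
  # lexicographic order in the given parameter order.
  g <- expand.grid(rev(per_parameter_values),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(g)), drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Expand method specs into the ordered list of base learners
#'
#' Flattens a list of [method_spec()] objects into one configuration per
#' hyperparameter-table row, preserving spec order and then row order. The
#' total number of configurations L is the sum of the row counts, and each
#' configuration's `learner_index` (1-based) is its column position in the
#' out-of-fold meta-feature table.
#'
#' @param specs A `method_spec` or list of them.
#' @return List of `base_learner_config` objects, each with elements
#'   `method`, `hyperparameters` (named list, possibly empty),
#'   `learner_index`, and `label`.
#' @export
#' @examples
#' specs <- list(
#'   method_spec("random_forest", data.frame(mtry = c(2, 5))),
#'   method_spec("elastic_net", data.frame(alpha = 1, lambda = 0.1)))
#' length(expand_base_learners(specs))  # 3
expand_base_learners <- function(specs) {
  if (inherits(specs, "method_spec")) specs <- list(specs)
  if (!is.list(specs) || length(specs) == 0L) {
    stop("specs must be a non-empty list of method_spec objects", call. = FALSE)
  }
  specs <- lapply(specs, function(s) {
    if (!inherits(s, "method_spec")) {
      stop("every element of specs must be a method_spec", call. = FALSE)
    }
    s
  })
  configs <- list()
  idx <- 0L
  for (s in specs) {
    for (r in seq_len(nrow(s$grid))) {
      idx <- idx + 1L
      hyper <- as.list(s$grid[r, , drop = FALSE])
      names(hyper) <- colnames(s$grid)
      configs[[idx]] <- structure(
        list(method = s$method,
             hyperparameters = hyper,
             learner_index = idx,
             label = if (nrow(s$grid) > 1L) paste0(s$method, "#", r) else s$method),
        class = "base_learner_config")
    }
  }
  configs
}

#' @export
print.base_learner_config <- function(x, ...) {
  cat(sprintf("base learner %d: %s\n", x$learner_index, x$label))
  if (length(x$hyperparameters)) {
    cat("  ", paste(names(x$hyperparameters),
                    vapply(x$hyperparameters, format, ""), sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
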