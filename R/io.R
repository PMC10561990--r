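# Delimited-matrix I/O and run-configuration parsing. CSV dialect: comma
# separator, '.' decimal, mandatory header, UTF-8; a non-numeric first
# column is treated as the sample identifier.

#' Read a numeric matrix from CSV
#'
#' Reads a rectangular CSV with a header row. When the first column is
#' non-numeric it is used as row (sample) identifiers. Missing or
#' non-numeric cells are rejected with their (row, column) location. Set
#' `categorical = TRUE` for single-column class-label responses.
#'
#' @param path CSV file path.
#' @param categorical If `TRUE`, return character labels instead of
#'   numbers (for classification responses).
#' @return Matrix with column names (and row names when an identifier
#'   column is present); character matrix when `categorical = TRUE`.
#' @export
read_matrix <- function(path, categorical = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) == 0L) stop("no columns in ", path, call. = FALSE)
  if (anyDuplicated(colnames(df))) {
    stop("duplicate column names in ", path, ": ",
         paste(unique(colnames(df)[duplicated(colnames(df))]), collapse = ", "),
         call. = FALSE)
  }
  row_ids <- NULL
  first <- df[[1L]]
  if (ncol(df) > 1L && (is.character(first) || is.factor(first)) && !categorical) {
    row_ids <- as.character(first)
    df <- df[, -1L, drop = FALSE]
  }
  if (categorical) {
    if (ncol(df) > 1L && (is.character(df[[1L]]) || is.factor(df[[1L]]))) {
      # identifier column followed by the label column
      maybe_labels <- df[, -1L, drop = FALSE]
      if (ncol(maybe_labels) == 1L) {
        row_ids <- as.character(df[[1L]])
        df <- maybe_labels
      }
    }
    m <- as.matrix(df)
    storage.mode(m) <- "character"
  } else {
    for (j in seq_along(df)) {
      v <- df[[j]]
      if (!is.numeric(v)) {
        suppressWarnings(vn <- as.numeric(as.character(v)))
        bad <- which(is.na(vn) & !is.na(v) & as.character(v) != "NA")
        if (length(bad)) {
          stop("non-numeric cell at row ", bad[1L], ", column '",
               colnames(df)[j], "' in ", path, call. = FALSE)
        }
        df[[j]] <- vn
      }
    }
    m <- as.matrix(df)
  }
  na <- which(is.na(m), arr.ind = TRUE)
  if (nrow(na)) {
    stop("missing value at row ", na[1L, 1L], ", column '",
         colnames(m)[na[1L, 2L]], "' in ", path, call. = FALSE)
  }
  if (!is.null(row_ids)) rownames(m) <- row_ids
  m
}

#' Write a matrix to CSV at full precision
#'
#' Numeric values are serialized with 17 significant digits so that a
#' read/write round trip through [read_matrix()] is bitwise exact for
#' doubles.
#'
#' @param x Matrix (numeric or character).
#' @param path Output CSV path.
#' @param id_column Name for the identifier column when `x` has row names.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, id_column = "sample") {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  fmt_cell <- function(v) {
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
  }
  body <- apply(x, 2L, fmt_cell)
  if (!is.matrix(body)) body <- matrix(body, nrow = nrow(x))
  header <- colnames(x)
  if (!is.null(rownames(x))) {
    body <- cbind(rownames(x), body)
    header <- c(id_column, header)
  }
  lines <- c(paste(header, collapse = ","),
             apply(body, 1L, paste, collapse = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Parse and validate a run configuration
#'
#' Reads a YAML configuration describing the base learners, meta-learner,
#' and run settings, applies defaults (`nfold = 5`,
#' `train_each_fold = false`, `which_to_use` = all learners, `seed = 1`,
#' `cores = 1`), and resolves every method name against the adapter
#' registry. Each base learner entry names a `method` and either `grid:`
#' (per-parameter value lists, expanded to all combinations) or `rows:`
#' (explicit settings, one per base learner); both may be omitted for an
#' all-defaults single setting.
#'
#' @param path Path to a YAML file, or `text` given directly.
#' @param text YAML text (alternative to `path`).
#' @return A `run_config`: list with `base_learners` (list of
#'   [method_spec()]), `meta_learner`, `nfold`, `train_each_fold`,
#'   `which_to_use`, `seed`, `cores`, `task`.
#' @export
validate_config <- function(path = NULL, text = NULL) {
  raw <- if (!is.null(text)) yaml::yaml.load(text) else {
    if (is.null(path) || !file.exists(path)) {
      stop("config file not found: ", path, call. = FALSE)
    }
    yaml::read_yaml(path)
  }
  fail <- function(key, why) {
    stop("invalid configuration: '", key, "' ", why, call. = FALSE)
  }
  if (is.null(raw$base_learners) || length(raw$base_learners) == 0L) {
    fail("base_learners", "must list at least one learner")
  }
  parse_spec <- function(entry, key) {
    if (is.null(entry$method)) fail(key, "entry is missing 'method'")
    if (!entry$method %in% registered_learners()) {
      fail(key, paste0("names unknown method '", entry$method, "'"))
    }
    grid <- if (!is.null(entry$grid)) {
      if (length(entry$grid) == 0L) fail(key, "has an empty 'grid'")
      cartesian_grid(entry$grid)
    } else if (!is.null(entry$rows)) {
      if (length(entry$rows) == 0L) fail(key, "has empty 'rows'")
      do.call(rbind, lapply(entry$rows, function(r) as.data.frame(r)))
    } else {
      NULL
    }
    method_spec(entry$method, grid)
  }
  base_learners <- lapply(seq_along(raw$base_learners), function(i) {
    parse_spec(raw$base_learners[[i]], paste0("base_learners[", i, "]"))
  })
  if (is.null(raw$meta_learner)) fail("meta_learner", "is required")
  meta_learner <- parse_spec(raw$meta_learner, "meta_learner")
  nfold <- raw$nfold %||% 5L
  if (!is.numeric(nfold) || length(nfold) != 1L || nfold < 2L) {
    fail("nfold", "must be a single integer of at least 2")
  }
  tef <- raw$train_each_fold %||% FALSE
  if (!is.logical(tef) || length(tef) != 1L) fail("train_each_fold", "must be true/false")
  task <- raw$task %||% "auto"
  if (!task %in% c("auto", "regression", "classification")) {
    fail("task", "must be auto, regression, or classification")
  }
  L <- sum(vapply(base_learners, function(s) nrow(s$grid), 0L))
  wtu <- raw$which_to_use %||% seq_len(L)
  wtu <- as.integer(wtu)
  if (length(wtu) == 0L || anyNA(wtu) || anyDuplicated(wtu) ||
      any(wtu < 1L | wtu > L)) {
    fail("which_to_use", paste0("must be duplicate-free indices in 1..", L))
  }
  seed <- raw$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1L) fail("seed", "must be a single integer")
  cores <- raw$cores %||% 1L
  if (!is.numeric(cores) || length(cores) != 1L || cores < 1L) {
    fail("cores", "must be a single integer of at least 1")
  }
  structure(list(base_learners = base_learners, meta_learner = meta_learner,
                 nfold = as.integer(nfold), train_each_fold = tef,
                 which_to_use = wtu, seed = as.integer(seed),
                 cores = as.integer(cores), task = task),
            class = "run_config")
}

#' Train a stacked model from a run configuration
#'
#' Convenience wrapper: applies a validated configuration to data.
#'
#' @param X,Y Training data (see [stack_train()]).
#' @param config A `run_config` from [validate_config()].
#' @return A `stacked_model`.
#' @export
stack_train_config <- function(X, Y, config) {
  stopifnot(inherits(config, "run_config"))
  stack_train(X, Y,
              base_learners = config$base_learners,
              meta_learner = config$meta_learner,
              nfold = config$nfold,
              train_each_fold = config$train_each_fold,
              which_to_use = config$which_to_use,
              cores = config$cores,
              seed = config$seed,
              task = config$task)
}
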