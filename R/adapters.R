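# Default adapters for the method families the package targets:
# random forests, gradient boosting, support vector machines (radial and
# polynomial kernels), elastic nets, partial least squares, and plain
# linear baselines. Each adapter passes hyperparameter names through to the
# backing package verbatim; there is no translation layer, so the backing
# package's documentation is the authority on admissible names.

adapter_random_forest <- function() {
  list(
    fit = function(x, y, hyperparameters, seed) {
      require_pkg("ranger", "random_forest")
      args <- c(list(x = x, y = y, seed = seed,
                     num.threads = 1L,
                     classification = is.factor(y)),
                hyperparameters)
      do.call(ranger::ranger, args)
    },
    predict = function(state, x) {
      p <- stats::predict(state, data = x, num.threads = 1L)$predictions
      if (is.factor(p)) as.character(p) else as.numeric(p)
    })
}

adapter_gradient_boosting <- function() {
  list(
    fit = function(x, y, hyperparameters, seed) {
      require_pkg("xgboost", "gradient_boosting")
      nrounds <- hp(hyperparameters, "nrounds", 100L)
      params <- hyperparameters[setdiff(names(hyperparameters), "nrounds")]
      levels <- NULL
      if (is.factor(y)) {
        levels <- levels(y)
        label <- as.integer(y) - 1L
        params$objective <- if (length(levels) > 2L) "multi:softmax" else "binary:logistic"
        if (length(levels) > 2L) params$num_class <- length(levels)
      } else {
        label <- y
        params$objective <- "reg:squarederror"
      }
      params$nthread <- 1L
      params$seed <- seed
      set.seed(seed)
      dtrain <- xgboost::xgb.DMatrix(x, label = label, nthread = 1L)
      fit <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = nrounds, verbose = 0)
      list(booster = fit, levels = levels)
    },
    predict = function(state, x) {
      p <- stats::predict(state$booster, newdata = x)
      if (is.null(state$levels)) return(as.numeric(p))
      if (length(state$levels) == 2L) p <- as.integer(p > 0.5)
      state$levels[as.integer(p) + 1L]
    })
}

adapter_svm <- function(kernel) {
  list(
    fit = function(x, y, hyperparameters, seed) {
      require_pkg("kernlab", paste0("svm_", kernel))
      kpar_names <- switch(kernel,
                           radial = "sigma",
                           polynomial = c("degree", "scale", "offset"))
      kpar <- hyperparameters[intersect(names(hyperparameters), kpar_names)]
      rest <- hyperparameters[setdiff(names(hyperparameters), kpar_names)]
      set.seed(seed)
      args <- c(list(x = x, y = y,
                     kernel = if (kernel == "radial") "rbfdot" else "polydot",
                     kpar = if (length(kpar)) kpar else "automatic",
                     prob.model = FALSE),
                rest)
      fit <- suppressWarnings(do.call(kernlab::ksvm, args))
      list(model = fit, levels = if (is.factor(y)) levels(y) else NULL)
    },
    predict = function(state, x) {
      p <- kernlab::predict(state$model, x)
      if (is.null(state$levels)) as.numeric(p) else as.character(p)
    })
}

adapter_elastic_net <- function() {
  list(
    fit = function(x, y, hyperparameters, seed) {
      require_pkg("glmnet", "elastic_net")
      lambda <- hp(hyperparameters, "lambda", NULL)
      rest <- hyperparameters[setdiff(names(hyperparameters), "lambda")]
      family <- if (is.factor(y)) {
        if (nlevels(y) > 2L) "multinomial" else "binomial"
      } else "gaussian"
      set.seed(seed)
      # glmnet fits a decreasing lambda path; a single requested lambda is
      # extracted at prediction time from a short path for stability.
      args <- c(list(x = x, y = y, family = family), rest)
      fit <- do.call(glmnet::glmnet, args)
      list(model = fit, lambda = lambda,
           levels = if (is.factor(y)) levels(y) else NULL)
    },
    predict = function(state, x) {
      type <- if (is.null(state$levels)) "response" else "class"
      s <- if (is.null(state$lambda)) min(state$model$lambda) else state$lambda
      p <- stats::predict(state$model, newx = x, s = s, type = type, exact = FALSE)
      if (is.null(state$levels)) as.numeric(p) else as.character(p)
    })
}

adapter_pls <- function() {
  list(
    fit = function(x, y, hyperparameters, seed) {
      require_pkg("mixOmics", "pls")
      ncomp <- hp(hyperparameters, "ncomp", 2L)
      if (is.factor(y)) {
        fit <- mixOmics::plsda(x, y, ncomp = ncomp)
      } else {
        fit <- mixOmics::pls(x, y, ncomp = ncomp, mode = "regression")
      }
      list(model = fit, ncomp = ncomp, levels = if (is.factor(y)) levels(y) else NULL)
    },
    predict = function(state, x) {
      p <- stats::predict(state$model, newdata = x)
      if (is.null(state$levels)) {
        as.numeric(p$predict[, 1L, state$ncomp])
      } else {
        as.character(p$class$max.dist[, state$ncomp])
      }
    })
}

# Unpenalized linear baseline: ordinary least squares for regression,
# multinomial logit (nnet) for classification. Useful as a transparent
# meta-learner and in tests where closed-form behaviour matters.
adapter_linear <- function() {
  list(
    fit = function(x, y, hyperparameters, seed) {
      if (is.factor(y)) {
        require_pkg("nnet", "linear")
        d <- data.frame(.y = y, x, check.names = FALSE)
        set.seed(seed)
        fit <- nnet::multinom(.y ~ ., data = d, trace = FALSE)
        list(model = fit, levels = levels(y), kind = "multinom")
      } else {
        d <- data.frame(.y = y, x, check.names = FALSE)
        list(model = stats::lm(.y ~ ., data = d), levels = NULL, kind = "lm")
      }
    },
    predict = function(state, x) {
      d <- as.data.frame(x, check.names = FALSE)
      if (state$kind == "lm") {
        as.numeric(stats::predict(state$model, newdata = d))
      } else {
        as.character(stats::predict(state$model, newdata = d, type = "class"))
      }
    })
}

register_default_learners <- function() {
  a <- adapter_random_forest()
  register_learner("random_forest", a$fit, a$predict)
  a <- adapter_gradient_boosting()
  register_learner("gradient_boosting", a$fit, a$predict)
  a <- adapter_svm("radial")
  register_learner("svm_radial", a$fit, a$predict)
  a <- adapter_svm("polynomial")
  register_learner("svm_polynomial", a$fit, a$predict)
  a <- adapter_elastic_net()
  register_learner("elastic_net", a$fit, a$predict)
  a <- adapter_pls()
  register_learner("pls", a$fit, a$predict)
  a <- adapter_linear()
  register_learner("linear", a$fit, a$predict)
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  register_default_learners()
}
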