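# Synthetic test-bed generator: standard-normal features, unit main effects
# on the first n_causal variables, unit-coefficient products of neighboring
# causal variables, and Gaussian noise scaled to a requested
# signal-to-noise ratio.

latent_signal <- function(X, n_causal) {
  s <- rowSums(X[, seq_len(n_causal), drop = FALSE])
  if (n_causal >= 2L) {
    j <- seq_len(n_causal - 1L)
    s <- s + rowSums(X[, j, drop = FALSE] * X[, j + 1L, drop = FALSE])
  }
  s
}

#' Simulate a regression dataset with controlled signal-to-noise ratio
#'
#' Draws an n x p matrix of independent standard-normal features. The
#' signal is the sum of the first `n_causal` features (unit coefficients)
#' plus the products of each neighboring pair among those causal features
#' (again unit coefficients, `n_causal - 1` interaction pairs). Gaussian
#' noise is added with standard deviation `sd(signal)/sqrt(snr)`, so the
#' realized variance ratio var(signal)/noise_sd^2 equals `snr` by
#' construction. With additive independent noise the correlation between
#' signal and response approaches `sqrt(snr/(1+snr))` — the ceiling any
#' predictor can approach (about 0.894 at `snr = 4`).
#'
#' @param n Number of samples (default 1000).
#' @param p Number of features (default 200).
#' @param n_causal Number of causal features with unit main effects
#'   (default 20); must not exceed `p`.
#' @param snr Signal-to-noise variance ratio (default 4).
#' @param seed Integer seed; the dataset is a pure function of
#'   `(n, p, n_causal, snr, seed)`.
#' @return An object of class `simulated_dataset`: list with `X`, `Y`,
#'   `signal`, `noise`, `beta` (length-p 0/1 vector), `interaction_pairs`
#'   (2-column matrix of neighboring causal index pairs), `noise_sd`, `snr`,
#'   and `seed`.
#' @export
#' @examples
#' sim <- simulate_regression(n = 200, p = 50, n_causal = 10, snr = 4, seed = 7)
#' var(sim$signal) / sim$noise_sd^2  # = 4 by construction
simulate_regression <- function(n = 1000L, p = 200L, n_causal = 20L, snr = 4,
                                seed = 1L) {
  n <- as.integer(n); p <- as.integer(p); n_causal <- as.integer(n_causal)
  if (n_causal > p) stop("n_causal (", n_causal, ") exceeds p (", p, ")", call. = FALSE)
  if (n_causal < 1L) stop("n_causal must be at least 1", call. = FALSE)
  if (!is.numeric(snr) || snr <= 0) stop("snr must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  X <- matrix(stats::rnorm(n * p), nrow = n, ncol = p,
              dimnames = list(NULL, paste0("V", seq_len(p))))
  signal <- latent_signal(X, n_causal)
  noise_sd <- stats::sd(signal) / sqrt(snr)
  noise <- stats::rnorm(n, mean = 0, sd = noise_sd)
  beta <- c(rep(1, n_causal), rep(0, p - n_causal))
  pairs <- if (n_causal >= 2L) {
    cbind(j = seq_len(n_causal - 1L), k = seq_len(n_causal - 1L) + 1L)
  } else {
    cbind(j = integer(), k = integer())
  }
  structure(list(X = X, Y = signal + noise, signal = signal, noise = noise,
                 beta = beta, interaction_pairs = pairs,
                 noise_sd = noise_sd, snr = snr, seed = as.integer(seed)),
            class = "simulated_dataset")
}

#' Simulate a classification dataset with unbalanced classes
#'
#' Generates the same latent continuous response as
#' [simulate_regression()] (signal plus noise at the requested
#' signal-to-noise ratio) and bins it into `n_classes` ordered categories
#' at latent quantiles. The default bin probabilities are proportional to
#' `1:n_classes`, deliberately unequal so that minor classes exist — the
#' regime in which classifiers tend to struggle.
#'
#' @inheritParams simulate_regression
#' @param n_classes Number of categories (default 4).
#' @param bin_probs Optional probabilities of the `n_classes` bins (summing
#'   to 1, smallest class first by default ordering of the latent scale).
#' @return A `simulated_dataset` whose `Y` is a factor with levels
#'   `C1 < C2 < ...` in increasing order of the latent variable.
#' @export
simulate_classification <- function(n = 1000L, p = 200L, n_causal = 20L,
                                    n_classes = 4L, snr = 4, seed = 1L,
                                    bin_probs = NULL) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be at least 2", call. = FALSE)
  if (n_classes > n) stop("n_classes exceeds the number of samples", call. = FALSE)
  sim <- simulate_regression(n = n, p = p, n_causal = n_causal, snr = snr,
                             seed = seed)
  if (is.null(bin_probs)) bin_probs <- seq_len(n_classes) / sum(seq_len(n_classes))
  if (length(bin_probs) != n_classes || any(bin_probs <= 0)) {
    stop("bin_probs must be ", n_classes, " positive probabilities", call. = FALSE)
  }
  bin_probs <- bin_probs / sum(bin_probs)
  cuts <- stats::quantile(sim$Y, probs = cumsum(bin_probs)[-n_classes],
                          names = FALSE)
  labels <- paste0("C", seq_len(n_classes))
  y <- cut(sim$Y, breaks = c(-Inf, cuts, Inf), labels = labels, right = TRUE)
  sim$latent <- sim$Y
  sim$Y <- factor(as.character(y), levels = labels)
  sim$bin_probs <- bin_probs
  sim
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset:", nrow(x$X), "samples x", ncol(x$X), "features,",
      sum(x$beta != 0), "causal,", nrow(x$interaction_pairs),
      "interaction pairs, snr", x$snr, "\n")
  invisible(x)
}
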