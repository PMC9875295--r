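#' Uninformative variable elimination (UVE)
#'
#' Appends a seeded matrix of artificial noise variables (same width as the
#' real spectrum, uniform on `[0, noise_scale]` — small enough not to perturb
#' the fit, since the stability statistic is scale invariant), computes the
#' leave-one-out PLS coefficient matrix on the augmented data, and scores
#' every column by the stability \eqn{S_i = mean(b_i) / sd(b_i)} of its
#' coefficient across the leave-one-out fits. The elimination threshold is
#' `threshold_factor` times the largest absolute stability observed in the
#' noise block; real variables whose `|S|` exceeds it are kept.
#'
#' @param X numeric matrix of (smoothed) spectra, samples in rows.
#' @param y nitrogen contents (% mass).
#' @param n_components PLS components for the leave-one-out fits. The
#'   default is deliberately small: a single constituent drives the response,
#'   so the informative subspace is low-rank, and superfluous components make
#'   the leave-one-out coefficients of informative variables markedly less
#'   stable (hurting their stability scores).
#' @param noise_scale amplitude of the artificial noise variables.
#' @param threshold_factor multiplier on the maximum absolute noise
#'   stability (1 = the noise ceiling itself).
#' @param seed integer seed for the noise matrix.
#' @return an object of class `uve_result`: `selected` (indices into the
#'   real variables), `stability`, `noise_stability`, `threshold`.
#' @export
uve_select <- function(X, y, n_components = 2, noise_scale = 1e-10,
                       threshold_factor = 1, seed = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  p <- ncol(X)
  noise <- with_seed(seed, matrix(stats::runif(nrow(X) * p, 0, noise_scale),
                                  nrow(X), p))
  L <- loo_coefficient_matrix(cbind(X, noise), y, n_components)
  mu <- colMeans(L)
  sdv <- apply(L, 2L, stats::sd)
  degenerate <- sdv == 0
  if (any(degenerate))
    warning(sum(degenerate), " coefficient columns had zero variance; ",
            "their stability was set to 0")
  S <- ifelse(degenerate, 0, mu / sdv)
  stability <- S[seq_len(p)]
  noise_stability <- S[(p + 1L):(2L * p)]
  threshold <- threshold_factor * max(abs(noise_stability))
  structure(list(selected = which(abs(stability) > threshold),
                 stability = stability,
                 noise_stability = noise_stability,
                 threshold = threshold),
            class = "uve_result")
}

#' @export
print.uve_result <- function(x, ...) {
  cat(sprintf("UVE: %d / %d variables kept (|S| > %.3g)\n",
              length(x$selected), length(x$stability), x$threshold))
  invisible(x)
}
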