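#' Euclidean distance between two spectra
#'
#' \eqn{d(p, q) = \sqrt{\sum_j (x_p(j) - x_q(j))^2}} over the frequency
#' points — the distance underlying Kennard-Stone sample selection.
#'
#' @param a,b numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) stop("spectra must have the same length")
  sqrt(sum((a - b)^2))
}

split_result <- function(cal, pred, method, seed = NULL) {
  structure(list(cal_indices = as.integer(cal),
                 pred_indices = as.integer(pred),
                 method = method, seed = seed),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("%s split: %d calibration / %d prediction samples\n",
              x$method, length(x$cal_indices), length(x$pred_indices)))
  invisible(x)
}

#' Kennard-Stone calibration/prediction split
#'
#' Deterministic maximin selection: the two samples at the largest mutual
#' Euclidean distance seed the calibration set; each further pick is the
#' sample whose shortest distance to the already selected samples is largest.
#' Distance ties are broken by the lowest sample index, so the split is
#' platform-independent. `cal_indices` are ordered by selection step.
#'
#' Run this on the smoothed spectra: sample-set division follows smoothing
#' in the pipeline's processing order.
#'
#' @param data a [spectra_set()].
#' @param n_cal calibration set size, `2 <= n_cal < n_samples(data)`.
#' @return a `split_result` with `method = "KS"`.
#' @export
ks_split <- function(data, n_cal) {
  validate_spectra_set(data)
  n <- n_samples(data)
  if (n_cal < 2 || n_cal >= n)
    stop("n_cal must satisfy 2 <= n_cal < ", n)
  D <- as.matrix(stats::dist(data$power))
  # seed pair: global maximum distance, ties -> smallest (row, col) indices
  flat <- which(D == max(D), arr.ind = TRUE)
  flat <- flat[flat[, 1] < flat[, 2], , drop = FALSE]
  flat <- flat[order(flat[, 1], flat[, 2]), , drop = FALSE]
  sel <- as.integer(flat[1, ])
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < n_cal) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)  # which.max returns the first (lowest-index) argmax
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  split_result(sel, setdiff(seq_len(n), sel), "KS")
}

#' Random-sampling calibration/prediction split
#'
#' Uniform partition without replacement; deterministic given the seed.
#'
#' @inheritParams ks_split
#' @param seed integer seed.
#' @return a `split_result` with `method = "RS"`.
#' @export
rs_split <- function(data, n_cal, seed = 1) {
  validate_spectra_set(data)
  n <- n_samples(data)
  if (n_cal < 2 || n_cal >= n)
    stop("n_cal must satisfy 2 <= n_cal < ", n)
  cal <- sort(with_seed(seed, sample.int(n, n_cal)))
  split_result(cal, setdiff(seq_len(n), cal), "RS", seed)
}

#' Score a calibration split by leave-one-out PLS
#'
#' Fits a PLS model on the calibration samples and evaluates it by
#' leave-one-out cross-validation, returning the cross-validated R-squared
#' and RMSE — the quantities used to compare KS against RS division.
#'
#' @param data a [spectra_set()].
#' @param split a `split_result` from [ks_split()] or [rs_split()].
#' @param n_components PLS components (capped at the feasible rank).
#' @return list with `r2`, `rmse`, `method`.
#' @export
compare_splits <- function(data, split, n_components = 5) {
  validate_spectra_set(data)
  cal <- split$cal_indices
  X <- data$power[cal, , drop = FALSE]
  y <- data$nitrogen_pct[cal]
  if (stats::sd(y) == 0) stop("degenerate calibration set: constant nitrogen")
  ncomp <- min(n_components, length(cal) - 2L, ncol(X))
  cv <- cross_validate(X, y, ncomp, scheme = "loo")
  list(r2 = r_squared(y, cv$predictions), rmse = cv$rmsecv,
       method = split$method)
}
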