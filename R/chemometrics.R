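#' Fit a univariate partial least-squares regression (PLS1, NIPALS)
#'
#' Latent-variable regression for collinear spectra. Components are extracted
#' by the NIPALS sequence for a single response: weights proportional to the
#' covariance of the deflated predictors with the deflated response, scores,
#' loadings, then rank-one deflation. The regression coefficient vector is
#' assembled as \eqn{b = W (P'W)^{-1} q} so that predictions are
#' \eqn{\hat y = (X - \bar x) b + \bar y}.
#'
#' Component extraction stops early (without error) if the residual covariance
#' vanishes, e.g. for a constant response, in which case the remaining
#' coefficients are zero and the model predicts the response mean.
#'
#' @param X numeric matrix, one row per sample, one column per spectral
#'   variable.
#' @param y numeric response vector (here: nitrogen content, \% mass).
#' @param n_components number of latent variables to extract; must not exceed
#'   `min(nrow(X) - 1, ncol(X))`.
#' @return an object of class `pls_model` with elements `coefficients`,
#'   `x_mean`, `y_mean`, `weights`, `x_loadings`, `y_loadings`,
#'   `n_components` (requested) and `n_components_used`.
#' @seealso [predict.pls_model()], [cross_validate()]
#' @export
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' y <- X %*% c(1, -1, 0, 0.5) + rnorm(10, sd = 0.1)
#' m <- fit_pls(X, y, n_components = 2)
#' predict(m, X)
fit_pls <- function(X, y, n_components) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n != length(y)) stop("nrow(X) must equal length(y)")
  if (n < 2) stop("at least 2 samples are required")
  if (n_components < 1) stop("n_components must be >= 1")
  max_comp <- min(n - 1L, p)
  if (n_components > max_comp) {
    stop(sprintf("n_components = %d exceeds the feasible rank %d for a %d x %d matrix",
                 n_components, max_comp, n, p))
  }

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xd <- sweep(X, 2L, x_mean, "-")
  yd <- y - y_mean
  y_scale <- sqrt(sum(yd^2))

  W <- P <- matrix(0, p, n_components)
  q <- numeric(n_components)
  used <- 0L
  for (a in seq_len(n_components)) {
    w <- crossprod(Xd, yd)
    wn <- sqrt(sum(w^2))
    # residual covariance exhausted: stop, coefficients of later comps stay 0
    if (wn <= 1e-12 * max(1, y_scale)) break
    w <- w / wn
    tt <- Xd %*% w
    t2 <- sum(tt^2)
    if (t2 <= .Machine$double.eps * n) break
    pa <- crossprod(Xd, tt) / t2
    qa <- sum(yd * tt) / t2
    Xd <- Xd - tcrossprod(tt, pa)
    yd <- yd - qa * tt
    W[, a] <- w
    P[, a] <- pa
    q[a] <- qa
    used <- a
  }

  if (used == 0L) {
    b <- numeric(p)
  } else {
    Wk <- W[, seq_len(used), drop = FALSE]
    Pk <- P[, seq_len(used), drop = FALSE]
    # P'W is unit upper triangular for PLS1 NIPALS; forwardsolve-able, but a
    # generic solve keeps the code robust to round-off
    b <- as.numeric(Wk %*% solve(crossprod(Pk, Wk), q[seq_len(used)]))
  }

  structure(
    list(coefficients = b,
         x_mean = x_mean,
         y_mean = y_mean,
         weights = W[, seq_len(max(used, 1L)), drop = FALSE],
         x_loadings = P[, seq_len(max(used, 1L)), drop = FALSE],
         y_loadings = q[seq_len(max(used, 1L))],
         n_components = n_components,
         n_components_used = used),
    class = "pls_model")
}

#' Predict from a fitted PLS model
#'
#' @param object a `pls_model` from [fit_pls()].
#' @param newdata numeric matrix with the same number of columns the model was
#'   fitted on.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$coefficients))
  }
  as.numeric(sweep(newdata, 2L, object$x_mean, "-") %*% object$coefficients) +
    object$y_mean
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS1 model: %d variables, %d/%d components used\n",
              length(x$coefficients), x$n_components_used, x$n_components))
  invisible(x)
}

#' Root-mean-square error with the (n - 1) denominator
#'
#' Computed as \eqn{\sqrt{\sum_i (y_i - \hat y_i)^2 / (n - 1)}}. The
#' \eqn{n - 1} denominator is the convention this pipeline's reference
#' results use throughout (RMSEC, RMSEP, RMSECV); set `denominator = "n"`
#' for the plain root-mean-square convention of most other chemometrics
#' software.
#'
#' @param y observed values.
#' @param yhat predicted values, same length.
#' @param denominator `"n_minus_1"` (default) or `"n"`.
#' @return non-negative scalar, in the units of `y` (\% nitrogen here).
#' @export
#' @examples
#' rmse(c(0, 2), c(0, 0))  # sqrt(4 / 1) = 2
rmse <- function(y, yhat, denominator = c("n_minus_1", "n")) {
  denominator <- match.arg(denominator)
  if (length(y) != length(yhat)) stop("y and yhat must have the same length")
  n <- length(y)
  if (n < 2 && denominator == "n_minus_1") {
    stop("rmse with the (n - 1) denominator needs at least 2 values")
  }
  den <- if (denominator == "n_minus_1") n - 1 else n
  sqrt(sum((y - yhat)^2) / den)
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum (y - \hat y)^2 / \sum (y - \bar y)^2}. May be negative
#' for predictions worse than the mean; never exceeds 1.
#'
#' @inheritParams rmse
#' @return scalar \eqn{\le 1}.
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have the same length")
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop("r_squared is undefined for a constant y")
  1 - sum((y - yhat)^2) / sst
}

#' Cross-validated PLS error
#'
#' Each sample is predicted by a model fitted without it (leave-one-out) or
#' without its fold (k-fold; folds are contiguous blocks of a seeded shuffle,
#' so the assignment is reproducible). The RMSECV is computed by [rmse()]
#' over the held-out predictions.
#'
#' @inheritParams fit_pls
#' @param scheme `"loo"` or `"kfold"`.
#' @param k number of folds when `scheme = "kfold"`; `k = n` reduces to
#'   leave-one-out.
#' @param seed integer seed for the fold shuffle (ignored for LOO).
#' @return list with `rmsecv`, `predictions` (aligned with `y`), `scheme`.
#' @export
cross_validate <- function(X, y, n_components, scheme = c("loo", "kfold"),
                           k = 10, seed = 1) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n != length(y)) stop("nrow(X) must equal length(y)")
  if (scheme == "kfold") {
    if (k > n) stop("fold count k = ", k, " exceeds the number of samples ", n)
    if (k < 2) stop("k must be >= 2")
    folds <- integer(n)
    perm <- with_seed(seed, sample.int(n))
    folds[perm] <- cut(seq_len(n), breaks = k, labels = FALSE)
  } else {
    folds <- seq_len(n)
  }
  ncomp <- min(n_components, ncol(X))
  preds <- numeric(n)
  for (f in unique(folds)) {
    hold <- which(folds == f)
    ncomp_f <- min(ncomp, n - length(hold) - 1L)
    if (ncomp_f < 1) stop("training folds too small for even one component")
    fit <- fit_pls(X[-hold, , drop = FALSE], y[-hold], ncomp_f)
    preds[hold] <- predict(fit, X[hold, , drop = FALSE])
  }
  list(rmsecv = rmse(y, preds), predictions = preds, scheme = scheme)
}

#' Leave-one-out PLS coefficient matrix
#'
#' Row i holds the coefficient vector of the PLS model fitted with sample i
#' left out. The column-wise mean/standard-deviation of this matrix is the
#' basis of the UVE stability statistic.
#'
#' @inheritParams fit_pls
#' @return numeric matrix, `nrow(X)` rows by `ncol(X)` columns.
#' @export
loo_coefficient_matrix <- function(X, y, n_components) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n != length(y)) stop("nrow(X) must equal length(y)")
  ncomp <- min(n_components, n - 2L, ncol(X))
  if (ncomp < 1) stop("too few samples for leave-one-out PLS")
  L <- matrix(0, n, ncol(X))
  for (i in seq_len(n)) {
    L[i, ] <- fit_pls(X[-i, , drop = FALSE], y[-i], ncomp)$coefficients
  }
  L
}
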