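# squared Euclidean distances between rows of A and rows of B
row_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Train an exact-design radial basis function network
#'
#' One Gaussian hidden unit is centred on every calibration sample
#' (`Q` units for `Q` samples). The activation of unit i at input x is
#' \eqn{a_i(x) = \exp(-(0.8326\, \lVert x - C_i \rVert / spread)^2)}, so the
#' unit's output falls to 0.5 at distance `spread` — the usual
#' "expansion speed" semantics of exact-design RBF tools. Output weights and
#' bias solve the linear system \eqn{[A; 1]' [W; b_2] = y} in the
#' minimum-norm least-squares sense (Q equations, Q + 1 unknowns, hence an
#' essentially exact interpolation of the calibration targets).
#'
#' @param X_cal calibration spectra (matrix, samples in rows).
#' @param y_cal calibration nitrogen contents.
#' @param spread Gaussian width parameter, > 0.
#' @return an object of class `rbf_model`: `centers`, `spread`, `weights`,
#'   `bias`.
#' @export
rbf_train <- function(X_cal, y_cal, spread = 0.5) {
  X_cal <- as.matrix(X_cal)
  y_cal <- as.numeric(y_cal)
  if (spread <= 0) stop("spread must be > 0")
  Q <- nrow(X_cal)
  if (Q < 1) stop("at least one calibration sample is required")
  if (Q != length(y_cal)) stop("nrow(X_cal) must equal length(y_cal)")
  A <- exp(-(0.8326 / spread)^2 * row_dist2(X_cal, X_cal))
  M <- cbind(A, 1)                      # Q x (Q + 1) design
  sv <- svd(M)
  tol <- max(dim(M)) * .Machine$double.eps * sv$d[1]
  keep <- sv$d > tol
  if (!all(keep))
    warning("ill-conditioned RBF design: rank ", sum(keep), " of ", Q,
            "; solved by truncated least squares")
  wb <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], y_cal)) / sv$d[keep])
  structure(list(centers = X_cal, spread = spread,
                 weights = as.numeric(wb[seq_len(Q)]),
                 bias = as.numeric(wb[Q + 1L])),
            class = "rbf_model")
}

#' Predict from an exact-design RBF network
#'
#' @param object an `rbf_model`.
#' @param newdata matrix with the same feature count as the centres.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.rbf_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$centers))
    stop("newdata has ", ncol(newdata), " features; model expects ",
         ncol(object$centers))
  A <- exp(-(0.8326 / object$spread)^2 * row_dist2(newdata, object$centers))
  as.numeric(A %*% object$weights) + object$bias
}

#' @export
print.rbf_model <- function(x, ...) {
  cat(sprintf("exact-design RBF network: %d centres, spread %.3g\n",
              nrow(x$centers), x$spread))
  invisible(x)
}

#' Sweep the RBF spread parameter
#'
#' Trains one exact-design network per candidate spread and records its
#' calibration RMSE — the diagnostic used to pick the expansion speed
#' (conventionally scanned over 0.1-1 in steps of 0.1).
#'
#' @inheritParams rbf_train
#' @param spreads numeric vector of candidate spreads.
#' @return list with `table` (data.frame of spread and rmsec) and
#'   `best_spread` (argmin, first on ties).
#' @export
rbf_spread_sweep <- function(X_cal, y_cal, spreads = seq(0.1, 1, by = 0.1)) {
  if (length(spreads) == 0) stop("spread list must be non-empty")
  rmsec <- vapply(spreads, function(s) {
    m <- rbf_train(X_cal, y_cal, s)
    rmse(y_cal, predict(m, X_cal))
  }, numeric(1))
  list(table = data.frame(spread = spreads, rmsec = rmsec),
       best_spread = spreads[which.min(rmsec)])
}
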