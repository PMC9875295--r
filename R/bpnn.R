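minmax_scaler <- function(x) {
  lo <- apply(as.matrix(x), 2L, min)
  hi <- apply(as.matrix(x), 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1  # constant feature maps to the midpoint
  list(lo = lo, rng = rng)
}

scale_minmax <- function(x, sc) {
  sweep(sweep(as.matrix(x), 2L, sc$lo, "-"), 2L, sc$rng, "/") * 2 - 1
}

unscale_minmax <- function(x, sc) {
  sweep(sweep((as.matrix(x) + 1) / 2, 2L, sc$rng, "*"), 2L, sc$lo, "+")
}

#' Train a small backpropagation neural network
#'
#' A single hidden layer of `hidden_size` tanh units and a linear output,
#' trained by plain full-batch gradient descent on the mean squared error.
#' Inputs and the response are min-max normalized to \[-1, 1\] on the
#' calibration statistics only (no test leakage). Weight initialisation is
#' seeded, so training is deterministic given the seed. Training stops at
#' `max_epochs` or when the relative loss change drops below `tol`.
#'
#' The conventional configuration for this pipeline is 6 hidden neurons at
#' learning rate 0.01; note that plain gradient descent needs far more than
#' a couple of dozen epochs to converge — pass a generous `max_epochs` when
#' a fitted model (rather than the training contract) is the goal.
#'
#' @param X_cal calibration spectra (matrix, samples in rows).
#' @param y_cal calibration nitrogen contents.
#' @param hidden_size hidden neurons (default 6).
#' @param learning_rate gradient-descent step size (default 0.01).
#' @param max_epochs maximum full-batch epochs (default 22).
#' @param tol relative loss-change threshold for early stopping.
#' @param seed integer seed for the weight initialisation.
#' @return an object of class `bpnn_model` with the layer weights, the
#'   scalers, and the per-epoch `loss_trace`.
#' @export
bpnn_train <- function(X_cal, y_cal, hidden_size = 6, learning_rate = 0.01,
                       max_epochs = 22, tol = 1e-8, seed = 1) {
  X_cal <- as.matrix(X_cal)
  y_cal <- as.numeric(y_cal)
  n <- nrow(X_cal)
  if (n != length(y_cal)) stop("nrow(X_cal) must equal length(y_cal)")
  if (hidden_size < 1) stop("hidden_size must be >= 1")
  if (stats::sd(y_cal) == 0) stop("constant response: nothing to train on")
  if (any(!is.finite(X_cal)) || any(!is.finite(y_cal)))
    stop("training data must be finite")

  in_sc <- minmax_scaler(X_cal)
  out_sc <- minmax_scaler(y_cal)
  Xs <- scale_minmax(X_cal, in_sc)
  ys <- as.numeric(scale_minmax(y_cal, out_sc))
  p <- ncol(Xs)

  init <- with_seed(seed, list(
    W1 = matrix(stats::runif(p * hidden_size, -0.5, 0.5), p, hidden_size),
    b1 = stats::runif(hidden_size, -0.5, 0.5),
    W2 = stats::runif(hidden_size, -0.5, 0.5),
    b2 = stats::runif(1, -0.5, 0.5)))
  W1 <- init$W1; b1 <- init$b1; W2 <- init$W2; b2 <- init$b2

  loss_trace <- numeric(0)
  prev_loss <- Inf
  for (epoch in seq_len(max_epochs)) {
    H <- tanh(sweep(Xs %*% W1, 2L, b1, "+"))        # n x h
    yhat <- as.numeric(H %*% W2) + b2
    err <- yhat - ys
    loss <- mean(err^2)
    loss_trace <- c(loss_trace, loss)
    # backpropagation of the mean squared error
    d_out <- 2 * err / n                            # n
    gW2 <- as.numeric(crossprod(H, d_out))
    gb2 <- sum(d_out)
    d_hid <- (d_out %o% W2) * (1 - H^2)             # n x h
    gW1 <- crossprod(Xs, d_hid)
    gb1 <- colSums(d_hid)
    W1 <- W1 - learning_rate * gW1
    b1 <- b1 - learning_rate * gb1
    W2 <- W2 - learning_rate * gW2
    b2 <- b2 - learning_rate * gb2
    if (is.finite(prev_loss) && abs(prev_loss - loss) < tol * max(prev_loss, 1e-30))
      break
    prev_loss <- loss
  }

  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 input_scaler = in_sc, output_scaler = out_sc,
                 hidden_size = hidden_size, learning_rate = learning_rate,
                 loss_trace = loss_trace, seed = seed),
            class = "bpnn_model")
}

#' Predict from a trained backpropagation network
#'
#' Applies the input scaler, the forward pass, and the inverse output scaler.
#'
#' @param object a `bpnn_model`.
#' @param newdata matrix with the feature count the model was trained on.
#' @param ... unused.
#' @return numeric vector of predictions on the original response scale.
#' @export
predict.bpnn_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$W1))
    stop("newdata has ", ncol(newdata), " features; model expects ",
         nrow(object$W1))
  Xs <- scale_minmax(newdata, object$input_scaler)
  H <- tanh(sweep(Xs %*% object$W1, 2L, object$b1, "+"))
  ys <- as.numeric(H %*% object$W2) + object$b2
  as.numeric(unscale_minmax(ys, object$output_scaler))
}

#' @export
print.bpnn_model <- function(x, ...) {
  cat(sprintf("BPNN: %d -> %d -> 1, lr %.3g, %d epochs run (final loss %.3g)\n",
              nrow(x$W1), x$hidden_size, x$learning_rate,
              length(x$loss_trace), utils::tail(x$loss_trace, 1)))
  invisible(x)
}
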