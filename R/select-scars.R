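#' Stability competitive adaptive reweighted sampling (SCARS)
#'
#' Iteratively shrinks the variable set over `n_runs` rounds. Each round,
#' over the currently surviving variables:
#' \enumerate{
#'   \item draw `n_mc` Monte-Carlo calibration subsets (each a fraction
#'     `mc_fraction` of the samples), fit a PLS model on each, and compute the
#'     per-variable stability \eqn{c_j = |mean(b_j)| / sd(b_j)} across draws;
#'   \item retain the fraction of the full panel given by the exponential
#'     decay function \eqn{r_i = a e^{-k i}}, with `a`, `k` fixed by
#'     \eqn{r_1 = (P-1)/P} and \eqn{r_{n\_runs} = 2/P}: a share
#'     `forced_fraction` of that count is the top-stability variables kept
#'     deterministically (forced selection), the remainder is drawn from the
#'     other survivors without replacement with probability proportional to
#'     \eqn{c_j} (adaptive reweighted sampling) — together the round's subset
#'     and the survivors entering the next round;
#'   \item score the subset by k-fold cross-validated RMSECV, averaged over
#'     `n_cv_repeats` fold splits (the splits are shared across rounds so the
#'     scores are comparable).
#' }
#' The returned selection is the subset of the round with minimal RMSECV.
#' By design the survivors shrink towards a handful of frequencies, so a
#' coarse screen early and a fine screen late.
#'
#' @param X numeric matrix of (smoothed) spectra, samples in rows.
#' @param y nitrogen contents (% mass).
#' @param n_components PLS components of the Monte-Carlo stability fits
#'   (clipped when a subset gets smaller).
#' @param n_components_cv PLS components of the scoring cross-validation;
#'   defaults to `n_components`.
#' @param n_runs number of sampling rounds (default 50).
#' @param mc_fraction fraction of samples per Monte-Carlo draw.
#' @param n_mc Monte-Carlo draws per round.
#' @param n_folds folds of the scoring cross-validation (default 10).
#' @param forced_fraction share of each round's retained count kept
#'   deterministically by stability rank; the rest is weighted-sampled.
#' @param n_cv_repeats independent fold splits averaged into each round's
#'   RMSECV score.
#' @param seed integer seed controlling all sampling.
#' @return an object of class `scars_result`: `selected`, `best_run`,
#'   `per_run_rmsecv`, `per_run_subsets`, `n_runs`.
#' @export
scars_select <- function(X, y, n_components = 8, n_runs = 50,
                         mc_fraction = 0.8, n_mc = 50, n_folds = 10,
                         forced_fraction = 0.8, n_cv_repeats = 3,
                         n_components_cv = n_components, seed = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  P <- ncol(X)
  if (n_runs < 2) stop("n_runs must be >= 2")
  if (mc_fraction <= 0 || mc_fraction >= 1) stop("mc_fraction must be in (0, 1)")
  n_sub <- max(2L, floor(mc_fraction * n))

  # EDF constants from the endpoint conditions r_1 = (P-1)/P, r_last = 2/P
  k_edf <- log((P - 1) / 2) / (n_runs - 1)
  a_edf <- (P - 1) / P * exp(k_edf)

  surviving <- seq_len(P)
  subsets <- vector("list", n_runs)
  rmsecv <- rep(NA_real_, n_runs)

  for (run in seq_len(n_runs)) {
    run_seed <- derive_seed(seed, paste0("scars-run-", run))
    ncomp <- max(1L, min(n_components, length(surviving), n_sub - 1L))
    B <- with_seed(run_seed, {
      vapply(seq_len(n_mc), function(m) {
        rows <- sample.int(n, n_sub)
        fit_pls(X[rows, surviving, drop = FALSE], y[rows], ncomp)$coefficients
      }, numeric(length(surviving)))
    })
    B <- matrix(B, nrow = length(surviving))
    mu <- rowMeans(B)
    sdv <- apply(B, 1L, stats::sd)
    cj <- ifelse(sdv > 0, abs(mu) / sdv, 0)
    cj[!is.finite(cj)] <- 0

    n_keep <- max(2L, min(length(surviving), round(a_edf * exp(-k_edf * run) * P)))
    rank_order <- order(cj, decreasing = TRUE)
    n_forced <- min(n_keep, max(1L, round(forced_fraction * n_keep)))
    forced <- surviving[rank_order[seq_len(n_forced)]]
    n_draw <- n_keep - n_forced
    if (n_draw > 0) {
      pool <- rank_order[(n_forced + 1L):length(surviving)]
      w <- cj[pool]
      if (sum(w) == 0) w <- rep(1, length(pool))
      drawn <- with_seed(derive_seed(run_seed, "ars"),
                         sample(length(pool), size = min(n_draw, length(pool)),
                                prob = w))
      subset <- sort(c(forced, surviving[pool[drawn]]))
    } else {
      subset <- sort(forced)
    }
    if (length(subset) == 0) stop("SCARS produced an empty subset at run ", run)

    ncomp_cv <- max(1L, min(n_components_cv, length(subset)))
    # fold assignments shared across runs (so per-run scores are comparable)
    # and averaged over several repeats (so the argmin is not decided by one
    # lucky fold split)
    scores <- vapply(seq_len(n_cv_repeats), function(rep)
      cross_validate(X[, subset, drop = FALSE], y, ncomp_cv,
                     scheme = "kfold", k = min(n_folds, n),
                     seed = derive_seed(seed, paste0("cv-folds-", rep)))$rmsecv,
      numeric(1))
    subsets[[run]] <- subset
    rmsecv[run] <- mean(scores)
    surviving <- subset
  }

  best <- which.min(rmsecv)
  structure(list(selected = subsets[[best]], best_run = best,
                 per_run_rmsecv = rmsecv, per_run_subsets = subsets,
                 n_runs = n_runs),
            class = "scars_result")
}

#' @export
print.scars_result <- function(x, ...) {
  cat(sprintf("SCARS: %d runs; best RMSECV %.4f at run %d (%d variables kept)\n",
              x$n_runs, x$per_run_rmsecv[x$best_run], x$best_run,
              length(x$selected)))
  invisible(x)
}

#' Exponential decay schedule of SCARS
#'
#' The fraction of the full variable panel retained by forced selection at
#' each run, \eqn{r_i = a e^{-k i}}, with the endpoint conditions
#' \eqn{r_1 = (P-1)/P} and \eqn{r_{n\_runs} = 2/P}.
#'
#' @param P number of variables in the full panel.
#' @param n_runs number of runs.
#' @return numeric vector of length `n_runs`, non-increasing.
#' @export
scars_edf <- function(P, n_runs) {
  k <- log((P - 1) / 2) / (n_runs - 1)
  a <- (P - 1) / P * exp(k)
  a * exp(-k * seq_len(n_runs))
}
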