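# small, fast fixtures used across the suite

# a tiny but structurally complete benchmark population
tiny_config <- function(seed = 1, n_frequencies = 80, ...) {
  sim_config(n_gradients = 2, samples_per_gradient = 6,
             gradient_means_pct = c(2, 4), n_frequencies = n_frequencies,
             informative_bands_thz = c(0.4, 0.9),
             band_relative_strength = c(1, 0.7),
             seed = seed, ...)
}

# hand-rolled spectra set over an explicit grid
toy_spectra <- function(power, freqs = NULL, nitrogen = NULL) {
  power <- as.matrix(power)
  if (is.null(freqs)) freqs <- seq(0.1, 1.3, length.out = ncol(power))
  if (is.null(nitrogen)) nitrogen <- seq(1, 4, length.out = nrow(power))
  spectra_set(freqs, power, nitrogen, sprintf("T%02d", seq_len(nrow(power))))
}

# exhaustive Kennard-Stone reference: recomputes all distances at each step,
# ties broken by the lowest sample index (seed pair: lowest row, then column)
ks_oracle <- function(X, n_cal) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  best <- c(NA, NA)
  best_d <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > best_d) { best_d <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_cal) {
    cand <- setdiff(seq_len(n), sel)
    mins <- vapply(cand, function(k) min(D[k, sel]), numeric(1))
    sel <- c(sel, cand[which.max(mins)])
  }
  sel
}

# strip run_pipeline's attached diagnostics, leaving the bare fit_report
unclass_report <- function(r) {
  attributes(r) <- attributes(r)[c("names", "class")]
  r
}

# per-window quadratic least-squares fit evaluated at the window midpoint
sg_window_oracle <- function(x, center, half = 3, order = 2) {
  idx <- (center - half):(center + half)
  fit <- stats::lm(y ~ stats::poly(t, order, raw = TRUE),
                   data = data.frame(t = seq_along(idx), y = x[idx]))
  unname(stats::predict(fit)[half + 1])
}
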