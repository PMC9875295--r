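# planted instance: a few columns carry the response, the rest are noise
planted_instance <- function(seed, n = 30, p_noise = 45) {
  set.seed(seed)
  y <- rnorm(n, mean = 3)
  informative <- sapply(c(1, -0.5, 2, 0.8, -1.2), function(a) a * y)
  X <- cbind(informative, matrix(rnorm(n * p_noise), n))
  list(X = X, y = y, truth = 1:5)
}

test_that("UVE keeps planted variables and drops noise", {
  for (seed in 1:3) {
    inst <- planted_instance(seed)
    res <- uve_select(inst$X, inst$y, n_components = 2, seed = seed)
    expect_true(all(inst$truth %in% res$selected))
    expect_lte(sum(!res$selected %in% inst$truth), 5)
  }
})

test_that("UVE selects almost nothing when X is pure noise", {
  frac <- vapply(1:20, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 40), 20, 40)
    y <- rnorm(20)
    length(uve_select(X, y, n_components = 2, seed = seed)$selected) / 40
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("UVE stability equals a direct oracle and extreme thresholds empty it", {
  inst <- planted_instance(4)
  res <- uve_select(inst$X, inst$y, n_components = 2, seed = 4)
  # recompute stability with an independent two-pass mean/sd on the L matrix
  p <- ncol(inst$X)
  noise <- with_seed(4, matrix(stats::runif(nrow(inst$X) * p, 0, 1e-10),
                               nrow(inst$X), p))
  L <- loo_coefficient_matrix(cbind(inst$X, noise), inst$y, 2)
  S <- colMeans(L) / apply(L, 2, stats::sd)
  expect_equal(res$stability, S[1:p], tolerance = 1e-12)
  expect_equal(res$noise_stability, S[(p + 1):(2 * p)], tolerance = 1e-12)
  expect_equal(res$threshold, max(abs(S[(p + 1):(2 * p)])))
  expect_true(all(abs(res$stability[res$selected]) > res$threshold))

  none <- uve_select(inst$X, inst$y, n_components = 2,
                     threshold_factor = 1e6, seed = 4)
  expect_length(none$selected, 0)
})

test_that("the SCARS decay schedule is monotone with the stated endpoints", {
  for (P in c(50, 682)) {
    r <- scars_edf(P, 50)
    expect_true(all(diff(r) < 0))
    expect_equal(r[1], (P - 1) / P)
    expect_equal(r[50], 2 / P)
  }
})

test_that("SCARS shrinks per schedule, scores every run, returns the argmin", {
  inst <- planted_instance(2, n = 24, p_noise = 35)
  res <- scars_select(inst$X, inst$y, n_components = 3, n_runs = 12,
                      n_mc = 15, seed = 2)
  sizes <- lengths(res$per_run_subsets)
  expect_true(all(diff(sizes) <= 0))
  expect_true(all(is.finite(res$per_run_rmsecv)))
  expect_equal(res$best_run, which.min(res$per_run_rmsecv))
  expect_identical(res$selected, res$per_run_subsets[[res$best_run]])
  # reproducibility
  res2 <- scars_select(inst$X, inst$y, n_components = 3, n_runs = 12,
                       n_mc = 15, seed = 2)
  expect_identical(res$selected, res2$selected)

  # the EDF endpoint leaves about 2 variables at the final run
  expect_lte(length(res$per_run_subsets[[12]]), 3)

  two <- scars_select(inst$X, inst$y, n_components = 2, n_runs = 2,
                      n_mc = 10, seed = 1)
  expect_lte(length(two$per_run_subsets[[2]]), 2)
})

test_that("SCARS homes in on planted variables", {
  # exact collinearity makes minimal subsets optimal, so the check is that
  # the winning subset is informative and predictive, not that it is large
  for (seed in 1:3) {
    inst <- planted_instance(seed)
    res <- scars_select(inst$X, inst$y, n_components = 3, n_runs = 20,
                        n_mc = 25, seed = seed)
    expect_gte(sum(inst$truth %in% res$selected), 1)
    expect_lt(res$per_run_rmsecv[res$best_run], 0.2 * stats::sd(inst$y))
  }
})

test_that("iPLS tiles the grid and finds a planted interval", {
  # interval arithmetic on the 682-point grid
  cfg <- sim_config()
  d <- generate_spectra(cfg)
  ip <- ipls_select(d$power, d$nitrogen_pct, d$frequencies_thz, 22,
                    n_components = 2)
  expect_true(all(lengths(ip$interval_indices) == 31))
  expect_equal(unlist(ip$interval_indices), 1:682)
  expect_equal(unname(ip$interval_bounds_thz[12, ]), c(0.6996, 0.7632))
  expect_equal(unname(ip$interval_bounds_thz[22, 2]), 1.4)

  # planted block: signal confined to one interval, zero elsewhere
  set.seed(31)
  X <- matrix(rnorm(40 * 60), 40, 60)
  y <- rnorm(40, mean = 3)
  X[, 25:30] <- X[, 25:30] + y        # falls in interval 5 of 10 (cols 25-30)
  freqs <- seq(0.02, 1.2, length.out = 60)
  ip2 <- ipls_select(X, y, freqs, 10, n_components = 2)
  expect_equal(ip2$best_interval, 5)
  expect_equal(ip2$selected, 25:30)

  # permuted response: no interval looks predictive
  ip_null <- ipls_select(X, sample(y), freqs, 10, n_components = 2)
  expect_gt(min(ip_null$per_interval_rmsecv), 0.6 * stats::sd(y))

  expect_error(ipls_select(X, y, freqs, 1), ">= 2")
  expect_error(ipls_select(X, y, freqs[-1], 10), "one entry per column")
})

test_that("the interval-count search matches per-count recomputation", {
  set.seed(17)
  X <- matrix(rnorm(30 * 48), 30, 48)
  y <- rnorm(30, 3)
  X[, 13:18] <- X[, 13:18] + 0.8 * y
  freqs <- seq(0.05, 1.3, length.out = 48)
  srch <- ipls_interval_search(X, y, freqs, candidate_range = 3:8,
                               n_components = 2)
  expect_length(srch$per_n_rmsecv, 6)
  for (k in seq_along(3:8)) {
    direct <- ipls_select(X, y, freqs, (3:8)[k], n_components = 2)
    expect_equal(unname(srch$per_n_rmsecv[k]), min(direct$per_interval_rmsecv))
  }
  expect_equal(srch$best_n, (3:8)[which.min(srch$per_n_rmsecv)])

  single <- ipls_interval_search(X, y, freqs, candidate_range = 6,
                                 n_components = 2)
  expect_equal(single$best_n, 6)
  expect_error(ipls_interval_search(X, y, freqs, integer(0)), "empty")
})
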