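test_that("default benchmark has the documented shape and is seed-deterministic", {
  s1 <- generate_spectra(sim_config(seed = 7))
  expect_equal(dim(s1$power), c(80, 682))
  expect_length(s1$frequencies_thz, 682)
  expect_equal(max(s1$frequencies_thz), 1.4)
  expect_equal(length(unique(s1$gradient_labels)), 4)

  s2 <- generate_spectra(sim_config(seed = 7))
  expect_identical(s1, s2)
  s3 <- generate_spectra(sim_config(seed = 8))
  expect_false(identical(s1$power, s3$power))
})

test_that("with no nitrogen pathway and no noise all spectra are identical", {
  cfg <- tiny_config(noise_sd = 0, band_effect_per_pct = 0,
                     baseline_amp_per_pct = 0)
  s <- generate_spectra(cfg)
  expect_true(all(abs(sweep(s$power, 2, s$power[1, ])) < 1e-14))
})

test_that("noise-free generator matches an independent closed-form evaluation", {
  cfg <- sim_config(seed = 3, noise_sd = 0)
  s <- generate_spectra(cfg)
  f <- s$frequencies_thz
  j <- which.min(abs(f - 0.704))

  # independent evaluation of the generator equation at one frequency point:
  # peak Gaussian (sigma = width/sqrt(2)) times the nitrogen-scaled amplitude,
  # minus the planted absorption (flat-core/cosine-taper bump) at that point
  peak <- exp(-((f[j] - cfg$peak_center_thz)^2) / cfg$peak_width_thz^2)
  bump_at <- function(fj, b) {
    d <- abs(fj - b) / cfg$band_width_thz
    if (d <= 0.6) 1 else if (d < 1) 0.5 * (1 + cos(pi * (d - 0.6) / 0.4)) else 0
  }
  expected_one <- function(N) {
    peak * (cfg$baseline_base + cfg$baseline_amp_per_pct * N) -
      sum(cfg$band_relative_strength * cfg$band_effect_per_pct * N *
            vapply(cfg$informative_bands_thz, function(b) bump_at(f[j], b), 1))
  }
  expect_equal(s$power[, j], vapply(s$nitrogen_pct, expected_one, numeric(1)),
               tolerance = 1e-12)

  # gradient contrast at the 0.704 THz band centre equals the closed form
  hi <- s$gradient_labels == "G4"
  lo <- s$gradient_labels == "G1"
  dN <- mean(s$nitrogen_pct[hi]) - mean(s$nitrogen_pct[lo])
  expect_equal(mean(s$power[hi, j]) - mean(s$power[lo, j]),
               dN * (peak * cfg$baseline_amp_per_pct -
                       cfg$band_relative_strength[4] * cfg$band_effect_per_pct),
               tolerance = 1e-12)
})

test_that("power at a band centre is strictly decreasing in nitrogen", {
  cfg <- sim_config(noise_sd = 0)
  f <- frequency_grid(cfg)
  j <- which.min(abs(f - 0.817))
  vals <- vapply(c(1, 2, 3, 4, 5), function(N) clean_spectrum(cfg, N, f)[j],
                 numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("true_informative_indices returns the grid points under the bands", {
  cfg <- sim_config(n_frequencies = 700, informative_bands_thz = 0.7,
                    band_relative_strength = 1, band_width_thz = 0.01)
  idx <- true_informative_indices(cfg)
  f <- frequency_grid(cfg)  # step 0.002
  expect_equal(idx, seq(min(idx), max(idx)))  # contiguous
  expect_equal(length(idx), 11)
  expect_true(all(abs(f[idx] - 0.7) <= 0.01 + 1e-9))

  expect_identical(
    true_informative_indices(sim_config(informative_bands_thz = numeric(0),
                                        band_relative_strength = numeric(0))),
    integer(0))

  # overlapping bands: union without duplicates
  cfg2 <- sim_config(n_frequencies = 700, band_width_thz = 0.01,
                     informative_bands_thz = c(0.7, 0.712),
                     band_relative_strength = c(1, 1))
  idx2 <- true_informative_indices(cfg2)
  expect_false(anyDuplicated(idx2) > 0)
  expect_equal(idx2, seq(min(idx2), max(idx2)))
})

test_that("selection_recovery scores selections against the planted truth", {
  cfg <- sim_config()
  f <- frequency_grid(cfg)
  truth <- true_informative_indices(cfg, f)
  perfect <- selection_recovery(truth, cfg, f)
  expect_equal(perfect$index_recall, 1)
  expect_equal(perfect$band_recall, 1)
  expect_equal(perfect$fpr, 0)

  none <- selection_recovery(integer(0), cfg, f)
  expect_equal(none$index_recall, 0)
  expect_equal(none$fpr, 0)

  all_sel <- selection_recovery(seq_along(f), cfg, f)
  expect_equal(all_sel$index_recall, 1)
  expect_equal(all_sel$fpr, 1)
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(within_gradient_sd_pct = 0), "widths and standard")
  expect_error(sim_config(gradient_means_pct = c(1, 2)), "one mean per gradient")
  expect_error(sim_config(informative_bands_thz = c(0.5, 1.5),
                          band_relative_strength = c(1, 1)), "within")
  expect_error(sim_config(band_relative_strength = 1), "one entry per")
})
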