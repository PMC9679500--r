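test_that("degenerate variances collapse every plot to the mean", {
  cfg <- sim_config(genotypes_per_trial = 10, var_g = 0, var_rep = 0,
                    var_block = 0, var_e = 0, starch_mean = 25, seed = 3)
  ref <- simulate_reference(cfg)
  expect_true(all(ref$starch == 25))
  cfg_a <- sim_config(genotypes_per_trial = 12, design = "ALPHA_LATTICE",
                      blocks_per_rep = 3, var_g = 0, var_rep = 0,
                      var_block = 0, var_e = 0, starch_mean = 30, seed = 3)
  expect_true(all(simulate_reference(cfg_a)$starch == 30))
})

test_that("genotype-mean variance matches the generating model", {
  # var of genotype means over reps = var_g + var_e / n_reps = 25 + 2 = 27
  vars <- vapply(1:200, function(i) {
    cfg <- sim_config(genotypes_per_trial = 100, n_reps = 2,
                      design = "RCBD", var_g = 25, var_e = 4,
                      var_rep = 0, var_block = 0, seed = 1000L + i)
    ref <- simulate_reference(cfg)
    gm <- tapply(ref$starch, ref$genotype_id, mean)
    stats::var(gm)
  }, numeric(1))
  expect_lt(abs(mean(vars) - 27) / 27, 0.15)
})

test_that("default world emulates a high-variability trial (CV ~ 0.3)", {
  ref <- simulate_reference(sim_config(seed = 11))
  s <- summarize_reference(ref)
  expect_gt(s$cv, 0.25)
  expect_lt(s$cv, 0.35)
  expect_true(all(ref$starch > 0 & ref$starch < 100))
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- tiny_config()
  r1 <- simulate_reference(cfg); r2 <- simulate_reference(cfg)
  expect_identical(r1, r2)
  s1 <- simulate_spectra(r1, cfg); s2 <- simulate_spectra(r2, cfg)
  expect_identical(s1, s2)
  # and a different seed gives different draws
  r3 <- simulate_reference(tiny_config(seed = 43L))
  expect_false(identical(r1$starch, r3$starch))
})

test_that("noise-free forward model is exact and linear in starch", {
  cfg <- sim_config(genotypes_per_trial = 2, n_reps = 1,
                    var_g = 25, var_rep = 0, var_block = 0, var_e = 0,
                    band_centers = 900, band_widths = 20,
                    band_loadings = 0.002,
                    water_band_center = 970, water_band_width = 12,
                    water_const = 0.05, water_coef = 0.0008,
                    baseline_level = 0.4,
                    scatter_slope_sd = 0, scatter_offset_sd = 0,
                    noise_sd = 0, scans_per_sample = 1, seed = 5)
  ref <- simulate_reference(cfg)
  spc <- simulate_spectra(ref, cfg)
  w <- spc$wavelengths
  for (i in seq_len(nrow(ref))) {
    starch <- ref$starch[i]
    # independent hand computation of the stated forward model
    expected_at_center <- 0.4 + 0.002 * starch +
      (0.05 - 0.0008 * starch) * exp(-(900 - 970)^2 / (2 * 12^2))
    expect_equal(spc$reflectance[i, w == 900], expected_at_center,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # linearity: spectral difference of two starch levels is confined to
  # the bands and peaks at the band centre
  s10 <- expected_spectrum(10, cfg)
  s40 <- expected_spectrum(40, cfg)
  d <- abs(s40 - s10)
  far <- abs(w - 900) > 100 & abs(w - 970) > 60
  expect_true(all(d[far] < 1e-6))
  starch_band <- abs(w - 900) <= 30
  expect_equal(w[starch_band][which.max(d[starch_band])], 900)
})

test_that("default spectra are nonnegative and carry full scan metadata", {
  cfg <- tiny_config()
  ref <- simulate_reference(cfg)
  spc <- simulate_spectra(ref, cfg)
  expect_true(all(spc$reflectance >= 0))
  expect_equal(nrow(spc$reflectance), nrow(ref) * cfg$scans_per_sample)
  expect_setequal(unique(spc$meta$sample_id), ref$sample_id)
  expect_true(all(c("genotype_id", "trial_id", "rep", "block",
                    "scan_index") %in% names(spc$meta)))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(var_g = -1), "variances")
  expect_error(sim_config(band_centers = c(880, 912),
                          band_widths = 15,
                          band_loadings = c(1, 2, 3) * 1e-3),
               "equal length")
  expect_error(sim_config(shared_genotype_fraction = 1.2), "0, 1")
  expect_error(sim_config(design = "LATIN_SQUARE"), "design")
  ref_nostarch <- data.frame(sample_id = "a")
  expect_error(simulate_spectra(ref_nostarch, tiny_config()), "starch")
})

test_that("plant_outlier shifts exactly one sample", {
  fx <- make_samples()
  s <- fx$samples
  expect_identical(plant_outlier(s, s$meta$sample_id[1], 0), s)
  target <- s$meta$sample_id[4]
  sp <- plant_outlier(s, target, 10)
  changed <- rowSums(sp$reflectance != s$reflectance) > 0
  expect_identical(which(changed), which(s$meta$sample_id == target))
  # planted sample attains the largest Mahalanobis distance
  qc <- mahalanobis_filter(sp, threshold = Inf)
  expect_equal(which.max(qc$distances), which(s$meta$sample_id == target))
  expect_error(plant_outlier(s, "nope", 5), "unknown sample_id")
})
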