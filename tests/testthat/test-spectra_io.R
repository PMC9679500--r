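test_that("write -> read round-trips a valid spectra set", {
  s <- toy_spectra(n = 3)
  expect_equal(length(s$wavelengths), 331L)  # 1070 - 740 + 1
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(s, path)
  s2 <- read_spectra_csv(path)
  expect_equal(s2$wavelengths, s$wavelengths)
  expect_equal(s2$reflectance, s$reflectance, tolerance = 1e-12)
  expect_equal(s2$meta$sample_id, s$meta$sample_id)
})

test_that("grid gaps, duplicate keys and missing cells are caught", {
  s <- toy_spectra(n = 3, wavelengths = 895:905)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- cbind(s$meta, as.data.frame(s$reflectance, check.names = FALSE))
  write.csv(df[, names(df) != "900"], path, row.names = FALSE)
  expect_error(read_spectra_csv(path), "not uniform")

  dup <- df; dup$sample_id <- "same"; dup$scan_index <- 1L
  write.csv(dup, path, row.names = FALSE)
  expect_error(read_spectra_csv(path), "duplicate")

  df2 <- df; df2[2, "898"] <- NA
  write.csv(df2, path, row.names = FALSE)
  expect_warning(s3 <- read_spectra_csv(path), "rejected 1 row")
  expect_equal(nrow(s3$reflectance), 2L)
  expect_equal(attr(s3, "rejected"), 2L)

  expect_error(read_spectra_csv("does/not/exist.csv"), "no such file")
})

test_that("average_scans averages per sample and is idempotent", {
  w <- 740:749
  meta <- data.frame(sample_id = rep(c("a", "b"), each = 2),
                     genotype_id = rep(c("g1", "g2"), each = 2),
                     trial_id = "T", rep = "R1", block = "B1",
                     scan_index = c(1, 2, 1, 2))
  refl <- rbind(rep(0.2, 10), rep(0.4, 10), rep(0.5, 10), rep(0.5, 10))
  s <- spectra_set(w, refl, meta)
  avg <- average_scans(s)
  expect_equal(nrow(avg$reflectance), 2L)
  expect_equal(unname(avg$reflectance[1, 1]), 0.3)  # mean(0.2, 0.4)
  expect_equal(unname(avg$reflectance[2, ]), rep(0.5, 10))
  expect_false("scan_index" %in% names(avg$meta))
  expect_equal(average_scans(avg)$reflectance, avg$reflectance)

  # 30 samples x 3 scans in -> 30 rows out (count contract)
  fx <- make_samples(tiny_config(genotypes_per_trial = 15, n_reps = 2))
  expect_equal(nrow(fx$samples$reflectance), 30L)

  bad_meta <- meta; bad_meta$genotype_id <- c("g1", "gX", "g2", "g2")
  expect_error(average_scans(spectra_set(w, refl, bad_meta)),
               "not constant within sample")
})

test_that("trim_wavelengths selects, errors and composes", {
  s <- toy_spectra(n = 2)
  expect_equal(trim_wavelengths(s, 740, 1070)$reflectance, s$reflectance)
  tr <- trim_wavelengths(s, 815, 980)
  expect_equal(length(tr$wavelengths), 166L)  # 980 - 815 + 1
  expect_error(trim_wavelengths(s, 2000, 2100), "does not intersect")
  a <- trim_wavelengths(trim_wavelengths(s, 800, 1000), 900, 1050)
  b <- trim_wavelengths(s, 900, 1000)
  expect_equal(a$reflectance, b$reflectance)
  expect_equal(a$wavelengths, b$wavelengths)
})

test_that("compute_rsc applies the dry-mass ratio", {
  expect_equal(compute_rsc(25, 100), 25)
  expect_equal(compute_rsc(0, 100), 0)
  expect_equal(compute_rsc(41.6, 100), 41.6)
  expect_error(compute_rsc(10, 0), "positive")
  expect_error(compute_rsc(-1, 100), ">= 0")
})

test_that("summarize_reference computes per-trial sample statistics", {
  ref <- data.frame(
    trial_id = c("A", "A", "A", "B", "B", "C"),
    genotype_id = c("g1", "g2", "g3", "g1", "g2", "g1"),
    rep = "R1", block = "B1", design = "RCBD",
    starch = c(10, 10, 10, 10, 20, 15),
    sample_id = sprintf("p%d", 1:6))
  s <- summarize_reference(ref)
  expect_equal(s$sd[s$trial_id == "A"], 0)
  expect_equal(s$cv[s$trial_id == "A"], 0)
  expect_equal(s$sd[s$trial_id == "B"], sqrt(50), tolerance = 1e-12)
  expect_equal(s$cv[s$trial_id == "B"], sqrt(50) / 15, tolerance = 1e-12)
  expect_true(s$singleton[s$trial_id == "C"])
  expect_true(is.na(s$sd[s$trial_id == "C"]))
})

test_that("reference validation enforces the plot contract", {
  fx <- make_samples()
  expect_silent(validate_reference(fx$reference))
  bad <- fx$reference; bad$starch[1] <- 120
  expect_error(validate_reference(bad), "0, 100")
  bad <- fx$reference; bad$design[1] <- "SPLIT_PLOT"
  expect_error(validate_reference(bad), "RCBD or ALPHA_LATTICE")
  bad <- fx$reference; bad$sample_id[2] <- bad$sample_id[1]
  expect_error(validate_reference(bad), "unique")
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_csv(fx$reference, path)
  expect_equal(read_reference_csv(path)$starch, fx$reference$starch,
               tolerance = 1e-12)
})
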