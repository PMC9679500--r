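sim_rcbd <- function(n_g, n_b, var_g, var_b, var_e, mu = 25, seed = 1) {
  set.seed(seed)
  g <- rep(sprintf("g%03d", seq_len(n_g)), times = n_b)
  b <- rep(sprintf("b%02d", seq_len(n_b)), each = n_g)
  y <- mu + rnorm(n_g, 0, sqrt(var_g))[as.integer(factor(g))] +
    rnorm(n_b, 0, sqrt(var_b))[as.integer(factor(b))] +
    rnorm(n_g * n_b, 0, sqrt(var_e))
  list(y = y, g = g, b = b)
}

test_that("balanced-RCBD REML equals the ANOVA closed form", {
  for (seed in 1:5) {
    d <- sim_rcbd(30, 4, var_g = 25, var_b = 25, var_e = 6, seed = seed)
    vc <- fit_rcbd(d$y, d$g, d$b)
    oracle <- anova_rcbd_oracle(d$y, d$g, d$b)
    # REML equals the ANOVA method of moments only at interior solutions
    expect_gt(min(oracle$sigma2_g, oracle$sigma2_block, oracle$sigma2_e),
              0)
    expect_true(vc$converged)
    expect_equal(vc$sigma2_g, oracle$sigma2_g, tolerance = 1e-6)
    expect_equal(vc$sigma2_block, oracle$sigma2_block, tolerance = 1e-6)
    expect_equal(vc$sigma2_e, oracle$sigma2_e, tolerance = 1e-6)
    expect_equal(vc$nRep, 4)
  }
})

test_that("degenerate inputs give zero components", {
  vc <- fit_rcbd(rep(20, 40), rep(sprintf("g%02d", 1:20), 2),
                 rep(c("b1", "b2"), each = 20))
  expect_equal(vc$sigma2_g, 0)
  expect_equal(vc$sigma2_e, 0)
  expect_error(fit_rcbd(1:4, rep("g1", 4), c("b1", "b2", "b1", "b2")),
               ">= 2 genotypes")
})

test_that("alpha-lattice components vanish when rep/block effects are absent", {
  set.seed(31)
  n_g <- 60; n_r <- 2; n_blk <- 5
  g <- rep(sprintf("g%03d", 1:n_g), times = n_r)
  r <- rep(c("r1", "r2"), each = n_g)
  blk <- sprintf("b%d", rep(rep(1:n_blk, length.out = n_g), n_r))
  y <- 25 + rnorm(n_g, 0, 5)[as.integer(factor(g))] + rnorm(n_g * n_r, 0, 2)
  vc <- fit_alpha_lattice(y, g, r, blk)
  expect_true(vc$converged)
  expect_lte(vc$sigma2_rep, 0.05 * vc$sigma2_e)
  expect_lte(vc$sigma2_block, 0.05 * vc$sigma2_e)
  expect_equal(vc$sigma2_g, 25, tolerance = 0.5 * 25)
  expect_error(fit_alpha_lattice(y, g, r[-1], blk), "lengths differ")
})

test_that("alpha-lattice with one block per rep collapses to RCBD", {
  d <- sim_rcbd(40, 2, var_g = 16, var_b = 2, var_e = 4, seed = 8)
  vc_r <- fit_rcbd(d$y, d$g, d$b)
  vc_a <- fit_alpha_lattice(d$y, d$g, rep = d$b, block = rep("b1", 80))
  expect_equal(vc_a$sigma2_g, vc_r$sigma2_g, tolerance = 1e-4)
  expect_equal(vc_a$sigma2_e, vc_r$sigma2_e, tolerance = 1e-4)
  # rep and rep:block are aliased; only their sum is identified
  expect_equal(vc_a$sigma2_rep + vc_a$sigma2_block, vc_r$sigma2_block,
               tolerance = 1e-3)
  # determinism
  expect_equal(fit_alpha_lattice(d$y, d$g, d$b, rep("b1", 80))$sigma2_g,
               vc_a$sigma2_g)
})

test_that("broad_sense_h2 applies the entry-mean formula", {
  vc <- starchnir:::vc_result(sigma2_g = 4, sigma2_e = 2, nRep = 2)
  expect_equal(broad_sense_h2(vc), 80)
  expect_equal(broad_sense_h2(starchnir:::vc_result(0, NA, 0, 5, 2)), 0)
  expect_equal(broad_sense_h2(starchnir:::vc_result(5, NA, 0, 0, 2)), 100)
  expect_true(is.na(broad_sense_h2(starchnir:::vc_result(0, NA, 0, 0, 2))))
  # monotone in sigma2_g and nRep
  h <- vapply(c(1, 2, 4, 8), function(vg)
    broad_sense_h2(starchnir:::vc_result(vg, NA, 0, 4, 2)), numeric(1))
  expect_true(all(diff(h) > 0))
  h2 <- vapply(c(1, 2, 3), function(nr)
    broad_sense_h2(starchnir:::vc_result(4, NA, 0, 4, nr)), numeric(1))
  expect_true(all(diff(h2) > 0))
  expect_true(all(h >= 0 & h <= 100) && all(h2 >= 0 & h2 <= 100))
})

test_that("heritability recovery across a small design grid", {
  # light version of the full recovery study in the acceptance suite
  for (ratio in c(0.25, 4)) {
    var_g <- 4 * ratio
    h_true <- 100 * var_g / (var_g + 4 / 2)
    h_hat <- vapply(1:20, function(s) {
      d <- sim_rcbd(60, 2, var_g, var_b = 1, var_e = 4, seed = 300 + s)
      broad_sense_h2(fit_rcbd(d$y, d$g, d$b))
    }, numeric(1))
    expect_lt(abs(mean(h_hat) - h_true), 7)
  }
})

test_that("spectral scan is consistent with single-trait fits", {
  d <- sim_rcbd(30, 2, var_g = 25, var_b = 1, var_e = 4, seed = 41)
  X <- cbind(`900` = d$y, `901` = rnorm(60))
  scan <- spectral_heritability_scan(X, d$g, block = d$b, design = "RCBD")
  single <- broad_sense_h2(fit_rcbd(d$y, d$g, d$b))
  expect_equal(scan$H2[1], single, tolerance = 1e-8)
  expect_equal(scan$wavelength, c(900, 901))
  expect_lt(scan$H2[2], scan$H2[1])
  expect_true(all(scan$H2 >= 0 & scan$H2 <= 100, na.rm = TRUE))
})

test_that("pure-noise spectra have near-zero mean heritability", {
  set.seed(42)
  n_g <- 40
  g <- rep(sprintf("g%03d", 1:n_g), 2)
  b <- rep(c("b1", "b2"), each = n_g)
  X <- matrix(rnorm(2 * n_g * 25), 2 * n_g, 25,
              dimnames = list(NULL, 800 + 1:25))
  scan <- spectral_heritability_scan(X, g, block = b, design = "RCBD")
  expect_lt(mean(scan$H2, na.rm = TRUE), 10)
})
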