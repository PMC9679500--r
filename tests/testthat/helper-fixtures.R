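# Shared fixtures and independent oracles.

# small, fast simulation worlds used across test files
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(genotypes_per_trial = 30L, n_trials = 1L, n_reps = 2L,
         seed = 42L),
    list(...))
  do.call(sim_config, args)
}

multi_trial_config <- function(...) {
  args <- utils::modifyList(
    list(n_trials = 4L, genotypes_per_trial = 20L,
         shared_genotype_fraction = 0.3,
         design = c("RCBD", "ALPHA_LATTICE", "RCBD", "ALPHA_LATTICE"),
         blocks_per_rep = 4L, n_reps = 2L, seed = 99L),
    list(...))
  do.call(sim_config, args)
}

make_samples <- function(config = tiny_config()) {
  ref <- simulate_reference(config)
  list(reference = ref,
       samples = average_scans(simulate_spectra(ref, config)))
}

# ANOVA method-of-moments closed form for a balanced RCBD:
# sigma2_e = MSE, sigma2_g = (MS_G - MSE) / r, sigma2_b = (MS_B - MSE) / g
anova_rcbd_oracle <- function(values, genotype, block) {
  g <- factor(genotype); b <- factor(block)
  ng <- nlevels(g); nb <- nlevels(b)
  mu <- mean(values)
  gm <- tapply(values, g, mean)
  bm <- tapply(values, b, mean)
  ss_g <- nb * sum((gm - mu)^2)
  ss_b <- ng * sum((bm - mu)^2)
  fitted <- gm[g] + bm[b] - mu
  ss_e <- sum((values - fitted)^2)
  ms_g <- ss_g / (ng - 1)
  ms_b <- ss_b / (nb - 1)
  ms_e <- ss_e / ((ng - 1) * (nb - 1))
  list(sigma2_g = max(0, (ms_g - ms_e) / nb),
       sigma2_block = max(0, (ms_b - ms_e) / ng),
       sigma2_e = ms_e)
}

# brute-force Savitzky-Golay oracle: per interior point, least-squares
# polynomial over the window via lm with a matrix response
sg_oracle <- function(X, window, polyorder, deriv) {
  h <- (window - 1L) / 2L
  p <- ncol(X)
  idx <- (h + 1L):(p - h)
  z <- seq(-h, h)
  out <- matrix(NA_real_, nrow(X), length(idx))
  for (j in seq_along(idx)) {
    Y <- t(X[, (idx[j] - h):(idx[j] + h), drop = FALSE])
    fit <- stats::lm(Y ~ poly(z, polyorder, raw = TRUE))
    out[, j] <- stats::coef(fit)[deriv + 1L, ] * factorial(deriv)
  }
  out
}

# direct sliding-window re-computation of the gap-segment derivative
gapseg_oracle <- function(X, gap, segment) {
  w <- 2L * segment + gap
  h <- (w - 1L) / 2L
  p <- ncol(X)
  out <- matrix(NA_real_, nrow(X), p - 2L * h)
  for (i in seq_len(nrow(X))) {
    for (j in (h + 1L):(p - h)) {
      left <- mean(X[i, (j - h):(j - h + segment - 1L)])
      right <- mean(X[i, (j + h - segment + 1L):(j + h)])
      out[i, j - h] <- (right - left) / (segment + gap)
    }
  }
  out
}

# simple matrix + metadata spectra_set used by io/pretreatment tests
toy_spectra <- function(n = 5L, wavelengths = 740:1070, seed = 1L) {
  set.seed(seed)
  refl <- matrix(stats::runif(n * length(wavelengths), 0.3, 0.6), n)
  meta <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                     genotype_id = sprintf("g%02d", seq_len(n)),
                     trial_id = "T01", rep = "R01", block = "B01",
                     scan_index = 1L)
  spectra_set(wavelengths, refl, meta)
}
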