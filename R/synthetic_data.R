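# Synthetic multi-trial field designs and forward-modelled NIR spectra.
# The generator is the package's test bed: the study's raw spectra are not
# deposited, so every downstream stage is validated against simulated data
# with known ground truth (variance components, band positions, loadings).

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Describes a stated world: a set of cassava-style field trials (RCBD or
#' alpha-lattice), the variance components of the starch phenotype, and a
#' spectral forward model that maps plot starch to 740--1070 nm
#' reflectance. Defaults emulate the magnitudes of a high-variability
#' preliminary yield trial (plot CV ~ 0.27, entry-mean heritability ~ 0.9)
#' with starch- and water-linked Gaussian absorption bands between 815 and
#' 980 nm riding on a flat baseline with per-scan multiplicative/additive
#' scatter and noise.
#'
#' @param n_trials number of trials.
#' @param genotypes_per_trial genotypes evaluated in each trial.
#' @param shared_genotype_fraction fraction of each trial's genotypes drawn
#'   from a pool shared across all trials (same genetic effect everywhere).
#' @param design trial design(s), `"RCBD"` or `"ALPHA_LATTICE"`; recycled
#'   across trials.
#' @param n_reps complete replicates per trial.
#' @param blocks_per_rep incomplete blocks per replicate (alpha-lattice).
#' @param starch_mean overall mean starch, % fresh mass.
#' @param var_g,var_rep,var_block,var_e variance components (%^2) of
#'   genotype, replicate, block and residual effects.
#' @param band_centers,band_widths,band_loadings starch-linked Gaussian
#'   absorption bands: centres (nm), SD widths (nm) and loadings
#'   (reflectance units per % starch).
#' @param water_band_center,water_band_width water band position/width (nm).
#' @param water_const,water_coef water-band amplitude is
#'   `water_const - water_coef * starch` (more starch, less free water).
#' @param baseline_level flat baseline reflectance.
#' @param scatter_slope_sd,scatter_offset_sd per-scan multiplicative slope
#'   SD (unitless) and additive offset SD (reflectance units).
#' @param noise_sd per-sample spectral noise SD (reflectance units).
#' @param scan_noise_sd extra per-scan (within-plot) noise SD; default 10%
#'   of `noise_sd`.
#' @param scans_per_sample technical scans recorded per sample.
#' @param wavelengths integer wavelength grid, fixed by default to the
#'   740--1070 nm, 1 nm short-wave grid.
#' @param seed integer seed; the whole simulation is bit-reproducible.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_trials = 1L,
                       genotypes_per_trial = 150L,
                       shared_genotype_fraction = 0.25,
                       design = "RCBD",
                       n_reps = 2L,
                       blocks_per_rep = 5L,
                       starch_mean = 25,
                       var_g = 36,
                       var_rep = 1,
                       var_block = 1,
                       var_e = 6,
                       band_centers = c(880, 912, 960, 975),
                       band_widths = c(15, 15, 12, 10),
                       band_loadings = c(0.0020, 0.0018, 0.0012, 0.0008),
                       water_band_center = 970,
                       water_band_width = 12,
                       water_const = 0.05,
                       water_coef = 0.0008,
                       baseline_level = 0.40,
                       scatter_slope_sd = 0.02,
                       scatter_offset_sd = 0.01,
                       noise_sd = 0.002,
                       scan_noise_sd = NULL,
                       scans_per_sample = 3L,
                       wavelengths = 740:1070,
                       seed = 1L) {
  if (is.null(scan_noise_sd)) scan_noise_sd <- 0.1 * noise_sd
  cfg <- list(
    n_trials = as.integer(n_trials),
    genotypes_per_trial = as.integer(genotypes_per_trial),
    shared_genotype_fraction = shared_genotype_fraction,
    design = rep_len(toupper(design), n_trials),
    n_reps = as.integer(n_reps),
    blocks_per_rep = as.integer(blocks_per_rep),
    starch_mean = starch_mean,
    var_g = var_g, var_rep = var_rep, var_block = var_block, var_e = var_e,
    band_centers = band_centers, band_widths = band_widths,
    band_loadings = band_loadings,
    water_band_center = water_band_center,
    water_band_width = water_band_width,
    water_const = water_const, water_coef = water_coef,
    baseline_level = baseline_level,
    scatter_slope_sd = scatter_slope_sd,
    scatter_offset_sd = scatter_offset_sd,
    noise_sd = noise_sd, scan_noise_sd = scan_noise_sd,
    scans_per_sample = as.integer(scans_per_sample),
    wavelengths = as.integer(wavelengths),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  vars <- c("var_g", "var_rep", "var_block", "var_e")
  if (any(unlist(cfg[vars]) < 0)) stop("variances must be >= 0",
                                       call. = FALSE)
  if (!all(cfg$design %in% c("RCBD", "ALPHA_LATTICE"))) {
    stop("design must be RCBD or ALPHA_LATTICE", call. = FALSE)
  }
  nb <- lengths(cfg[c("band_centers", "band_widths", "band_loadings")])
  if (length(unique(nb)) != 1L) stop("band lists must have equal length",
                                     call. = FALSE)
  if (cfg$shared_genotype_fraction < 0 || cfg$shared_genotype_fraction > 1) {
    stop("shared_genotype_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_trials < 1L || cfg$genotypes_per_trial < 2L || cfg$n_reps < 1L) {
    stop("need >= 1 trial, >= 2 genotypes and >= 1 rep", call. = FALSE)
  }
  if (any(cfg$design == "ALPHA_LATTICE") && cfg$blocks_per_rep < 2L) {
    stop("alpha-lattice designs need >= 2 blocks per rep", call. = FALSE)
  }
  check_grid(cfg$wavelengths)
  invisible(cfg)
}

#' Simulate a multi-trial reference phenotype table
#'
#' Plot values are generated from exactly the mixed models later fitted by
#' the heritability module: for RCBD trials
#' `Y = mu + G_i + b_j + e_ij`, and for alpha-lattice trials
#' `Y = mu + G_i + Rep_j + b_k(j) + e_ijk`, with all effects independent
#' normal with the configured variances. A `shared_genotype_fraction` of
#' each trial's entries comes from a pool whose genetic effects are
#' identical across trials.
#'
#' @param config a [sim_config()].
#' @return a reference table (see [validate_reference()]).
#' @export
simulate_reference <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n_shared <- round(config$shared_genotype_fraction *
                        config$genotypes_per_trial)
    shared_ids <- if (n_shared > 0) sprintf("GS%04d", seq_len(n_shared))
                  else character(0)
    shared_eff <- stats::rnorm(n_shared, 0, sqrt(config$var_g))
    names(shared_eff) <- shared_ids
    rows <- vector("list", config$n_trials)
    for (tr in seq_len(config$n_trials)) {
      trial_id <- sprintf("T%02d", tr)
      n_own <- config$genotypes_per_trial - n_shared
      own_ids <- if (n_own > 0) sprintf("%s_G%04d", trial_id, seq_len(n_own))
                 else character(0)
      own_eff <- stats::rnorm(n_own, 0, sqrt(config$var_g))
      gids <- c(shared_ids, own_ids)
      geff <- c(shared_eff, stats::setNames(own_eff, own_ids))
      design <- config$design[tr]
      per_rep <- vector("list", config$n_reps)
      for (r in seq_len(config$n_reps)) {
        if (design == "RCBD") {
          # one complete block per replicate; block == rep
          block <- rep(sprintf("B%02d", r), length(gids))
          rep_eff <- 0
          blk_eff <- stats::rnorm(1, 0, sqrt(config$var_block))
          blk_eff <- rep(blk_eff, length(gids))
        } else {
          nb <- config$blocks_per_rep
          blk_id <- rep(seq_len(nb), length.out = length(gids))
          blk_id <- sample(blk_id)   # randomize genotypes into blocks
          block <- sprintf("B%02d", blk_id)
          rep_eff <- stats::rnorm(1, 0, sqrt(config$var_rep))
          b_eff <- stats::rnorm(nb, 0, sqrt(config$var_block))
          blk_eff <- b_eff[blk_id]
        }
        e <- stats::rnorm(length(gids), 0, sqrt(config$var_e))
        starch <- config$starch_mean + geff[gids] + rep_eff + blk_eff + e
        per_rep[[r]] <- data.frame(
          trial_id = trial_id,
          genotype_id = gids,
          rep = sprintf("R%02d", r),
          block = block,
          design = design,
          starch = as.numeric(starch),
          stringsAsFactors = FALSE
        )
      }
      rows[[tr]] <- do.call(rbind, per_rep)
    }
    ref <- do.call(rbind, rows)
    # keep phenotypes physically valid; never triggers at default scales
    ref$starch <- pmin(pmax(ref$starch, 0.5), 99.5)
    ref$sample_id <- paste(ref$trial_id, ref$genotype_id, ref$rep, sep = ".")
    rownames(ref) <- NULL
    validate_reference(ref)
    ref
  })
}

band_profile <- function(wavelengths, center, width) {
  exp(-(wavelengths - center)^2 / (2 * width^2))
}

#' Noise-free expected spectrum for a starch value
#'
#' The deterministic part of the forward model: baseline plus starch-linked
#' absorption bands plus a water band whose amplitude decreases with
#' starch.
#'
#' @param starch starch value (% fresh mass), scalar.
#' @param config a [sim_config()].
#' @return numeric vector over `config$wavelengths`.
#' @export
expected_spectrum <- function(starch, config) {
  w <- config$wavelengths
  sig <- rep(config$baseline_level, length(w))
  for (k in seq_along(config$band_centers)) {
    sig <- sig + config$band_loadings[k] * starch *
      band_profile(w, config$band_centers[k], config$band_widths[k])
  }
  amp_w <- config$water_const - config$water_coef * starch
  sig + amp_w * band_profile(w, config$water_band_center,
                             config$water_band_width)
}

#' Simulate NIR spectra for a reference table
#'
#' For each plot, `scans_per_sample` technical scans are generated as
#' `(1 + slope) * signal + offset + noise`, where `signal` is
#' [expected_spectrum()] of the plot's starch value plus a per-sample
#' spectral deviation (SD `noise_sd`, shared across the plot's scans);
#' `slope` and `offset` are per-scan scatter draws and the per-scan noise
#' has SD `scan_noise_sd`.
#'
#' @param reference a reference table with starch values.
#' @param config a [sim_config()].
#' @return a [spectra_set()] with one row per scan.
#' @export
simulate_spectra <- function(reference, config) {
  validate_sim_config(config)
  if (!"starch" %in% names(reference) || anyNA(reference$starch)) {
    stop("reference rows must carry starch values", call. = FALSE)
  }
  w <- config$wavelengths
  p <- length(w)
  n_plot <- nrow(reference)
  s <- config$scans_per_sample
  with_seed(config$seed + 1L, {
    refl <- matrix(0, n_plot * s, p)
    meta <- vector("list", n_plot)
    for (i in seq_len(n_plot)) {
      sig <- expected_spectrum(reference$starch[i], config)
      sig <- sig + stats::rnorm(p, 0, config$noise_sd)
      for (j in seq_len(s)) {
        slope <- stats::rnorm(1, 0, config$scatter_slope_sd)
        offset <- stats::rnorm(1, 0, config$scatter_offset_sd)
        scan <- (1 + slope) * sig + offset +
          stats::rnorm(p, 0, config$scan_noise_sd)
        refl[(i - 1L) * s + j, ] <- scan
      }
      meta[[i]] <- data.frame(
        sample_id = reference$sample_id[i],
        genotype_id = reference$genotype_id[i],
        trial_id = reference$trial_id[i],
        rep = reference$rep[i],
        block = reference$block[i],
        scan_index = seq_len(s),
        stringsAsFactors = FALSE
      )
    }
    spectra_set(w, refl, do.call(rbind, meta))
  })
}

#' Shift one sample's spectra to plant an outlier
#'
#' Adds `magnitude` times the per-wavelength SD (computed across all rows)
#' to every scan of the chosen sample. A fixture for validating the
#' Mahalanobis outlier filter.
#'
#' @param spectra a [spectra_set()].
#' @param sample_id the sample to displace.
#' @param magnitude shift size in multiples of the per-wavelength SD.
#' @return the modified `spectra_set`.
#' @export
plant_outlier <- function(spectra, sample_id, magnitude) {
  rows <- which(spectra$meta$sample_id == sample_id)
  if (!length(rows)) stop("unknown sample_id: ", sample_id, call. = FALSE)
  sds <- apply(spectra$reflectance, 2, stats::sd)
  refl <- spectra$reflectance
  refl[rows, ] <- refl[rows, , drop = FALSE] +
    rep(magnitude * sds, each = length(rows))
  spectra_set(spectra$wavelengths, refl, spectra$meta)
}
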