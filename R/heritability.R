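# REML variance components for the two field-design models and
# broad-sense heritability, for the starch trait and per wavelength.
# lme4 is the REML engine (the standard in plant-breeding analysis); the
# balanced-design ANOVA closed form serves as the independent oracle in
# the test suite.

vc_result <- function(sigma2_g = 0, sigma2_rep = NA_real_,
                      sigma2_block = 0, sigma2_e = 0, nRep = 1,
                      converged = TRUE, loglik = NA_real_) {
  structure(list(sigma2_g = sigma2_g, sigma2_rep = sigma2_rep,
                 sigma2_block = sigma2_block, sigma2_e = sigma2_e,
                 nRep = nRep, converged = converged, loglik = loglik),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components> sigma2_g=", signif(x$sigma2_g, 5),
      " sigma2_rep=", signif(x$sigma2_rep, 5),
      " sigma2_block=", signif(x$sigma2_block, 5),
      " sigma2_e=", signif(x$sigma2_e, 5),
      " nRep=", signif(x$nRep, 4),
      " converged=", x$converged, "\n", sep = "")
  invisible(x)
}

mean_reps <- function(genotype) {
  mean(table(genotype))
}

extract_vc <- function(fit, term) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  hit <- vc$vcov[vc$grp == term]
  if (length(hit)) hit[1L] else 0
}

lmer_quiet <- function(formula, data) {
  # bobyqa with a tight trust-region radius: matches the balanced-design
  # ANOVA closed form to ~1e-7 relative, which the oracle tests require
  ctrl <- lme4::lmerControl(optimizer = "bobyqa",
                            check.conv.singular = "ignore",
                            calc.derivs = FALSE,
                            optCtrl = list(rhoend = 1e-13))
  withCallingHandlers(
    tryCatch(lme4::lmer(formula, data = data, REML = TRUE, control = ctrl),
             error = function(e) e),
    message = function(m) invokeRestart("muffleMessage"),
    warning = function(w) invokeRestart("muffleWarning")
  )
}

#' REML variance components for an RCBD trial
#'
#' Fits `value ~ (1 | genotype) + (1 | block)` by REML (genotype and block
#' random, intercept fixed) and returns the genotype, block and residual
#' variance components together with the mean number of replications per
#' genotype. Non-convergence is flagged on the result, not thrown.
#'
#' @param values plot-level trait or reflectance values.
#' @param genotype,block factors/labels per plot.
#' @return a `variance_components` object.
#' @export
fit_rcbd <- function(values, genotype, block) {
  if (length(unique(genotype)) < 2L) stop("need >= 2 genotypes",
                                          call. = FALSE)
  nrep <- mean_reps(genotype)
  if (stats::var(values) < 1e-24) {
    return(vc_result(0, NA_real_, 0, 0, nrep, TRUE, NA_real_))
  }
  df <- data.frame(y = values, g = factor(genotype), b = factor(block))
  fit <- lmer_quiet(y ~ (1 | g) + (1 | b), df)
  if (inherits(fit, "error")) {
    return(vc_result(NA_real_, NA_real_, NA_real_, NA_real_, nrep, FALSE))
  }
  conv <- length(fit@optinfo$conv$lme4) == 0L
  vc_result(sigma2_g = extract_vc(fit, "g"),
            sigma2_rep = NA_real_,
            sigma2_block = extract_vc(fit, "b"),
            sigma2_e = stats::sigma(fit)^2,
            nRep = nrep, converged = conv,
            loglik = as.numeric(stats::logLik(fit)))
}

#' REML variance components for an alpha-lattice trial
#'
#' Fits `value ~ (1 | genotype) + (1 | rep) + (1 | rep:block)` by REML:
#' genotype, replicate and incomplete block nested within replicate all
#' random. The printed field-design model reuses one variance symbol for
#' replicates and blocks; here a distinct replicate component is
#' estimated.
#'
#' @param values plot-level values.
#' @param genotype,rep,block labels per plot; blocks nested in reps.
#' @return a `variance_components` object.
#' @export
fit_alpha_lattice <- function(values, genotype, rep, block) {
  if (length(unique(genotype)) < 2L) stop("need >= 2 genotypes",
                                          call. = FALSE)
  n <- length(values)
  if (length(genotype) != n || length(rep) != n || length(block) != n) {
    stop("argument lengths differ", call. = FALSE)
  }
  nrep <- mean_reps(genotype)
  if (stats::var(values) < 1e-24) {
    return(vc_result(0, 0, 0, 0, nrep, TRUE, NA_real_))
  }
  df <- data.frame(y = values, g = factor(genotype), r = factor(rep),
                   b = factor(paste(rep, block, sep = ":")))
  fit <- lmer_quiet(y ~ (1 | g) + (1 | r) + (1 | b), df)
  if (inherits(fit, "error")) {
    return(vc_result(NA_real_, NA_real_, NA_real_, NA_real_, nrep, FALSE))
  }
  conv <- length(fit@optinfo$conv$lme4) == 0L
  vc_result(sigma2_g = extract_vc(fit, "g"),
            sigma2_rep = extract_vc(fit, "r"),
            sigma2_block = extract_vc(fit, "b"),
            sigma2_e = stats::sigma(fit)^2,
            nRep = nrep, converged = conv,
            loglik = as.numeric(stats::logLik(fit)))
}

#' Broad-sense heritability on the 0-100 scale
#'
#' `H2 = 100 * sigma2_g / (sigma2_g + sigma2_e / nRep)`: the entry-mean
#' fraction of phenotypic variance attributable to genotype.
#'
#' @param vc a `variance_components` object.
#' @return H2 in `[0, 100]`, or `NA` when all variances are zero.
#' @export
broad_sense_h2 <- function(vc) {
  if (!isTRUE(vc$converged)) return(NA_real_)
  denom <- vc$sigma2_g + vc$sigma2_e / vc$nRep
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  100 * vc$sigma2_g / denom
}

#' Per-wavelength broad-sense heritability scan
#'
#' Fits the trial-appropriate mixed model independently at every
#' wavelength of plot-level spectra and reports the variance components
#' and H2 profile. Per-wavelength non-convergence is recorded and the scan
#' continues.
#'
#' @param X plot-level reflectance matrix (one row per plot) or
#'   [spectra_set()] after [average_scans()].
#' @param genotype,rep,block design labels per row.
#' @param design `"RCBD"` or `"ALPHA_LATTICE"`.
#' @param wavelengths optional wavelength labels (defaults to column
#'   names).
#' @return data.frame with `wavelength`, `sigma2_g`, `sigma2_rep`,
#'   `sigma2_block`, `sigma2_e`, `H2`, `converged`.
#' @export
spectral_heritability_scan <- function(X, genotype, rep = NULL,
                                       block, design = "RCBD",
                                       wavelengths = NULL) {
  X <- as_X(X)
  design <- toupper(design)
  wl <- wavelengths %||% suppressWarnings(as.numeric(colnames(X)))
  if (is.null(wl) || anyNA(wl)) wl <- seq_len(ncol(X))
  rows <- lapply(seq_len(ncol(X)), function(j) {
    vc <- if (design == "RCBD") {
      fit_rcbd(X[, j], genotype, block)
    } else {
      fit_alpha_lattice(X[, j], genotype, rep, block)
    }
    data.frame(wavelength = wl[j],
               sigma2_g = vc$sigma2_g,
               sigma2_rep = vc$sigma2_rep,
               sigma2_block = vc$sigma2_block,
               sigma2_e = vc$sigma2_e,
               H2 = broad_sense_h2(vc),
               converged = vc$converged)
  })
  do.call(rbind, rows)
}
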