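# Validation engine: genotype-grouped 70/30 resampling, the prediction
# metric suite, and the CV0/CV00/CV1/CV2 genotype-by-environment schemes.

#' Genotype-grouped train/test split
#'
#' Groups (genotypes), not plots, are sampled without replacement; every
#' plot of a group lands on the same side. The training set receives
#' `floor(train_fraction * n_groups)` groups.
#'
#' @param groups grouping label per row (e.g. genotype ids).
#' @param train_fraction fraction of groups assigned to training.
#' @param seed integer seed.
#' @return list with `train_idx`, `test_idx`, `train_groups`,
#'   `test_groups`.
#' @export
grouped_split <- function(groups, train_fraction = 0.7, seed = 1L) {
  g <- unique(groups)
  if (length(g) < 2L) stop("need at least 2 groups to split", call. = FALSE)
  n_train <- floor(train_fraction * length(g))
  if (n_train < 1L || n_train >= length(g)) {
    stop("train_fraction leaves an empty side", call. = FALSE)
  }
  train_g <- with_seed(seed, sample(g, n_train))
  is_train <- groups %in% train_g
  list(train_idx = which(is_train), test_idx = which(!is_train),
       train_groups = train_g, test_groups = setdiff(g, train_g))
}

#' Prediction-quality metric suite
#'
#' Computes the metric bundle used to judge NIRS calibrations: `r2p`
#' (squared Pearson correlation), `rmsep`, `bias` (mean of
#' predicted - observed), `sep` (sample SD of the residuals,
#' bias-corrected), `rpd` (SD(obs)/RMSEP), `rpiq` (IQR(obs)/RMSEP,
#' type-7 quantiles) and Lin's concordance `ccc` computed with
#' n-denominator moments. When RMSEP is 0 (perfect agreement) `rpd` and
#' `rpiq` are undefined and reported as `NA`.
#'
#' @param observed,predicted numeric vectors of equal length >= 3.
#' @return one-row data.frame of metrics.
#' @export
compute_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3L) {
    stop("need equal-length vectors of at least 3 values", call. = FALSE)
  }
  if (stats::sd(observed) == 0) stop("constant observed values: metrics ",
                                     "undefined", call. = FALSE)
  res <- predicted - observed
  rmsep <- sqrt(mean(res^2))
  n <- length(observed)
  mo <- mean(observed); mp <- mean(predicted)
  so <- mean((observed - mo)^2)   # n-denominator moments for CCC
  sp <- mean((predicted - mp)^2)
  sop <- mean((observed - mo) * (predicted - mp))
  ccc <- 2 * sop / (so + sp + (mo - mp)^2)
  r2p <- if (stats::sd(predicted) == 0) 0 else
    stats::cor(observed, predicted)^2
  data.frame(
    r2p = r2p,
    rmsep = rmsep,
    bias = mean(res),
    sep = stats::sd(res),
    rpd = if (rmsep == 0) NA_real_ else stats::sd(observed) / rmsep,
    rpiq = if (rmsep == 0) NA_real_ else
      unname(stats::IQR(observed, type = 7) / rmsep),
    ccc = ccc
  )
}

#' Assemble an aligned modelling dataset
#'
#' Averages scans to one spectrum per sample, joins the plot-level
#' reference table by `sample_id` and returns the aligned matrices the
#' modelling and evaluation functions consume.
#'
#' @param spectra a [spectra_set()] (scan- or sample-level).
#' @param reference a reference table.
#' @param average average repeated scans first (default TRUE).
#' @return list with `X`, `y`, `genotype`, `trial`, `rep`, `block`,
#'   `sample_id`, `design`, `wavelengths`.
#' @export
assemble_dataset <- function(spectra, reference, average = TRUE) {
  validate_reference(reference)
  s <- if (average) average_scans(spectra) else spectra
  idx <- match(s$meta$sample_id, reference$sample_id)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no spectra match the reference table",
                       call. = FALSE)
  idx <- idx[keep]
  list(X = s$reflectance[keep, , drop = FALSE],
       y = reference$starch[idx],
       genotype = reference$genotype_id[idx],
       trial = reference$trial_id[idx],
       rep = reference$rep[idx],
       block = reference$block[idx],
       design = reference$design[idx],
       sample_id = reference$sample_id[idx],
       wavelengths = s$wavelengths)
}

#' Repeated within-trial evaluation
#'
#' The core resampling loop: per iteration a genotype-grouped
#' 70/30 split, 5-fold hyperparameter tuning on the training side, a final
#' fit, and the metric suite on the held-out test side. Reports the full
#' per-iteration table plus mean/SD aggregates.
#'
#' @param X predictor matrix (pretreated spectra, one row per sample).
#' @param y observed starch values.
#' @param genotype genotype label per row (grouping key).
#' @param algorithm `"PLSR"`, `"SVM_RADIAL"` or `"RF"`.
#' @param niter number of split iterations (default 50).
#' @param train_fraction fraction of genotypes in training (default 0.7).
#' @param k tuning folds (default 5).
#' @param seed integer seed; iteration i uses `seed + i`.
#' @param ... passed to [select_hyperparameters()].
#' @return an `evaluation_result`: list with `iterations` (data.frame) and
#'   `summary` (mean and SD rows).
#' @export
within_trial_evaluate <- function(X, y, genotype, algorithm = "PLSR",
                                  niter = 50L, train_fraction = 0.7,
                                  k = 5L, seed = 1L, ...) {
  X <- as_X(X)
  rows <- vector("list", niter)
  for (i in seq_len(niter)) {
    it_seed <- seed + i
    sp <- grouped_split(genotype, train_fraction, seed = it_seed)
    Xtr <- X[sp$train_idx, , drop = FALSE]
    ytr <- y[sp$train_idx]
    tune <- select_hyperparameters(Xtr, ytr, algorithm, k = k,
                                   seed = it_seed,
                                   groups = genotype[sp$train_idx], ...)
    model <- fit_model(Xtr, ytr, algorithm, tune$hyperparams)
    pred <- predict(model, X[sp$test_idx, , drop = FALSE])
    met <- compute_metrics(y[sp$test_idx], pred)
    met$r2cv <- tune$r2cv
    met$rmsecv <- tune$rmsecv
    met$iteration <- i
    met$hyperparams <- paste(names(tune$hyperparams),
                             vapply(tune$hyperparams, function(v)
                               paste(signif(unlist(v), 4), collapse = "/"),
                               character(1)),
                             sep = "=", collapse = ";")
    rows[[i]] <- met
  }
  iterations <- do.call(rbind, rows)
  num <- c("r2p", "rmsep", "bias", "sep", "rpd", "rpiq", "ccc", "r2cv",
           "rmsecv")
  summary <- rbind(
    data.frame(stat = "mean", t(colMeans(iterations[num], na.rm = TRUE))),
    data.frame(stat = "sd", t(apply(iterations[num], 2, stats::sd,
                                    na.rm = TRUE)))
  )
  structure(list(iterations = iterations, summary = summary,
                 algorithm = algorithm, niter = niter, seed = seed),
            class = "evaluation_result")
}

#' Build genotype-by-environment validation plans
#'
#' The four breeder-relevant schemes, each plan a train/test row split over
#' an aligned multi-trial dataset:
#' * `CV2` (tested genotypes, tested environments): `round(0.3 * G)` of the
#'   focal trial's genotypes form the test set; all remaining plots of the
#'   focal trial and all plots of every other trial train the model.
#' * `CV1` (untested genotypes, tested environments): same test sets as CV2
#'   under the same seed, but every plot of a test-set genotype (in any
#'   trial) is removed from training.
#' * `CV0` (tested genotypes, untested environments): the entire focal
#'   trial is the test set; all other trials train the model.
#' * `CV00` (untested genotypes, untested environments): as CV0, but all
#'   genotypes occurring in the focal trial are removed from training.
#'
#' CV1/CV2 are resampled (`niter` plans); CV0/CV00 are deterministic single
#' plans.
#'
#' @param scheme one of `"CV2"`, `"CV1"`, `"CV0"`, `"CV00"`.
#' @param genotype,trial aligned label vectors (one entry per sample row).
#' @param focal_trial the trial treated as the prediction target.
#' @param seed integer seed; CV1/CV2 iteration i draws with `seed + i`.
#' @param niter plans for CV1/CV2 (default 50).
#' @param test_fraction genotype fraction tested under CV1/CV2.
#' @return list of plans, each with `train_idx`, `test_idx`,
#'   `test_genotypes`, `scheme`, `focal_trial`, `iteration`.
#' @export
build_cv_scheme <- function(scheme = c("CV2", "CV1", "CV0", "CV00"),
                            genotype, trial, focal_trial, seed = 1L,
                            niter = 50L, test_fraction = 0.3) {
  scheme <- match.arg(scheme)
  if (length(unique(trial)) < 2L) {
    stop("cross-trial schemes need at least 2 trials", call. = FALSE)
  }
  if (!focal_trial %in% trial) stop("focal trial not present: ",
                                    focal_trial, call. = FALSE)
  in_focal <- trial == focal_trial
  focal_geno <- unique(genotype[in_focal])
  plan <- function(train_idx, test_idx, test_g, it) {
    list(scheme = scheme, focal_trial = focal_trial, iteration = it,
         train_idx = train_idx, test_idx = test_idx,
         test_genotypes = test_g)
  }
  if (scheme %in% c("CV0", "CV00")) {
    test_idx <- which(in_focal)
    train_idx <- if (scheme == "CV0") {
      which(!in_focal)
    } else {
      which(!in_focal & !genotype %in% focal_geno)
    }
    return(list(plan(train_idx, test_idx, focal_geno, 1L)))
  }
  n_test <- round(test_fraction * length(focal_geno))
  if (n_test < 1L || n_test >= length(focal_geno)) {
    stop("test_fraction leaves an empty side for trial ", focal_trial,
         call. = FALSE)
  }
  lapply(seq_len(niter), function(i) {
    test_g <- with_seed(seed + i, sample(focal_geno, n_test))
    test_idx <- which(in_focal & genotype %in% test_g)
    train_idx <- if (scheme == "CV2") {
      setdiff(seq_along(genotype), test_idx)
    } else {
      which(!genotype %in% test_g)
    }
    plan(train_idx, test_idx, test_g, i)
  })
}

#' Run the CV schemes over a multi-trial dataset
#'
#' Orchestrates [build_cv_scheme()], pretreatment, tuning, fitting and the
#' metric suite into a tidy long-format result table.
#'
#' @param spectra a [spectra_set()] (scans or samples).
#' @param reference a reference table covering all trials.
#' @param pretreatments character vector of pretreatment ids.
#' @param algorithms character vector of algorithm tags.
#' @param schemes subset of `c("CV2", "CV1", "CV0", "CV00")`.
#' @param focal_trials trials to evaluate (default: all).
#' @param niter iterations for CV1/CV2 (single plan for CV0/CV00).
#' @param k tuning folds.
#' @param seed integer seed.
#' @param ... passed to [select_hyperparameters()].
#' @return data.frame with one row per
#'   scheme x trial x pretreatment x algorithm x iteration.
#' @export
run_cv_schemes <- function(spectra, reference,
                           pretreatments = "RAW", algorithms = "PLSR",
                           schemes = c("CV2", "CV1", "CV0", "CV00"),
                           focal_trials = NULL, niter = 50L, k = 5L,
                           seed = 1L, ...) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  out <- list()
  for (pre in pretreatments) {
    treated <- apply_pretreatment(spectra, pre)
    data <- assemble_dataset(treated, reference)
    trials <- focal_trials %||% sort(unique(data$trial))
    for (scheme in schemes) {
      for (tr in trials) {
        plans <- build_cv_scheme(scheme, data$genotype, data$trial, tr,
                                 seed = seed, niter = niter)
        for (algo in algorithms) {
          for (pl in plans) {
            it_seed <- seed + pl$iteration
            Xtr <- data$X[pl$train_idx, , drop = FALSE]
            ytr <- data$y[pl$train_idx]
            tune <- select_hyperparameters(
              Xtr, ytr, algo, k = k, seed = it_seed,
              groups = data$genotype[pl$train_idx], ...)
            model <- fit_model(Xtr, ytr, algo, tune$hyperparams)
            pred <- predict(model, data$X[pl$test_idx, , drop = FALSE])
            met <- compute_metrics(data$y[pl$test_idx], pred)
            met$scheme <- scheme
            met$focal_trial <- tr
            met$pretreatment <- pre
            met$algorithm <- algo
            met$iteration <- pl$iteration
            out[[length(out) + 1L]] <- met
          }
        }
      }
    }
  }
  do.call(rbind, out)
}
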