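# Configuration and end-to-end orchestration: average -> QC -> pretreat ->
# split -> tune -> fit -> metrics (+ importance, heritability), with all
# stage artifacts written to disk and a manifest for bit-identical replay.

#' Build and validate a pipeline configuration
#'
#' Defaults equal the analysis protocol's stated values: 70% of genotypes
#' in training, 50 split iterations, Mahalanobis threshold 3, 5 tuning
#' folds. Input is either a simulation config (`simulate = list(...)`
#' arguments for [sim_config()]) or paths to spectra/reference CSVs.
#'
#' @param spectra_csv,reference_csv input paths (ignored when `simulate`
#'   is given).
#' @param simulate named list of [sim_config()] arguments, or a
#'   `sim_config`.
#' @param pretreatments subset of [pretreatment_ids()].
#' @param algorithms subset of `c("PLSR", "SVM_RADIAL", "RF")`.
#' @param schemes cross-trial schemes to run (`character(0)` for none).
#' @param niter split iterations.
#' @param train_fraction training genotype fraction.
#' @param mahalanobis_threshold outlier threshold.
#' @param trim optional `c(min_nm, max_nm)`.
#' @param k tuning folds.
#' @param max_rank PLSR rank cap.
#' @param run_heritability fit per-trial starch heritability.
#' @param heritability_scan run the per-wavelength H2 scan.
#' @param seed top-level seed; per-stage seeds are derived from it.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(spectra_csv = NULL, reference_csv = NULL,
                            simulate = NULL,
                            pretreatments = "RAW",
                            algorithms = "PLSR",
                            schemes = character(0),
                            niter = 50L, train_fraction = 0.7,
                            mahalanobis_threshold = 3,
                            trim = NULL, k = 5L, max_rank = 10L,
                            run_heritability = TRUE,
                            heritability_scan = FALSE,
                            seed = 1L) {
  if (is.null(simulate) &&
      (is.null(spectra_csv) || is.null(reference_csv))) {
    stop("provide either simulate= or both spectra_csv= and ",
         "reference_csv=", call. = FALSE)
  }
  if (!length(pretreatments)) stop("empty pretreatment list", call. = FALSE)
  bad <- setdiff(pretreatments, pretreatment_ids())
  if (length(bad)) stop("unknown pretreatment(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(algorithms, c("PLSR", "SVM_RADIAL", "RF"))
  if (length(bad)) stop("unknown algorithm(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(schemes, c("CV2", "CV1", "CV0", "CV00"))
  if (length(bad)) stop("unknown scheme(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(simulate) && !inherits(simulate, "sim_config")) {
    simulate <- do.call(sim_config, simulate)
  }
  structure(list(
    spectra_csv = spectra_csv, reference_csv = reference_csv,
    simulate = simulate,
    pretreatments = pretreatments, algorithms = algorithms,
    schemes = schemes, niter = as.integer(niter),
    train_fraction = train_fraction,
    mahalanobis_threshold = mahalanobis_threshold,
    trim = trim, k = as.integer(k), max_rank = as.integer(max_rank),
    run_heritability = isTRUE(run_heritability),
    heritability_scan = isTRUE(heritability_scan),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file of [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(args$simulate)) args$simulate <- as.list(args$simulate)
  do.call(pipeline_config, args)
}

#' Run the full calibration pipeline
#'
#' Stages, in order: load or simulate inputs; average scans; PCA +
#' Mahalanobis QC; optional wavelength trimming; per pretreatment x
#' algorithm x trial, repeated genotype-grouped evaluation; optional
#' cross-trial CV schemes; VIP importance from a full-data PLSR fit;
#' per-trial starch heritability and optionally the per-wavelength scan.
#' All artifacts are written under `out_dir` together with a JSON manifest
#' (config, seed, package version) sufficient to replay the run.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return (invisibly) a list of in-memory results.
#' @export
run_pipeline <- function(config, out_dir = tempfile("starchnir_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "input"
  result <- list()
  tryCatch({
    if (!is.null(config$simulate)) {
      reference <- simulate_reference(config$simulate)
      spectra <- simulate_spectra(reference, config$simulate)
    } else {
      spectra <- read_spectra_csv(config$spectra_csv)
      reference <- read_reference_csv(config$reference_csv)
    }
    write_reference_csv(reference, file.path(out_dir, "reference.csv"))
    result$reference_summary <- summarize_reference(reference)
    utils::write.csv(result$reference_summary,
                     file.path(out_dir, "reference_summary.csv"),
                     row.names = FALSE)

    stage <- "average"
    samples <- average_scans(spectra)

    stage <- "qc"
    qc <- mahalanobis_filter(samples, config$mahalanobis_threshold)
    result$qc <- list(removed_ids = qc$removed_ids,
                      n_components = qc$n_components,
                      distances = qc$distances)
    jsonlite::write_json(
      list(removed_ids = qc$removed_ids, n_components = qc$n_components,
           threshold = config$mahalanobis_threshold),
      file.path(out_dir, "qc_report.json"), auto_unbox = TRUE)
    samples <- qc$kept

    if (!is.null(config$trim)) {
      stage <- "trim"
      samples <- trim_wavelengths(samples, config$trim[1], config$trim[2])
    }

    stage <- "evaluate"
    eval_rows <- list()
    for (pre in config$pretreatments) {
      treated <- apply_pretreatment(samples, pre)
      data <- assemble_dataset(treated, reference, average = FALSE)
      for (algo in config$algorithms) {
        for (tr in sort(unique(data$trial))) {
          rows <- data$trial == tr
          if (length(unique(data$genotype[rows])) < 4L) next
          ev <- within_trial_evaluate(
            data$X[rows, , drop = FALSE], data$y[rows],
            data$genotype[rows], algorithm = algo,
            niter = config$niter, train_fraction = config$train_fraction,
            k = config$k, seed = config$seed, max_rank = config$max_rank)
          tab <- ev$iterations
          tab$trial <- tr; tab$pretreatment <- pre; tab$algorithm <- algo
          eval_rows[[length(eval_rows) + 1L]] <- tab
        }
      }
    }
    result$evaluation <- do.call(rbind, eval_rows)
    utils::write.csv(result$evaluation,
                     file.path(out_dir, "evaluation.csv"),
                     row.names = FALSE)

    if (length(config$schemes) && length(unique(reference$trial_id)) > 1L) {
      stage <- "cv_schemes"
      result$cv_schemes <- run_cv_schemes(
        spectra, reference,
        pretreatments = config$pretreatments[1],
        algorithms = config$algorithms[1],
        schemes = config$schemes, niter = config$niter,
        k = config$k, seed = config$seed, max_rank = config$max_rank)
      utils::write.csv(result$cv_schemes,
                       file.path(out_dir, "cv_schemes.csv"),
                       row.names = FALSE)
    }

    stage <- "importance"
    if ("PLSR" %in% config$algorithms) {
      data <- assemble_dataset(
        apply_pretreatment(samples, config$pretreatments[1]),
        reference, average = FALSE)
      tune <- select_hyperparameters(data$X, data$y, "PLSR",
                                     k = config$k, seed = config$seed,
                                     groups = data$genotype,
                                     max_rank = config$max_rank)
      full <- fit_model(data$X, data$y, "PLSR", tune$hyperparams)
      result$importance <- vip_scores(full)
      utils::write.csv(result$importance,
                       file.path(out_dir, "importance_vip.csv"),
                       row.names = FALSE)
    }

    if (config$run_heritability) {
      stage <- "heritability"
      h_rows <- lapply(sort(unique(reference$trial_id)), function(tr) {
        rows <- reference$trial_id == tr
        vc <- if (reference$design[rows][1] == "RCBD") {
          fit_rcbd(reference$starch[rows], reference$genotype_id[rows],
                   reference$block[rows])
        } else {
          fit_alpha_lattice(reference$starch[rows],
                            reference$genotype_id[rows],
                            reference$rep[rows], reference$block[rows])
        }
        data.frame(trial_id = tr, sigma2_g = vc$sigma2_g,
                   sigma2_e = vc$sigma2_e, nRep = vc$nRep,
                   H2 = broad_sense_h2(vc), converged = vc$converged)
      })
      result$heritability <- do.call(rbind, h_rows)
      utils::write.csv(result$heritability,
                       file.path(out_dir, "heritability.csv"),
                       row.names = FALSE)
      if (config$heritability_scan) {
        stage <- "heritability_scan"
        data <- assemble_dataset(samples, reference, average = FALSE)
        scans <- lapply(sort(unique(data$trial)), function(tr) {
          rows <- data$trial == tr
          des <- data$design[rows][1]
          sc <- spectral_heritability_scan(
            data$X[rows, , drop = FALSE], data$genotype[rows],
            data$rep[rows], data$block[rows], design = des,
            wavelengths = data$wavelengths)
          sc$trial_id <- tr
          sc
        })
        result$heritability_scan <- do.call(rbind, scans)
        utils::write.csv(result$heritability_scan,
                         file.path(out_dir, "heritability_scan.csv"),
                         row.names = FALSE)
      }
    }

    stage <- "manifest"
    manifest <- list(
      package = "starchnir",
      version = as.character(utils::packageVersion("starchnir")),
      seed = config$seed,
      config = config_to_list(config)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

config_to_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$simulate)) out$simulate <- unclass(out$simulate)
  out
}
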