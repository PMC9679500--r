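#' Read a spectra CSV
#'
#' Reads the comma-separated export dialect used throughout the package:
#' UTF-8, header row, metadata columns first, then one column per integer
#' wavelength named by its bare nanometre value (e.g. `740`, `741`, ...).
#' R's `read.csv` prefixes numeric column names with `X`; both forms are
#' accepted.
#'
#' Rows with any missing reflectance value are rejected and reported via a
#' warning (the rejected row numbers are attached as attribute
#' `"rejected"`). A non-uniform wavelength grid or duplicate
#' (sample_id, scan_index) keys are errors.
#'
#' @param path path to a CSV file.
#' @return a [spectra_set()].
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = TRUE, stringsAsFactors = FALSE)
  nm <- sub("^X", "", names(df))
  is_wl <- grepl("^[0-9]+$", nm)
  if (sum(is_wl) < 2L) stop("no wavelength columns found in ", path,
                            call. = FALSE)
  w <- as.integer(nm[is_wl])
  ord <- order(w)
  check_grid(w[ord])
  meta <- df[, !is_wl, drop = FALSE]
  refl <- as.matrix(df[, which(is_wl)[ord], drop = FALSE])
  if (!is.numeric(refl)) stop("unparseable reflectance cells in ", path,
                              call. = FALSE)
  bad <- which(rowSums(is.na(refl)) > 0L)
  if (length(bad)) {
    warning("rejected ", length(bad), " row(s) with missing reflectance: ",
            paste(utils::head(bad, 10L), collapse = ", "),
            if (length(bad) > 10L) ", ..." else "", call. = FALSE)
    refl <- refl[-bad, , drop = FALSE]
    meta <- meta[-bad, , drop = FALSE]
  }
  if (all(c("sample_id", "scan_index") %in% names(meta))) {
    key <- paste(meta$sample_id, meta$scan_index, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate (sample_id, scan_index) keys in ", path, call. = FALSE)
    }
  }
  out <- spectra_set(w[ord], refl, meta)
  attr(out, "rejected") <- bad
  out
}

#' Write a spectra set as CSV
#'
#' Inverse of [read_spectra_csv()]: metadata columns followed by one column
#' per wavelength, named by bare integer nanometres.
#'
#' @param spectra a [spectra_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  df <- cbind(spectra$meta, as.data.frame(spectra$reflectance,
                                          check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average repeated scans per sample
#'
#' Collapses the repeated scans of each sample to its arithmetic mean
#' spectrum, one row per `sample_id`. All metadata other than `scan_index`
#' must be constant within a sample; `scan_index` is dropped.
#'
#' @param spectra a [spectra_set()].
#' @return a `spectra_set` with one row per sample.
#' @export
average_scans <- function(spectra) {
  meta <- spectra$meta
  ids <- unique(meta$sample_id)
  keep_cols <- setdiff(names(meta), "scan_index")
  rows <- match(ids, meta$sample_id)
  out_meta <- meta[rows, keep_cols, drop = FALSE]
  for (col in keep_cols) {
    n_distinct <- tapply(meta[[col]], meta$sample_id, function(v)
      length(unique(v)))
    if (any(n_distinct > 1L)) {
      stop("metadata column '", col, "' is not constant within sample(s): ",
           paste(utils::head(names(n_distinct)[n_distinct > 1L], 5L),
                 collapse = ", "), call. = FALSE)
    }
  }
  g <- match(meta$sample_id, ids)
  refl <- rowsum(spectra$reflectance, g) / as.vector(table(g))
  spectra_set(spectra$wavelengths, refl, out_meta)
}

#' Trim a spectra set to a wavelength range
#'
#' @param spectra a [spectra_set()].
#' @param min_nm,max_nm inclusive range in nanometres.
#' @return a `spectra_set` restricted to `[min_nm, max_nm]`.
#' @export
trim_wavelengths <- function(spectra, min_nm, max_nm) {
  keep <- spectra$wavelengths >= min_nm & spectra$wavelengths <= max_nm
  if (!any(keep)) {
    stop("range [", min_nm, ", ", max_nm, "] nm does not intersect grid [",
         min(spectra$wavelengths), ", ", max(spectra$wavelengths), "] nm",
         call. = FALSE)
  }
  spectra_set(spectra$wavelengths[keep],
              spectra$reflectance[, keep, drop = FALSE],
              spectra$meta)
}

#' Root starch content from extraction masses
#'
#' RSC (%) = 100 * DSM / FM, where DSM is the dry mass of starch extracted
#' from a fresh-root sample of mass FM.
#'
#' @param dry_starch_mass dry starch mass in grams, `>= 0`.
#' @param fresh_mass fresh root mass in grams, `> 0`.
#' @return starch content as a percentage of fresh mass.
#' @export
compute_rsc <- function(dry_starch_mass, fresh_mass) {
  if (any(fresh_mass <= 0)) stop("fresh_mass must be positive",
                                 call. = FALSE)
  if (any(dry_starch_mass < 0)) stop("dry_starch_mass must be >= 0",
                                     call. = FALSE)
  100 * dry_starch_mass / fresh_mass
}

#' Validate a reference phenotype table
#'
#' A reference table holds one row per field plot with columns `trial_id`,
#' `genotype_id`, `rep`, `block`, `design` (\"RCBD\" or \"ALPHA_LATTICE\"),
#' `starch` (% fresh mass) and a unique `sample_id` linking plots to
#' spectra.
#'
#' @param reference a data.frame.
#' @return the validated data.frame, invisibly classed `reference_table`.
#' @export
validate_reference <- function(reference) {
  need <- c("trial_id", "genotype_id", "rep", "block", "design", "starch",
            "sample_id")
  miss <- setdiff(need, names(reference))
  if (length(miss)) stop("reference table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(reference$design %in% c("RCBD", "ALPHA_LATTICE"))) {
    stop("design must be RCBD or ALPHA_LATTICE", call. = FALSE)
  }
  per_trial <- tapply(reference$design, reference$trial_id, function(v)
    length(unique(v)))
  if (any(per_trial > 1L)) stop("design must be constant within a trial",
                                call. = FALSE)
  if (any(!is.finite(reference$starch)) ||
      any(reference$starch <= 0 | reference$starch >= 100)) {
    stop("starch values must lie in (0, 100) %", call. = FALSE)
  }
  if (anyDuplicated(reference$sample_id)) {
    stop("sample_id must be unique per plot", call. = FALSE)
  }
  class(reference) <- unique(c("reference_table", class(reference)))
  invisible(reference)
}

#' Per-trial summary statistics of the reference trait
#'
#' Computes, per trial, the plot and genotype counts and the minimum,
#' maximum, mean, sample standard deviation (n-1) and coefficient of
#' variation (SD/mean) of the starch phenotype. Trials with a single plot
#' are flagged and their dispersion statistics set to `NA`.
#'
#' @param reference a reference table (see [validate_reference()]).
#' @return data.frame, one row per trial.
#' @export
summarize_reference <- function(reference) {
  validate_reference(reference)
  trials <- sort(unique(reference$trial_id))
  rows <- lapply(trials, function(tr) {
    v <- reference$starch[reference$trial_id == tr]
    g <- reference$genotype_id[reference$trial_id == tr]
    ok <- length(v) >= 2L
    data.frame(
      trial_id = tr,
      n_plots = length(v),
      n_genotypes = length(unique(g)),
      min = min(v), max = max(v), mean = mean(v),
      sd = if (ok) stats::sd(v) else NA_real_,
      cv = if (ok) stats::sd(v) / mean(v) else NA_real_,
      singleton = !ok,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a reference table as CSV
#' @param reference a reference table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_csv <- function(reference, path) {
  utils::write.csv(reference, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference table from CSV
#' @param path CSV path.
#' @return a validated reference table.
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_reference(df)
  df
}
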