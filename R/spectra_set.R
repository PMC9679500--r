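#' Construct a spectra set
#'
#' A `spectra_set` bundles a reflectance matrix with its integer-nanometre
#' wavelength grid and per-row sample metadata. Rows are individual scans
#' (or, after [average_scans()], samples); columns are wavelengths on a
#' strictly increasing, uniformly spaced grid such as the 740--1070 nm,
#' 1 nm grid of a pocket short-wave NIR sensor.
#'
#' @param wavelengths integer vector, strictly increasing, uniform step.
#' @param reflectance numeric matrix, one row per scan, one column per
#'   wavelength.
#' @param meta data.frame with one row per scan. Must contain `sample_id`;
#'   `genotype_id`, `trial_id`, `rep`, `block` and `scan_index` are kept
#'   when present.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavelengths, reflectance, meta) {
  wavelengths <- as.integer(round(wavelengths))
  reflectance <- as.matrix(reflectance)
  if (!is.data.frame(meta)) meta <- as.data.frame(meta)
  if (ncol(reflectance) != length(wavelengths)) {
    stop("reflectance has ", ncol(reflectance), " columns but grid has ",
         length(wavelengths), " wavelengths", call. = FALSE)
  }
  if (nrow(reflectance) != nrow(meta)) {
    stop("reflectance and meta disagree on row count", call. = FALSE)
  }
  if (!"sample_id" %in% names(meta)) {
    stop("meta must contain a 'sample_id' column", call. = FALSE)
  }
  check_grid(wavelengths)
  if (anyNA(reflectance)) {
    stop("reflectance contains missing values; use read_spectra_csv() ",
         "for row-level rejection", call. = FALSE)
  }
  colnames(reflectance) <- as.character(wavelengths)
  rownames(reflectance) <- NULL
  rownames(meta) <- NULL
  structure(
    list(wavelengths = wavelengths, reflectance = reflectance, meta = meta),
    class = "spectra_set"
  )
}

check_grid <- function(w) {
  if (length(w) < 2L) stop("wavelength grid needs at least 2 points",
                           call. = FALSE)
  d <- diff(w)
  if (any(d <= 0L)) stop("wavelength grid must be strictly increasing",
                         call. = FALSE)
  if (length(unique(d)) != 1L) {
    stop("wavelength grid is not uniform (gaps at ",
         paste(utils::head(w[which(d != d[1L]) + 1L], 3L), collapse = ", "),
         " nm)", call. = FALSE)
  }
  invisible(w)
}

grid_step <- function(spectra) {
  diff(spectra$wavelengths[1:2])
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$reflectance), " scans x ",
      length(x$wavelengths), " wavelengths [",
      min(x$wavelengths), "-", max(x$wavelengths), " nm, step ",
      grid_step(x), " nm]\n", sep = "")
  cat("  samples: ", length(unique(x$meta$sample_id)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$reflectance)

#' Subset a spectra set by row
#'
#' @param spectra a [spectra_set()].
#' @param idx integer or logical row index.
#' @return a `spectra_set` with the selected rows.
#' @export
subset_rows <- function(spectra, idx) {
  spectra_set(spectra$wavelengths,
              spectra$reflectance[idx, , drop = FALSE],
              spectra$meta[idx, , drop = FALSE])
}
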