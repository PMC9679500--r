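# Exploratory PCA and Mahalanobis-distance outlier screening of spectra.

#' Principal component analysis of spectra
#'
#' Column-mean-centred PCA via SVD. Scores are orthogonal; the proportion
#' of variance explained per component is reported.
#'
#' @param spectra a [spectra_set()] or numeric matrix.
#' @param n_components number of components to retain (default: all,
#'   `min(n - 1, p)`).
#' @return a `spectra_pca` list with `scores`, `loadings`, `explained`
#'   (variance proportions) and `center`.
#' @export
pca_spectra <- function(spectra, n_components = NULL) {
  X <- if (inherits(spectra, "spectra_set")) spectra$reflectance else
    as.matrix(spectra)
  n <- nrow(X)
  if (n < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  max_k <- min(n - 1L, ncol(X))
  if (is.null(n_components)) n_components <- max_k
  if (n_components > max_k) {
    stop("n_components must be <= min(n - 1, p) = ", max_k, call. = FALSE)
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = n_components, nv = n_components)
  explained <- sv$d^2 / sum(sv$d^2)
  structure(list(
    scores = sv$u %*% diag(sv$d[seq_len(n_components)],
                           n_components, n_components),
    loadings = sv$v,
    explained = explained[seq_len(n_components)],
    center = ctr
  ), class = "spectra_pca")
}

#' Mahalanobis-distance outlier filter
#'
#' With many more wavelengths than samples the raw spectral covariance is
#' singular, so distances are computed in the space of PCA scores retaining
#' `cum_var` (default 95%) of the variance, capped at `n - 2` components.
#' Each retained score is standardised by its SD and the distance is
#' reported as `sqrt(mean(z^2))` over the k retained components, i.e.
#' divided by `sqrt(k)` so the default threshold of 3 behaves like a 3-SD
#' rule regardless of k. Rows with distance > `threshold` are removed.
#'
#' @param spectra a [spectra_set()].
#' @param threshold removal threshold in SD-like units (default 3).
#' @param cum_var cumulative variance retained for the score space.
#' @return list with `kept` (a `spectra_set`), `removed_ids`
#'   (sample ids of removed rows), `distances` (per input row) and
#'   `n_components`.
#' @export
mahalanobis_filter <- function(spectra, threshold = 3, cum_var = 0.95) {
  n <- nrow(spectra$reflectance)
  if (n < 3L) {
    warning("fewer than 3 samples; QC skipped", call. = FALSE)
    return(list(kept = spectra, removed_ids = character(0),
                distances = rep(NA_real_, n), n_components = 0L))
  }
  pca <- pca_spectra(spectra)
  k <- which(cumsum(pca$explained) >= cum_var)[1L]
  if (is.na(k)) k <- length(pca$explained)
  k <- max(1L, min(k, n - 2L))
  sc <- pca$scores[, seq_len(k), drop = FALSE]
  z <- sweep(sc, 2, apply(sc, 2, stats::sd), `/`)
  d <- sqrt(rowSums(z^2) / k)
  drop_rows <- which(d > threshold)
  kept <- if (length(drop_rows)) subset_rows(spectra, -drop_rows) else
    spectra
  list(kept = kept,
       removed_ids = unique(spectra$meta$sample_id[drop_rows]),
       distances = d,
       n_components = k)
}
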