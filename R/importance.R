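# Wavelength-importance profiling: VIP for PLSR, permutation importance
# for any fitted model (the RF default), and top-k reporting.

#' Variable importance in projection (VIP) for a PLSR model
#'
#' `VIP_j = sqrt(p * sum_a SSY_a * (w_ja / ||w_a||)^2 / sum_a SSY_a)` over
#' the model's selected rank, where `SSY_a` is the response variance
#' explained by component a. The mean of the squared scores over
#' wavelengths is exactly 1.
#'
#' @param model a `calibration_model` with `algorithm = "PLSR"`.
#' @param wavelengths optional numeric wavelengths for the profile
#'   (defaults to the model's stored grid).
#' @return an `importance_profile` data.frame (`wavelength`, `score`) with
#'   attribute `method = "VIP"`.
#' @export
vip_scores <- function(model, wavelengths = NULL) {
  if (!inherits(model, "calibration_model") || model$algorithm != "PLSR") {
    stop("VIP requires a fitted PLSR model", call. = FALSE)
  }
  A <- model$rank
  W <- model$W[, seq_len(A), drop = FALSE]
  ssy <- model$ssy[seq_len(A)]
  wnorm2 <- colSums(W^2)          # = 1 for NIPALS weights, kept for safety
  p <- nrow(W)
  num <- (W^2 %*% (ssy / wnorm2))
  vip <- sqrt(p * num / sum(ssy))
  wl <- wavelengths %||% suppressWarnings(as.numeric(model$wavelengths))
  if (is.null(wl) || length(wl) != p || anyNA(wl)) wl <- seq_len(p)
  structure(data.frame(wavelength = wl, score = as.numeric(vip)),
            method = "VIP", class = c("importance_profile", "data.frame"))
}

#' Permutation wavelength importance
#'
#' For each wavelength, the mean increase in test RMSE over `n_perm`
#' random shuffles of that column. Applicable to any fitted calibration
#' model; the conventional choice for random forests.
#'
#' @param model a fitted `calibration_model`.
#' @param X,y evaluation data on the training grid.
#' @param n_perm permutations per wavelength (default 5).
#' @param seed integer seed.
#' @return an `importance_profile` data.frame with attribute
#'   `method = "permutation"`.
#' @export
permutation_importance <- function(model, X, y, n_perm = 5L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  X <- as_X(X)
  base_rmse <- sqrt(mean((predict(model, X) - y)^2))
  p <- ncol(X)
  scores <- with_seed(seed, {
    vapply(seq_len(p), function(j) {
      deltas <- vapply(seq_len(n_perm), function(r) {
        Xp <- X
        Xp[, j] <- X[sample.int(nrow(X)), j]
        sqrt(mean((predict(model, Xp) - y)^2)) - base_rmse
      }, numeric(1))
      mean(deltas)
    }, numeric(1))
  })
  wl <- suppressWarnings(as.numeric(colnames(X)))
  if (is.null(colnames(X)) || anyNA(wl)) wl <- seq_len(p)
  structure(data.frame(wavelength = wl, score = scores),
            method = "permutation",
            class = c("importance_profile", "data.frame"))
}

#' Top-k wavelengths of an importance profile
#'
#' Sorted by descending score; ties broken by ascending wavelength.
#'
#' @param profile an `importance_profile`.
#' @param k number of wavelengths to report.
#' @return numeric vector of wavelengths, ordered.
#' @export
top_wavelengths <- function(profile, k) {
  if (k > nrow(profile)) stop("k exceeds the number of wavelengths",
                              call. = FALSE)
  ord <- order(-profile$score, profile$wavelength)
  profile$wavelength[ord][seq_len(k)]
}
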