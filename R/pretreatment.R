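# Spectral pretreatment: SNV scatter correction, Savitzky-Golay
# smoothing/derivatives and gap-segment derivatives, composable into the 13
# named variants (raw + 12 combinations) used for calibration screening.

#' The 13 pretreatment identifiers
#' @return character vector of valid pretreatment ids.
#' @export
pretreatment_ids <- function() {
  c("RAW", "SNV", "D1", "D2", "SNV1D", "SNV2D", "SG", "SNVSG", "SGD1",
    "SG.D1W5", "SG.D1W11", "SG.D2W5", "SG.D2W11")
}

#' Resolve a pretreatment id to its operator chain
#'
#' Conventions: standalone first/second derivatives (`D1`, `D2`) are simple
#' finite differences (gap-segment with segment = 1, gap = 1); plain `SG`
#' and `SNVSG` smooth with window 11; the gap-segment derivative `SGD1`
#' uses window 11 split as segment 3 / gap 5; Savitzky-Golay polynomial
#' order is 2 for derivative order <= 1 and 3 for second derivatives.
#' Scatter correction (SNV) is always applied before smoothing or
#' differentiation.
#'
#' @param id one of [pretreatment_ids()], or an existing spec list.
#' @param sg_polyorder optional override of the polynomial order.
#' @param sgd1_gap,sgd1_segment optional override of the `SGD1` split.
#' @return a `pretreatment_spec` list with a `steps` element.
#' @export
pretreatment_spec <- function(id, sg_polyorder = NULL, sgd1_gap = 5L,
                              sgd1_segment = 3L) {
  if (inherits(id, "pretreatment_spec")) return(id)
  id <- match.arg(id, pretreatment_ids())
  poly_for <- function(deriv) {
    if (!is.null(sg_polyorder)) sg_polyorder else if (deriv <= 1L) 2L else 3L
  }
  sg <- function(window, deriv) {
    list(op = "sg", window = as.integer(window), deriv = as.integer(deriv),
         polyorder = as.integer(poly_for(deriv)))
  }
  gapseg <- function(deriv, gap, segment) {
    list(op = "gapseg", deriv = as.integer(deriv), gap = as.integer(gap),
         segment = as.integer(segment))
  }
  snv <- list(op = "snv")
  steps <- switch(id,
    RAW      = list(),
    SNV      = list(snv),
    D1       = list(gapseg(1L, 1L, 1L)),
    D2       = list(gapseg(2L, 1L, 1L)),
    SNV1D    = list(snv, gapseg(1L, 1L, 1L)),
    SNV2D    = list(snv, gapseg(2L, 1L, 1L)),
    SG       = list(sg(11L, 0L)),
    SNVSG    = list(snv, sg(11L, 0L)),
    SGD1     = list(gapseg(1L, sgd1_gap, sgd1_segment)),
    SG.D1W5  = list(sg(5L, 1L)),
    SG.D1W11 = list(sg(11L, 1L)),
    SG.D2W5  = list(sg(5L, 2L)),
    SG.D2W11 = list(sg(11L, 2L))
  )
  structure(list(id = id, steps = steps), class = "pretreatment_spec")
}

#' Standard normal variate transform
#'
#' Centers and scales each spectrum (row) to mean 0 and sample SD 1,
#' removing per-spectrum additive offsets and multiplicative scatter.
#' Zero-variance spectra cannot be scaled: for a matrix they are dropped
#' with a warning (attribute `"excluded"` lists the rows); a single
#' zero-variance vector is an error.
#'
#' @param x numeric vector (one spectrum) or matrix (rows are spectra).
#' @return the transformed vector or matrix.
#' @export
snv <- function(x) {
  if (is.matrix(x)) {
    s <- apply(x, 1, stats::sd)
    bad <- which(s == 0 | !is.finite(s))
    if (length(bad)) {
      warning("excluded ", length(bad), " zero-variance spectrum(s)",
              call. = FALSE)
      x <- x[-bad, , drop = FALSE]
      s <- s[-bad]
    }
    out <- (x - rowMeans(x)) / s
    attr(out, "excluded") <- bad
    return(out)
  }
  s <- stats::sd(x)
  if (s == 0 || !is.finite(s)) stop("zero-variance spectrum", call. = FALSE)
  (x - mean(x)) / s
}

sg_coefficients <- function(window, polyorder, deriv, step) {
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (polyorder >= window) stop("polyorder must be < window", call. = FALSE)
  if (deriv > polyorder) stop("deriv_order must be <= polyorder",
                              call. = FALSE)
  h <- (window - 1L) / 2L
  A <- outer(seq(-h, h), 0:polyorder, `^`)
  C <- solve(crossprod(A), t(A))
  C[deriv + 1L, ] * factorial(deriv) / step^deriv
}

apply_conv <- function(X, coef) {
  w <- length(coef)
  p <- ncol(X)
  if (w > p) stop("window exceeds number of wavelengths", call. = FALSE)
  h <- (w - 1L) / 2L
  n_out <- p - 2L * h
  # banded p x n_out operator; p is small (<= a few hundred)
  T_ <- matrix(0, p, n_out)
  for (j in seq_len(n_out)) T_[j:(j + w - 1L), j] <- coef
  X %*% T_
}

#' Savitzky-Golay filtering and differentiation
#'
#' Replaces each interior point by the `deriv_order`-th derivative (scaled
#' by the grid step) of the local least-squares polynomial of degree
#' `polyorder` fitted over a centred window. Edge points with incomplete
#' windows are dropped, so the wavelength grid shrinks by
#' `(window - 1) / 2` on each side.
#'
#' @param spectra a [spectra_set()] or numeric matrix.
#' @param window odd window width (points).
#' @param polyorder polynomial degree (< window).
#' @param deriv_order derivative order (0, 1 or 2; <= polyorder).
#' @param step grid step in nm (taken from the grid for a `spectra_set`).
#' @return object of the same type, with a shrunken grid.
#' @export
savitzky_golay <- function(spectra, window, polyorder, deriv_order = 0L,
                           step = 1) {
  if (inherits(spectra, "spectra_set")) {
    coef <- sg_coefficients(window, polyorder, deriv_order,
                            grid_step(spectra))
    h <- (window - 1L) / 2L
    out <- apply_conv(spectra$reflectance, coef)
    w <- spectra$wavelengths[(h + 1L):(length(spectra$wavelengths) - h)]
    return(spectra_set(w, out, spectra$meta))
  }
  coef <- sg_coefficients(window, polyorder, deriv_order, step)
  apply_conv(as.matrix(spectra), coef)
}

gapseg_coefficients <- function(gap, segment, step) {
  if (gap < 1L || segment < 1L) stop("gap and segment must be >= 1",
                                     call. = FALSE)
  w <- 2L * segment + gap
  coef <- numeric(w)
  coef[seq_len(segment)] <- -1 / segment
  coef[(segment + gap + 1L):w] <- 1 / segment
  # centre-to-centre distance of the flank segments, in grid points
  coef / ((segment + gap) * step)
}

#' Gap-segment derivative
#'
#' Estimates the derivative at each point as the difference of the means of
#' two flanking segments separated by a gap, normalised by the
#' centre-to-centre flank distance. Second order applies the rule twice.
#' The window (`2 * segment + gap` points) must be odd so the output stays
#' centred; edges are dropped.
#'
#' @param spectra a [spectra_set()] or numeric matrix.
#' @param deriv_order 1 or 2.
#' @param gap points between the flank segments.
#' @param segment points per flank segment.
#' @param step grid step in nm.
#' @return object of the same type, with a shrunken grid.
#' @export
gap_segment_derivative <- function(spectra, deriv_order = 1L, gap = 1L,
                                   segment = 1L, step = 1) {
  if (!deriv_order %in% 1:2) stop("deriv_order must be 1 or 2",
                                  call. = FALSE)
  if ((2L * segment + gap) %% 2L == 0L) {
    stop("gap-segment window (2*segment + gap) must be odd", call. = FALSE)
  }
  one_pass <- function(X, st) apply_conv(X, gapseg_coefficients(gap, segment,
                                                                st))
  if (inherits(spectra, "spectra_set")) {
    st <- grid_step(spectra)
    h <- (2L * segment + gap - 1L) / 2L
    out <- one_pass(spectra$reflectance, st)
    w <- spectra$wavelengths[(h + 1L):(length(spectra$wavelengths) - h)]
    if (deriv_order == 2L) {
      out <- one_pass(out, st)
      w <- w[(h + 1L):(length(w) - h)]
    }
    return(spectra_set(w, out, spectra$meta))
  }
  out <- one_pass(as.matrix(spectra), step)
  if (deriv_order == 2L) out <- one_pass(out, step)
  out
}

#' Apply a named pretreatment to a spectra set
#'
#' Composes the operators of a [pretreatment_spec()] in order (scatter
#' correction first, then smoothing/differentiation). The output grid may
#' shrink at the edges; it is carried on the returned object.
#'
#' @param spectra a [spectra_set()].
#' @param spec a pretreatment id string or [pretreatment_spec()].
#' @return a transformed `spectra_set`.
#' @export
apply_pretreatment <- function(spectra, spec) {
  spec <- pretreatment_spec(spec)
  out <- spectra
  for (stp in spec$steps) {
    out <- switch(stp$op,
      snv = {
        tr <- snv(out$reflectance)
        excl <- attr(tr, "excluded")
        meta <- if (length(excl)) out$meta[-excl, , drop = FALSE] else
          out$meta
        spectra_set(out$wavelengths, tr, meta)
      },
      sg = savitzky_golay(out, stp$window, stp$polyorder, stp$deriv),
      gapseg = gap_segment_derivative(out, stp$deriv, stp$gap, stp$segment)
    )
  }
  out
}
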