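## Orthonormal filter banks. Daubechies lowpass coefficients are the
## published constants; the highpass is the quadrature mirror
## g[k] = (-1)^k h[L-1-k], and the synthesis bank equals the analysis bank
## (orthogonal transform).
wavelet_filters <- function(name) {
  lo <- switch(name,
    haar = ,
    db1 = rep(1 / sqrt(2), 2),
    db2 = c(0.48296291314469025, 0.8365163037378079,
            0.2241438680420134, -0.12940952255092145),
    db4 = c(0.2303778133088965, 0.7148465705529157,
            0.6308807679298589, -0.027983769416859854,
            -0.18703481171909309, 0.030841381835560764,
            0.0328830116668852, -0.010597401785069032),
    stop("unknown wavelet basis '", name, "' (available: haar, db1, db2, db4)")
  )
  L <- length(lo)
  hi <- (-1)^(seq_len(L) - 1) * rev(lo)
  list(lo = lo, hi = hi, length = L, name = name)
}

## Periodized analysis step along the rows (first index) of a matrix:
## cA[k, ] = sum_j lo[j] * M[(2k + j) mod n, ]. n must be even.
dwt_step_rows <- function(M, f) {
  n <- nrow(M)
  half <- n %/% 2L
  cA <- matrix(0, half, ncol(M))
  cD <- matrix(0, half, ncol(M))
  base <- 2L * (seq_len(half) - 1L)
  for (j in seq_len(f$length)) {
    rows <- (base + (j - 1L)) %% n + 1L
    cA <- cA + f$lo[j] * M[rows, , drop = FALSE]
    cD <- cD + f$hi[j] * M[rows, , drop = FALSE]
  }
  list(lo = cA, hi = cD)
}

## Periodized synthesis step (exact inverse of dwt_step_rows by
## orthogonality of the periodized filter matrix).
idwt_step_rows <- function(cA, cD, f) {
  half <- nrow(cA)
  n <- 2L * half
  X <- matrix(0, n, ncol(cA))
  base <- 2L * (seq_len(half) - 1L)
  for (j in seq_len(f$length)) {
    rows <- (base + (j - 1L)) %% n + 1L
    X[rows, ] <- X[rows, ] + f$lo[j] * cA + f$hi[j] * cD
  }
  X
}

dwt2_single <- function(M, f) {
  cols <- dwt_step_rows(M, f)                 # filter along rows (height)
  ll <- dwt_step_rows(t(cols$lo), f)          # then along columns (width)
  hh <- dwt_step_rows(t(cols$hi), f)
  list(a = t(ll$lo),                          # low/low
       h = t(hh$lo),                          # high in height, low in width
       v = t(ll$hi),                          # low in height, high in width
       d = t(hh$hi))                          # high/high
}

idwt2_single <- function(a, h, v, d, f) {
  lo <- t(idwt_step_rows(t(a), t(v), f))
  hi <- t(idwt_step_rows(t(h), t(d), f))
  idwt_step_rows(lo, hi, f)
}

max_wavelet_levels <- function(dims, filter_length) {
  lev <- 0L
  n <- min(dims)
  while (n %% 2L == 0L && n >= filter_length) {
    lev <- lev + 1L
    n <- n %/% 2L
  }
  lev
}

#' Multilevel 2-D wavelet decomposition
#'
#' Decomposes a 2-D slice into a coarsest approximation band plus, per level,
#' horizontal/vertical/diagonal detail bands, using a periodized orthonormal
#' transform (each subband is exactly half the parent per axis, and the
#' inverse transform reconstructs the input to machine precision).
#'
#' Details are ordered finest first: `details[[1]]` holds the level-1 bands.
#'
#' @param vol 2-D [image_volume] or matrix.
#' @param basis wavelet family: `"haar"` (= `"db1"`), `"db2"` or `"db4"`
#'   (default; 4 vanishing moments, 8 taps).
#' @param levels decomposition depth (>= 1); every level requires the current
#'   band to have even sides no shorter than twice the filter length.
#' @return Object of class `wavelet_coeffs` with fields `approx`, `details`,
#'   `basis_name`, `levels`.
#' @export
wavelet_decompose <- function(vol, basis = "db4", levels = 2L) {
  M <- as_image_data(vol)
  if (length(dim(M)) != 2L) stop("wavelet stage operates on a single 2-D slice")
  levels <- as.integer(levels)
  if (levels < 1L) stop("`levels` must be >= 1")
  f <- wavelet_filters(basis)
  maxlev <- max_wavelet_levels(dim(M), f$length)
  if (levels > maxlev)
    stop("image ", paste(dim(M), collapse = "x"), " supports at most ",
         maxlev, " level(s) with basis '", basis, "'")
  details <- vector("list", levels)
  cur <- M
  for (l in seq_len(levels)) {
    b <- dwt2_single(cur, f)
    details[[l]] <- list(h = b$h, v = b$v, d = b$d)
    cur <- b$a
  }
  structure(list(approx = cur, details = details, basis_name = basis,
                 levels = levels, input_dim = dim(M)),
            class = "wavelet_coeffs")
}

#' @export
print.wavelet_coeffs <- function(x, ...) {
  cat(sprintf("<wavelet_coeffs> basis %s, %d level(s), input %s\n",
              x$basis_name, x$levels, paste(x$input_dim, collapse = "x")))
  cat("  approx:", paste(dim(x$approx), collapse = "x"), "\n")
  for (l in seq_len(x$levels))
    cat(sprintf("  level %d details: %s\n", l,
                paste(dim(x$details[[l]]$h), collapse = "x")))
  invisible(x)
}

#' Inverse multilevel 2-D wavelet transform
#'
#' Exact inverse of [wavelet_decompose]; an untouched decomposition
#' reproduces the input to within 1e-8 (in practice machine precision).
#'
#' @param coeffs a `wavelet_coeffs` object.
#' @return A numeric matrix of the original image shape.
#' @export
wavelet_reconstruct <- function(coeffs) {
  stopifnot(inherits(coeffs, "wavelet_coeffs"))
  f <- wavelet_filters(coeffs$basis_name)
  cur <- coeffs$approx
  for (l in rev(seq_len(coeffs$levels))) {
    dl <- coeffs$details[[l]]
    if (!identical(dim(dl$h), dim(cur)) || !identical(dim(dl$v), dim(cur)) ||
        !identical(dim(dl$d), dim(cur)))
      stop("subband shapes at level ", l, " are inconsistent with the approximation band")
    cur <- idwt2_single(cur, dl$h, dl$v, dl$d, f)
  }
  if (!identical(dim(cur), coeffs$input_dim))
    stop("reconstructed shape differs from the recorded input shape")
  cur
}

#' Threshold specification
#'
#' @param tau non-negative threshold in coefficient units.
#' @param softness blending exponent in `[0, 1]`: 0 (default) is pure soft
#'   thresholding; 1 is hard thresholding; values between blend the two
#'   (firm-threshold family).
#' @return Object of class `threshold_spec`.
#' @export
threshold_spec <- function(tau, softness = 0) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0) stop("`tau` must be a scalar >= 0")
  if (softness < 0 || softness > 1) stop("`softness` must be in [0, 1]")
  structure(list(tau = tau, softness = softness), class = "threshold_spec")
}

#' Data-driven threshold from the filtered image
#'
#' The pipeline's threshold rule: tau = tau_factor times the mean intensity
#' of the similarity-filtered image (default factor 0.005). The rule's
#' per-pixel product is reduced to a scalar via the image mean so that one
#' threshold applies to every detail subband.
#'
#' @param filtered the similarity-filtered [image_volume] or matrix.
#' @param tau_factor positive multiplier (default 0.005).
#' @param softness passed through to [threshold_spec] (default 0).
#' @return A [threshold_spec].
#' @export
compute_tau <- function(filtered, tau_factor = 0.005, softness = 0) {
  x <- as_image_data(filtered)
  if (length(x) == 0L) stop("empty image")
  if (tau_factor <= 0) stop("`tau_factor` must be > 0")
  threshold_spec(tau_factor * mean(x), softness = softness)
}

soft_threshold_values <- function(w, tau, softness = 0) {
  soft <- sign(w) * pmax(abs(w) - tau, 0)
  if (softness == 0) return(soft)
  hard <- w * (abs(w) >= tau)
  (1 - softness) * soft + softness * hard
}

#' Soft-threshold wavelet detail coefficients
#'
#' Applies W -> sgn(W) * (|W| - tau) for |W| >= tau and 0 otherwise to every
#' detail subband at every level. The approximation band is left untouched
#' (shrinking the DC band would shift global brightness). Energy never
#' increases and no coefficient grows in magnitude.
#'
#' @param coeffs a `wavelet_coeffs` object.
#' @param spec a [threshold_spec].
#' @return A `wavelet_coeffs` object with shrunken detail bands.
#' @export
soft_threshold <- function(coeffs, spec) {
  stopifnot(inherits(coeffs, "wavelet_coeffs"), inherits(spec, "threshold_spec"))
  out <- coeffs
  for (l in seq_len(coeffs$levels)) {
    out$details[[l]] <- lapply(coeffs$details[[l]], soft_threshold_values,
                               tau = spec$tau, softness = spec$softness)
  }
  out
}
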