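#' Similarity-filter parameters
#'
#' Parameters of the regularized neighborhood pixel-similarity stage: for
#' every target pixel, all pixels in a `search_size` x `search_size` window
#' are compared through `patch_size` x `patch_size` patches around them, and
#' the target is replaced by the weight-normalized average of the candidates.
#'
#' @param h smoothing strength in intensity units; larger h averages more
#'   aggressively (default 3, the pipeline's standard setting).
#' @param patch_size odd side length of the comparison patch (default 7).
#' @param search_size odd side length of the search window (default 21).
#' @param sigma_eta standard deviation (in pixels) of the Gaussian weighting
#'   applied over patch offsets in the patch distance; `Inf` gives the plain
#'   L2 norm. Default `patch_size / 4`.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(h = 3, patch_size = 7L, search_size = 21L,
                          sigma_eta = patch_size / 4) {
  patch_size <- as.integer(patch_size); search_size <- as.integer(search_size)
  if (h <= 0) stop("`h` must be > 0")
  if (patch_size %% 2L == 0L || search_size %% 2L == 0L)
    stop("`patch_size` and `search_size` must be odd")
  if (patch_size > search_size) stop("`patch_size` must be <= `search_size`")
  if (!(sigma_eta > 0)) stop("`sigma_eta` must be > 0 (Inf allowed)")
  structure(list(h = h, patch_size = patch_size, search_size = search_size,
                 sigma_eta = sigma_eta),
            class = "filter_params")
}

#' @export
print.filter_params <- function(x, ...) {
  cat(sprintf("<filter_params> h = %g, patch %dx%d, search %dx%d, sigma_eta = %g\n",
              x$h, x$patch_size, x$patch_size, x$search_size, x$search_size,
              x$sigma_eta))
  invisible(x)
}

## Symmetric (mirror, edge-inclusive) reflection of index i into 1..n.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- ((i - 1L) %% period + period) %% period  # 0-based, folded into [0, 2n)
  ifelse(j < n, j + 1L, period - j)
}

#' Gaussian patch-offset kernel
#'
#' The weighting G_eta over patch offsets used inside the patch distance:
#' a 2-D isotropic Gaussian of standard deviation `sigma_eta` centered on the
#' patch, normalized to sum to 1. `sigma_eta = Inf` gives uniform weights
#' (plain L2 norm).
#'
#' @param size odd patch side.
#' @param sigma_eta Gaussian std in pixels, or `Inf`.
#' @return A `size` x `size` matrix summing to 1.
#' @export
patch_kernel <- function(size, sigma_eta) {
  if (size %% 2L == 0L) stop("`size` must be odd")
  if (is.infinite(sigma_eta)) return(matrix(1 / size^2, size, size))
  r <- (size - 1L) / 2
  off <- seq(-r, r)
  g <- exp(-outer(off^2, off^2, `+`) / (2 * sigma_eta^2))
  g / sum(g)
}

#' Extract a patch around a pixel
#'
#' Returns the `size` x `size` neighborhood centered at `center`, with
#' out-of-bounds pixels filled by symmetric (mirror) border reflection.
#'
#' @param vol an [image_volume] holding a 2-D slice, or a matrix.
#' @param center integer `c(row, col)` (1-based) of the patch center.
#' @param size odd patch side.
#' @return A `size` x `size` numeric matrix.
#' @export
extract_patch <- function(vol, center, size) {
  x <- as_image_data(vol)
  if (length(dim(x)) != 2L) stop("`vol` must be a single 2-D slice")
  if (size %% 2L == 0L) stop("`size` must be odd")
  r <- (size - 1L) / 2
  ri <- reflect_index(seq(center[1] - r, center[1] + r), nrow(x))
  ci <- reflect_index(seq(center[2] - r, center[2] + r), ncol(x))
  x[ri, ci, drop = FALSE]
}

#' Gaussian-weighted squared patch distance
#'
#' d2(Pa, Pb) = sum over offsets of G_eta(offset) * (Pa - Pb)^2, with G_eta
#' the normalized Gaussian kernel of [patch_kernel]. This is the squared
#' norm ||Pa - Pb||^2 entering the exponential weight.
#'
#' @param pa,pb patches of identical (odd, square) shape.
#' @param sigma_eta Gaussian weighting std; `Inf` for the plain L2 norm.
#' @return A non-negative scalar.
#' @export
patch_distance <- function(pa, pb, sigma_eta = nrow(pa) / 4) {
  if (!identical(dim(pa), dim(pb))) stop("patches must have the same shape")
  k <- patch_kernel(nrow(pa), sigma_eta)
  sum(k * (pa - pb)^2)
}

#' Exponential similarity weight
#'
#' The unnormalized weight exp(-d2 / h^2) given a squared patch distance; the
#' normalization (division by the sum of weights over the search window) is
#' applied in [weighted_average].
#'
#' @param d2 non-negative squared patch distance.
#' @param h smoothing strength, > 0.
#' @return Weight in (0, 1].
#' @export
compute_weight <- function(d2, h) {
  if (any(d2 < 0)) stop("`d2` must be >= 0")
  if (h <= 0) stop("`h` must be > 0")
  exp(-d2 / h^2)
}

#' Similarity weights for a single pixel
#'
#' Diagnostic view of the weight field: for one target pixel, the
#' unnormalized weights W over its search window, their maximum-relative
#' form, and the normalizer Z (sum of weights). The self-weight (zero patch
#' distance) is always the maximum.
#'
#' @param vol 2-D [image_volume] or matrix.
#' @param center target pixel `c(row, col)`.
#' @param params a [filter_params].
#' @return List with `weights` (search x search matrix), `relative`
#'   (weights / max), `normalized` (weights / Z) and `normalizer`.
#' @export
pixel_weights <- function(vol, center, params = filter_params()) {
  x <- as_image_data(vol)
  s <- params$search_size; r <- (s - 1L) / 2
  pa <- extract_patch(x, center, params$patch_size)
  w <- matrix(0, s, s)
  for (di in -r:r) for (dj in -r:r) {
    pb <- extract_patch(x, center + c(di, dj), params$patch_size)
    w[di + r + 1, dj + r + 1] <-
      compute_weight(patch_distance(pa, pb, params$sigma_eta), params$h)
  }
  list(weights = w, relative = w / max(w), normalized = w / sum(w),
       normalizer = sum(w))
}

#' Regularized neighborhood similarity filtering
#'
#' The first stage of the denoiser: every pixel is replaced by the convex,
#' weight-normalized average of the pixels in its search window, each
#' weighted by exp(-d2/h^2) where d2 is the Gaussian-weighted squared
#' distance between the patches around target and candidate. Borders are
#' handled by symmetric reflection. The output therefore always stays within
#' the intensity range of the input.
#'
#' @param vol a single 2-D slice ([image_volume] or matrix), normalized.
#' @param params a [filter_params].
#' @return Filtered image of the same class and shape as the input. The
#'   attribute `pixel_visits` carries the instrumented count of patch-pixel
#'   reads performed by the filtering loops.
#' @export
weighted_average <- function(vol, params = filter_params()) {
  x <- as_image_data(vol)
  if (length(dim(x)) != 2L) stop("similarity filter operates on a single 2-D slice")
  if (params$search_size > min(dim(x)))
    stop("search window (", params$search_size, ") larger than image (",
         paste(dim(x), collapse = "x"), ")")
  k <- patch_kernel(params$patch_size, params$sigma_eta)
  out <- nlm_core(x, params$patch_size, params$search_size, params$h, k)
  visits <- attr(out, "pixel_visits")
  if (inherits(vol, "image_volume")) {
    res <- vol
    attr(out, "pixel_visits") <- NULL
    res$data <- out
    res$intensity_range <- range(out)
    attr(res, "pixel_visits") <- visits
    res
  } else {
    out
  }
}
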