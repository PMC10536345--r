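#' Quality-metric parameters
#'
#' Constants of the full-reference metrics: SSIM stabilizers C1 = (K1*L)^2
#' and C2 = (K2*L)^2 with K1 = 0.01, K2 = 0.03 on dynamic range L (255 for
#' 8-bit data, giving C1 = 6.5025 and C2 = 58.5225), the Gaussian SSIM
#' window (11 x 11, std 1.5), and the PSNR peak MAX = L.
#'
#' @param K1,K2 SSIM stability constants (defaults 0.01 and 0.03).
#' @param L dynamic range of the data (default 255).
#' @param ssim_window odd side of the Gaussian-weighted local SSIM window.
#' @param ssim_sigma std of that Gaussian window in pixels.
#' @return Object of class `metric_params` with derived `C1`, `C2`, `max_i`.
#' @export
metric_params <- function(K1 = 0.01, K2 = 0.03, L = 255,
                          ssim_window = 11L, ssim_sigma = 1.5) {
  if (L <= 0) stop("`L` must be > 0")
  if (ssim_window %% 2L == 0L) stop("`ssim_window` must be odd")
  structure(list(K1 = K1, K2 = K2, L = L,
                 C1 = (K1 * L)^2, C2 = (K2 * L)^2,
                 ssim_window = as.integer(ssim_window), ssim_sigma = ssim_sigma,
                 max_i = L),
            class = "metric_params")
}

check_same_shape <- function(x, y) {
  if (!identical(dim(x), dim(y))) stop("images must have the same shape")
}

gaussian_kernel_2d <- function(size, sigma) {
  r <- (size - 1L) / 2
  off <- seq(-r, r)
  g <- exp(-outer(off^2, off^2, `+`) / (2 * sigma^2))
  g / sum(g)
}

## Mean over slices for 3-D input, scalar for 2-D.
slicewise_mean <- function(x, y, vol, f) {
  if (length(dim(x)) == 2L) return(f(x, y))
  ax <- if (inherits(vol, "image_volume")) vol$slice_axis else 1L
  n <- dim(x)[ax]
  vals <- vapply(seq_len(n), function(i) {
    idx <- rep(list(quote(expr = )), 3L); idx[[ax]] <- i
    f(as.matrix(do.call(`[`, c(list(x), idx, list(drop = TRUE)))),
      as.matrix(do.call(`[`, c(list(y), idx, list(drop = TRUE)))))
  }, numeric(1))
  mean(vals)
}

#' Structural similarity index (SSIM)
#'
#' SSIM(x, y) = (2 mu_x mu_y + C1)(2 sigma_xy + C2) /
#' ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2)). In the default
#' `"local"` mode the statistics are computed in Gaussian-weighted local
#' windows (11 x 11, std 1.5, replicate borders) and the resulting map is
#' mean-pooled. `"global"` mode evaluates the formula once over the whole
#' image (useful for closed-form verification). 3-D volumes are scored per
#' slice and averaged.
#'
#' @param x,y images of identical shape on the same dynamic range.
#' @param params a [metric_params].
#' @param mode `"local"` (default) or `"global"`.
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(x, y, params = metric_params(), mode = c("local", "global")) {
  mode <- match.arg(mode)
  xv <- x
  x <- as_image_data(x); y <- as_image_data(y)
  check_same_shape(x, y)
  f <- function(a, b) {
    if (mode == "global") {
      mu_x <- mean(a); mu_y <- mean(b)
      vx <- mean((a - mu_x)^2); vy <- mean((b - mu_y)^2)
      cxy <- mean((a - mu_x) * (b - mu_y))
      ((2 * mu_x * mu_y + params$C1) * (2 * cxy + params$C2)) /
        ((mu_x^2 + mu_y^2 + params$C1) * (vx + vy + params$C2))
    } else {
      w <- gaussian_kernel_2d(params$ssim_window, params$ssim_sigma)
      mu_x <- EBImage::filter2(a, w, boundary = "replicate")
      mu_y <- EBImage::filter2(b, w, boundary = "replicate")
      xx <- EBImage::filter2(a * a, w, boundary = "replicate") - mu_x^2
      yy <- EBImage::filter2(b * b, w, boundary = "replicate") - mu_y^2
      xy <- EBImage::filter2(a * b, w, boundary = "replicate") - mu_x * mu_y
      smap <- ((2 * mu_x * mu_y + params$C1) * (2 * xy + params$C2)) /
        ((mu_x^2 + mu_y^2 + params$C1) * (xx + yy + params$C2))
      mean(smap)
    }
  }
  slicewise_mean(x, y, xv, f)
}

#' Peak signal-to-noise ratio (dB)
#'
#' PSNR = 10 log10(MAX^2 / MSE) with MAX the peak intensity (`params$max_i`,
#' 255 for 8-bit data) and MSE the mean squared difference. Identical images
#' give `+Inf`.
#'
#' @inheritParams ssim
#' @return PSNR in decibels.
#' @export
psnr <- function(x, y, params = metric_params()) {
  x <- as_image_data(x); y <- as_image_data(y)
  check_same_shape(x, y)
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(params$max_i^2 / mse)
}

#' Root mean square error
#'
#' sqrt(mean((x - y)^2)).
#'
#' @inheritParams ssim
#' @return Non-negative scalar.
#' @export
rmse <- function(x, y) {
  x <- as_image_data(x); y <- as_image_data(y)
  check_same_shape(x, y)
  sqrt(mean((x - y)^2))
}

scharr_masks <- function() {
  gx <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3, 3) / 16  # d/d(row)
  list(gx = gx, gy = t(gx))
}

#' Gradient magnitude map
#'
#' Per-pixel sqrt(Hx^2 + Vy^2) where Hx and Vy are the horizontal and
#' vertical Scharr mask responses (the FSIM convention), with replicate
#' borders.
#'
#' @param x a 2-D [image_volume] or matrix.
#' @return A matrix of the same shape.
#' @export
gradient_magnitude <- function(x) {
  m <- as_image_data(x)
  if (length(dim(m)) != 2L) stop("gradient_magnitude operates on a single 2-D slice")
  k <- scharr_masks()
  hx <- EBImage::filter2(m, k$gx, boundary = "replicate")
  vy <- EBImage::filter2(m, k$gy, boundary = "replicate")
  sqrt(hx^2 + vy^2)
}

#' Feature similarity index (FSIM)
#'
#' Canonical FSIM: per-pixel similarity of phase-congruency maps
#' S_PC = (2 PC1 PC2 + T1)/(PC1^2 + PC2^2 + T1) and of Scharr gradient
#' magnitudes S_G = (2 G1 G2 + T2)/(G1^2 + G2^2 + T2), combined as
#' S_PC * S_G and pooled with weights max(PC1, PC2). Being built on phase
#' congruency, FSIM is invariant to constant brightness shifts. A border rim
#' the width of the smallest log-Gabor wavelength is excluded from pooling
#' (filter support). 3-D volumes are scored per slice and averaged.
#'
#' @param x,y images of identical shape (reference, test).
#' @param T1 stabilizer for the phase-congruency factor (default 0.85).
#' @param T2 stabilizer for the gradient factor (default 160, matched to
#'   Scharr/16 responses on a [0, 255] range).
#' @param ... passed to [phase_congruency].
#' @return FSIM in `[0, 1]`.
#' @export
fsim <- function(x, y, T1 = 0.85, T2 = 160, ...) {
  xv <- x
  x <- as_image_data(x); y <- as_image_data(y)
  check_same_shape(x, y)
  f <- function(a, b) {
    pc1 <- phase_congruency(a, ...)
    pc2 <- phase_congruency(b, ...)
    g1 <- gradient_magnitude(a)
    g2 <- gradient_magnitude(b)
    s_pc <- (2 * pc1 * pc2 + T1) / (pc1^2 + pc2^2 + T1)
    s_g <- (2 * g1 * g2 + T2) / (g1^2 + g2^2 + T2)
    pcm <- pmax(pc1, pc2)
    rim <- attr(pc1, "min_wavelength")
    n <- nrow(a); m <- ncol(a)
    keep_r <- (rim + 1):(n - rim); keep_c <- (rim + 1):(m - rim)
    sl <- (s_pc * s_g * pcm)[keep_r, keep_c]
    wt <- pcm[keep_r, keep_c]
    sum(sl) / (sum(wt) + .Machine$double.eps)
  }
  slicewise_mean(x, y, xv, f)
}

#' Full quality report
#'
#' Computes SSIM, PSNR, RMSE and (optionally) FSIM of a test image against a
#' reference, with a per-slice breakdown for 3-D input.
#'
#' @param reference clean reference [image_volume].
#' @param test degraded or denoised [image_volume] of the same shape.
#' @param params a [metric_params].
#' @param with_fsim compute FSIM too (needs slices of at least the largest
#'   log-Gabor support; default `TRUE`).
#' @return Object of class `quality_report`.
#' @export
quality_report <- function(reference, test, params = metric_params(),
                           with_fsim = TRUE) {
  res <- list(ssim = ssim(reference, test, params),
              psnr = psnr(reference, test, params),
              rmse = rmse(reference, test),
              fsim = if (with_fsim) fsim(reference, test) else NA_real_,
              params = params)
  x <- as_image_data(reference)
  if (length(dim(x)) == 3L && inherits(reference, "image_volume")) {
    n <- n_slices(reference)
    res$per_slice <- data.frame(
      slice = seq_len(n),
      ssim = vapply(seq_len(n), function(i)
        ssim(get_slice(reference, i), get_slice(test, i), params), numeric(1)),
      psnr = vapply(seq_len(n), function(i)
        psnr(get_slice(reference, i), get_slice(test, i), params), numeric(1)),
      rmse = vapply(seq_len(n), function(i)
        rmse(get_slice(reference, i), get_slice(test, i)), numeric(1)))
  }
  structure(res, class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  cat(sprintf("  SSIM: %.4f   PSNR: %.2f dB   RMSE: %.4f   FSIM: %s\n",
              x$ssim, x$psnr, x$rmse,
              if (is.na(x$fsim)) "-" else sprintf("%.4f", x$fsim)))
  invisible(x)
}
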