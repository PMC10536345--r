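## Log-Gabor phase congruency.
##
## Local feature significance measured as the degree of phase alignment of
## log-Gabor filter responses across scales, per orientation, with
## Rayleigh-based noise-energy compensation. Because every filter has zero
## response at DC, the map is exactly invariant to adding a constant to the
## image; on a constant image all responses vanish and the map is 0.

## Raised Butterworth lowpass over the normalized frequency plane, used to
## tame the high-frequency tail of the coarsest filters.
lowpass_radial <- function(radius, cutoff = 0.45, order = 15) {
  1 / (1 + (radius / cutoff)^(2 * order))
}

freq_grids <- function(nr, nc) {
  fx <- (seq_len(nc) - 1) / nc; fx[fx >= 0.5] <- fx[fx >= 0.5] - 1
  fy <- (seq_len(nr) - 1) / nr; fy[fy >= 0.5] <- fy[fy >= 0.5] - 1
  X <- matrix(fx, nr, nc, byrow = TRUE)
  Y <- matrix(fy, nr, nc)
  r <- sqrt(X^2 + Y^2)
  r[1, 1] <- 1  # avoid log(0); the DC gain is forced to 0 below
  list(radius = r, theta = atan2(-Y, X))
}

#' Phase congruency map
#'
#' Computes a per-pixel phase-congruency map in [0, 1] from a multi-scale,
#' multi-orientation log-Gabor filter bank (defaults: 4 scales starting at a
#' 6-pixel wavelength with scaling factor 2, 4 orientations) with
#' Rayleigh-model noise-energy compensation estimated from the
#' smallest-scale amplitudes. The measure is invariant to constant
#' brightness shifts and to contrast scaling of features; a constant image
#' maps to all zeros.
#'
#' @param x 2-D [image_volume] or matrix; its shortest side must be at least
#'   the largest filter wavelength (`min_wavelength * mult^(nscale-1)`).
#' @param nscale number of filter scales (default 4).
#' @param norient number of filter orientations (default 4).
#' @param min_wavelength wavelength of the finest scale in pixels (default 6).
#' @param mult scaling factor between scales (default 2).
#' @param sigma_onf ratio controlling the radial log-Gabor bandwidth
#'   (default 0.55, about two octaves).
#' @param k noise threshold in standard deviations above the estimated noise
#'   energy mean (default 2).
#' @param epsilon stabilizer against division by zero (default 1e-4).
#' @return Matrix in `[0, 1]` with attribute `min_wavelength`.
#' @export
phase_congruency <- function(x, nscale = 4L, norient = 4L, min_wavelength = 6,
                             mult = 2, sigma_onf = 0.55, k = 2,
                             epsilon = 1e-4) {
  m <- as_image_data(x)
  if (length(dim(m)) != 2L) stop("phase_congruency operates on a single 2-D slice")
  max_wave <- min_wavelength * mult^(nscale - 1)
  if (min(dim(m)) < max_wave)
    stop("image ", paste(dim(m), collapse = "x"),
         " is smaller than the largest filter support (", max_wave, " px)")
  nr <- nrow(m); nc <- ncol(m)
  g <- freq_grids(nr, nc)
  lp <- lowpass_radial(g$radius)
  imfft <- stats::fft(m)

  # Radial components, one per scale (shared across orientations)
  radial <- vector("list", nscale)
  for (s in seq_len(nscale)) {
    f0 <- 1 / (min_wavelength * mult^(s - 1))
    rf <- exp(-(log(g$radius / f0))^2 / (2 * log(sigma_onf)^2)) * lp
    rf[1, 1] <- 0
    radial[[s]] <- rf
  }

  theta_sigma <- pi / norient / 1.3
  pc_num <- matrix(0, nr, nc)
  pc_den <- matrix(0, nr, nc)
  npix <- nr * nc

  for (o in seq_len(norient)) {
    angle <- (o - 1) * pi / norient
    dth <- abs(atan2(sin(g$theta - angle), cos(g$theta - angle)))
    spread <- exp(-dth^2 / (2 * theta_sigma^2))
    sumE <- matrix(0, nr, nc); sumO <- matrix(0, nr, nc)
    sumAn <- matrix(0, nr, nc)
    EO_re <- vector("list", nscale); EO_im <- vector("list", nscale)
    tau <- 0
    for (s in seq_len(nscale)) {
      filt <- radial[[s]] * spread
      resp <- stats::fft(imfft * filt, inverse = TRUE) / npix
      re <- Re(resp); im <- Im(resp)
      EO_re[[s]] <- re; EO_im[[s]] <- im
      an <- sqrt(re^2 + im^2)
      sumAn <- sumAn + an
      sumE <- sumE + re; sumO <- sumO + im
      if (s == 1L) tau <- stats::median(an) / sqrt(log(4))
    }
    xe <- sqrt(sumE^2 + sumO^2) + epsilon
    meanE <- sumE / xe; meanO <- sumO / xe
    energy <- matrix(0, nr, nc)
    for (s in seq_len(nscale)) {
      energy <- energy + EO_re[[s]] * meanE + EO_im[[s]] * meanO -
        abs(EO_re[[s]] * meanO - EO_im[[s]] * meanE)
    }
    # Rayleigh noise-energy compensation from the finest-scale amplitude
    total_tau <- tau * (1 - (1 / mult)^nscale) / (1 - 1 / mult)
    noise_mean <- total_tau * sqrt(pi / 2)
    noise_sigma <- total_tau * sqrt((4 - pi) / 2)
    T <- (noise_mean + k * noise_sigma) / 1.7
    energy <- pmax(energy - T, 0)
    pc_num <- pc_num + energy
    pc_den <- pc_den + sumAn
  }
  pc <- pc_num / (pc_den + epsilon)
  pc <- pmin(pmax(pc, 0), 1)
  attr(pc, "min_wavelength") <- as.integer(min_wavelength)
  pc
}
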