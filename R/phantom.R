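#' Synthetic phantom specification
#'
#' Geometry and texture parameters of the built-in T1w-like test volume:
#' piecewise-smooth tissue regions built from smooth random blob fields
#' (default geometry 181 slices of 256 x 256 pixels at 1 mm), three tissue
#' intensity classes emulating CSF/grey/white contrast, an optional smooth
#' multiplicative bias field, and optional softening of class boundaries.
#' Everything is deterministic under the seed.
#'
#' @param shape integer `c(slices, height, width)` (default
#'   `c(181, 256, 256)`).
#' @param tissue_levels strictly increasing class mean intensities before
#'   normalization (default `c(50, 120, 200)`).
#' @param blob_count number of smooth 3-D Gaussian blobs shaping the tissue
#'   regions (default 6).
#' @param bias_amplitude relative amplitude of the low-frequency intensity
#'   inhomogeneity, in `[0, 0.5]` (default 0.1).
#' @param edge_softness Gaussian blur std in pixels applied to class
#'   boundaries (default 1.5; 0 disables).
#' @param seed RNG seed (default 1).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(181L, 256L, 256L),
                         tissue_levels = c(50, 120, 200),
                         blob_count = 6L, bias_amplitude = 0.1,
                         edge_softness = 1.5, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("`shape` must be 3 positive integers")
  if (any(diff(tissue_levels) <= 0)) stop("`tissue_levels` must be strictly increasing")
  if (blob_count < 1L && length(tissue_levels) > 1L)
    stop("`blob_count` must be >= 1 when more than one tissue level is requested")
  if (bias_amplitude < 0 || bias_amplitude > 0.5) stop("`bias_amplitude` must be in [0, 0.5]")
  if (edge_softness < 0) stop("`edge_softness` must be >= 0")
  structure(list(shape = shape, tissue_levels = tissue_levels,
                 blob_count = as.integer(blob_count),
                 bias_amplitude = bias_amplitude,
                 edge_softness = edge_softness, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a noise-free synthetic phantom
#'
#' Builds the package's stand-in for an external simulated-brain volume:
#' per slice, smooth closed regions (level sets of a sum of seeded 3-D
#' Gaussian blobs) are assigned the tissue intensities, boundaries are
#' optionally softened by Gaussian blur, a smooth low-frequency bias field
#' is multiplied in, and the whole volume is normalized to [0, 255]. The
#' result has edges, flat regions and slow intensity drifts -- the features
#' a denoiser must preserve -- without any anatomical atlas or download.
#'
#' @param spec a [phantom_spec].
#' @return A noise-free [image_volume] with spacing `(1, 1, 1)` mm,
#'   `slice_axis = 1`, intensities in [0, 255].
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  ns <- spec$shape[1]; h <- spec$shape[2]; w <- spec$shape[3]
  K <- length(spec$tissue_levels)
  B <- spec$blob_count

  pars <- with_seed(spec$seed, list(
    cy = stats::runif(B, 0.15, 0.85) * h,
    cx = stats::runif(B, 0.15, 0.85) * w,
    cz = stats::runif(B, 0.1, 0.9) * max(ns, 2),
    ry = stats::runif(B, 0.10, 0.30) * h,
    rx = stats::runif(B, 0.10, 0.30) * w,
    rz = stats::runif(B, 0.4, 1.2) * max(ns, 2),
    amp = stats::runif(B, 0.5, 1),
    phases = stats::runif(6, 0, 2 * pi)
  ))

  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)

  field <- array(0, dim = c(ns, h, w))
  for (z in seq_len(ns)) {
    sl <- matrix(0, h, w)
    for (b in seq_len(B)) {
      az <- pars$amp[b] * exp(-(z - pars$cz[b])^2 / (2 * pars$rz[b]^2))
      sl <- sl + az * exp(-((yy - pars$cy[b])^2 / (2 * pars$ry[b]^2) +
                              (xx - pars$cx[b])^2 / (2 * pars$rx[b]^2)))
    }
    field <- set_slice(field, 1L, z, sl)
  }

  # Tissue classes: global quantile level sets of the blob field
  breaks <- stats::quantile(field, probs = seq(0, 1, length.out = K + 1))
  breaks[1] <- -Inf; breaks[K + 1] <- Inf
  cls <- array(findInterval(field, breaks, rightmost.closed = TRUE),
               dim = dim(field))
  cls[cls > K] <- K
  vol <- array(spec$tissue_levels[cls], dim = dim(field))

  if (spec$edge_softness > 0) {
    for (z in seq_len(ns)) {
      vol <- set_slice(vol, 1L, z,
                       EBImage::gblur(matrix(vol[z, , ], h, w),
                                      sigma = spec$edge_softness))
    }
  }

  if (spec$bias_amplitude > 0) {
    ph <- pars$phases
    zz <- array(rep(seq_len(ns), times = h * w), dim = c(ns, h, w))
    yyv <- aperm(array(rep(seq_len(h), times = ns * w), dim = c(h, ns, w)), c(2, 1, 3))
    xxv <- aperm(array(rep(seq_len(w), times = ns * h), dim = c(w, ns, h)), c(2, 3, 1))
    raw <- cos(2 * pi * yyv / h + ph[1]) + cos(2 * pi * xxv / w + ph[2]) +
      cos(2 * pi * zz / max(ns, 2) + ph[3]) +
      cos(2 * pi * (yyv / h + xxv / w) + ph[4])
    raw <- raw / max(abs(raw))
    vol <- vol * (1 + spec$bias_amplitude * raw)
  }

  lo <- min(vol); hi <- max(vol)
  vol <- (vol - lo) * (255 / (hi - lo))
  image_volume(vol, spacing = c(1, 1, 1), slice_axis = 1L,
               intensity_range = c(0, 255))
}

#' Default phantom slice
#'
#' Convenience wrapper producing a single 2-D phantom slice with the default
#' in-plane geometry (256 x 256), used throughout the experiments and tests.
#'
#' @param seed RNG seed.
#' @param size in-plane side length (default 256).
#' @param ... further arguments passed to [phantom_spec].
#' @return A 2-D [image_volume] in [0, 255].
#' @export
phantom_slice <- function(seed = 1L, size = 256L, ...) {
  vol <- make_phantom(phantom_spec(shape = c(1L, size, size), seed = seed, ...))
  image_volume(get_slice(vol, 1L), spacing = vol$spacing[2:3],
               intensity_range = vol$intensity_range)
}
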