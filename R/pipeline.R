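#' Pipeline configuration
#'
#' Bundles all tunables of the two-stage denoiser: the similarity-filter
#' parameters, the wavelet basis and depth, the data-driven threshold factor,
#' and an optional noise specification for simulation mode. Round-trips
#' losslessly through YAML via [write_config]/[read_config].
#'
#' @param filter a [filter_params] (default h = 3, patch 7, search 21).
#' @param wavelet wavelet basis name (default `"db4"`).
#' @param levels decomposition depth (default 2).
#' @param tau_factor multiplier of the mean filtered intensity giving the
#'   soft threshold (default 0.005).
#' @param softness thresholding blend in `[0, 1]`, 0 = pure soft (default).
#' @param noise optional [noise_spec] for simulation mode.
#' @param metrics_enabled compute quality metrics in experiment runs.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = filter_params(), wavelet = "db4",
                            levels = 2L, tau_factor = 0.005, softness = 0,
                            noise = NULL, metrics_enabled = TRUE) {
  stopifnot(inherits(filter, "filter_params"))
  wavelet_filters(wavelet)  # validates the name
  if (!is.null(noise)) stopifnot(inherits(noise, "noise_spec"))
  structure(list(filter = filter, wavelet = wavelet,
                 levels = as.integer(levels), tau_factor = tau_factor,
                 softness = softness, noise = noise,
                 metrics_enabled = isTRUE(metrics_enabled)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  filter: h = %g, patch %d, search %d\n",
              x$filter$h, x$filter$patch_size, x$filter$search_size))
  cat(sprintf("  wavelet: %s, %d level(s), tau_factor %g, softness %g\n",
              x$wavelet, x$levels, x$tau_factor, x$softness))
  if (!is.null(x$noise))
    cat(sprintf("  noise: %s %g%% seed %d\n", x$noise$model,
                x$noise$level_pct, x$noise$seed))
  invisible(x)
}

#' Write a pipeline configuration to YAML
#' @param cfg a [pipeline_config].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  lst <- list(filter = unclass(cfg$filter), wavelet = cfg$wavelet,
              levels = cfg$levels, tau_factor = cfg$tau_factor,
              softness = cfg$softness,
              noise = if (!is.null(cfg$noise)) unclass(cfg$noise)[c("model", "level_pct", "seed")],
              metrics_enabled = cfg$metrics_enabled)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path a YAML file written by [write_config] (or hand-edited with the
#'   same keys).
#' @return A [pipeline_config].
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  fp <- do.call(filter_params, lst$filter)
  ns <- if (!is.null(lst$noise)) do.call(noise_spec, lst$noise)
  pipeline_config(filter = fp, wavelet = lst$wavelet, levels = lst$levels,
                  tau_factor = lst$tau_factor, softness = lst$softness,
                  noise = ns, metrics_enabled = lst$metrics_enabled)
}

denoise_slice <- function(m, cfg) {
  filtered <- tryCatch(weighted_average(m, cfg$filter),
                       error = function(e) stop("similarity-filter stage: ",
                                                conditionMessage(e), call. = FALSE))
  spec <- compute_tau(filtered, cfg$tau_factor, cfg$softness)
  coeffs <- tryCatch(wavelet_decompose(filtered, cfg$wavelet, cfg$levels),
                     error = function(e) stop("wavelet-decomposition stage: ",
                                              conditionMessage(e), call. = FALSE))
  rec <- wavelet_reconstruct(soft_threshold(coeffs, spec))
  overshoot <- mean(rec < 0 | rec > 255)
  out <- pmin(pmax(rec, 0), 255)
  attr(out, "tau") <- spec$tau
  attr(out, "overshoot") <- overshoot
  out
}

#' Denoise an image with the similarity + wavelet pipeline
#'
#' The package's main entry point. Each 2-D slice is passed through the
#' regularized neighborhood similarity filter, a data-driven threshold
#' tau = tau_factor * mean(filtered) is computed, the filtered slice is
#' wavelet-decomposed, detail coefficients are soft-thresholded, the slice
#' is reconstructed by the inverse transform and clipped to [0, 255], and
#' slices are reassembled into a volume of the original shape. Inputs not
#' already on the [0, 255] range are normalized first (with a message).
#'
#' @param vol an [image_volume] (2-D slice or 3-D volume).
#' @param config a [pipeline_config].
#' @param normalize normalize to [0, 255] if needed (default `TRUE`).
#' @return An object of class `pixsimwave` with the input, the denoised
#'   volume, per-slice thresholds, and the configuration. Use [fitted] for
#'   the denoised [image_volume] and [residuals] for the removed noise.
#' @export
pixsimwave <- function(vol, config = pipeline_config(), normalize = TRUE) {
  stopifnot(inherits(vol, "image_volume"), inherits(config, "pipeline_config"))
  if (!is_normalized(vol)) {
    if (!normalize) stop("input is not on [0, 255]; set `normalize = TRUE`")
    message("normalizing input to [0, 255]")
    vol <- normalize_to_8bit(vol)
  }
  taus <- numeric(0)
  overshoots <- numeric(0)
  fit <- map_slices(vol, function(m) {
    out <- denoise_slice(m, config)
    taus <<- c(taus, attr(out, "tau"))
    overshoots <<- c(overshoots, attr(out, "overshoot"))
    attributes(out) <- list(dim = dim(out))
    out
  })
  structure(list(input = vol, denoised = fit, tau = taus,
                 overshoot = overshoots, config = config,
                 call = match.call()),
            class = "pixsimwave")
}

#' Denoise and return just the image
#'
#' Convenience wrapper around [pixsimwave] returning the denoised
#' [image_volume] directly.
#'
#' @inheritParams pixsimwave
#' @return The denoised [image_volume].
#' @export
denoise <- function(vol, config = pipeline_config(), normalize = TRUE) {
  fitted(pixsimwave(vol, config, normalize))
}

#' @export
fitted.pixsimwave <- function(object, ...) object$denoised

#' @export
residuals.pixsimwave <- function(object, ...) {
  object$input$data - object$denoised$data
}

#' @export
print.pixsimwave <- function(x, ...) {
  d <- dim(x$input$data)
  cat("PixSimWave denoising fit\n")
  cat("  input: ", paste(d, collapse = " x "), " | slices:", n_slices(x$input), "\n")
  cat(sprintf("  filter: h = %g, patch %d, search %d | wavelet %s x%d | tau_factor %g\n",
              x$config$filter$h, x$config$filter$patch_size,
              x$config$filter$search_size, x$config$wavelet, x$config$levels,
              x$config$tau_factor))
  cat(sprintf("  threshold tau: %s\n",
              paste(format(round(range(x$tau), 4)), collapse = " .. ")))
  invisible(x)
}

#' @export
summary.pixsimwave <- function(object, reference = NULL, ...) {
  r <- residuals(object)
  cat("PixSimWave denoising fit\n")
  cat(sprintf("  removed-signal RMS: %.4f | max |residual|: %.4f\n",
              sqrt(mean(r^2)), max(abs(r))))
  cat(sprintf("  reconstruction overshoot fraction: %.3g\n",
              mean(object$overshoot)))
  if (!is.null(reference)) {
    qr_in <- quality_report(reference, object$input, with_fsim = FALSE)
    qr_out <- quality_report(reference, object$denoised, with_fsim = FALSE)
    cat(sprintf("  vs reference: SSIM %.4f -> %.4f | PSNR %.2f -> %.2f dB\n",
                qr_in$ssim, qr_out$ssim, qr_in$psnr, qr_out$psnr))
  }
  invisible(object)
}

#' @export
plot.pixsimwave <- function(x, slice = 1L, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show_slice <- function(m, main) {
    graphics::image(t(m[nrow(m):1, ]), col = grDevices::gray.colors(256, 0, 1),
                    axes = FALSE, main = main, useRaster = TRUE, zlim = c(0, 255))
  }
  show_slice(get_slice(x$input, slice), "input")
  show_slice(get_slice(x$denoised, slice), "denoised")
  invisible(x)
}

#' Noise sweep experiment
#'
#' For every combination of noise model, level and seed: inject noise into
#' the clean image, denoise it with the pipeline, and score both the noisy
#' and the denoised image against the clean reference. This reproduces the
#' layout of a noise-density comparison table.
#'
#' @param clean a clean, normalized [image_volume] (typically a phantom
#'   slice).
#' @param models character vector from `c("gaussian", "rician")`.
#' @param levels noise levels in percent, each in (0, 100).
#' @param seeds integer vector of RNG seeds.
#' @param config a [pipeline_config].
#' @param with_fsim also compute FSIM (default `TRUE`).
#' @return A data.frame with one row per (model, level, seed) carrying
#'   `ssim`, `psnr`, `rmse`, `fsim` of the denoised image and `ssim_noisy`,
#'   `psnr_noisy`, `rmse_noisy`, `fsim_noisy` of the noisy input.
#' @export
run_experiment <- function(clean, models = c("gaussian", "rician"),
                           levels = c(3, 5, 7, 11, 13, 15, 17),
                           seeds = 1:10, config = pipeline_config(),
                           with_fsim = TRUE) {
  if (length(models) == 0L) stop("`models` must name at least one noise model")
  if (any(levels <= 0 | levels >= 100)) stop("`levels` must lie in (0, 100)")
  grid <- expand.grid(seed = seeds, level = levels, model = models,
                      stringsAsFactors = FALSE)
  params <- metric_params()
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    spec <- noise_spec(g$model, g$level, seed = g$seed)
    noisy <- add_noise(clean, spec)
    den <- denoise(noisy, config)
    data.frame(model = g$model, level = g$level, seed = g$seed,
               ssim = ssim(clean, den, params),
               psnr = psnr(clean, den, params),
               rmse = rmse(clean, den),
               fsim = if (with_fsim) fsim(clean, den) else NA_real_,
               ssim_noisy = ssim(clean, noisy, params),
               psnr_noisy = psnr(clean, noisy, params),
               rmse_noisy = rmse(clean, noisy),
               fsim_noisy = if (with_fsim) fsim(clean, noisy) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Export experiment results
#'
#' Writes a [run_experiment] table as CSV and/or JSON.
#'
#' @param results data.frame from [run_experiment].
#' @param csv,json optional output paths.
#' @return `results`, invisibly.
#' @export
export_results <- function(results, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(results, csv, row.names = FALSE)
  if (!is.null(json)) jsonlite::write_json(results, json, digits = NA)
  invisible(results)
}

#' Instrumented per-stage operation counts
#'
#' Runs the pipeline stages on one 2-D slice and reports how many pixel
#' (or coefficient) visits each stage performed, measured from the actual
#' run: the similarity filter's count comes from its instrumented inner
#' loops, the wavelet stages from the sizes of the subbands actually
#' produced times the filter taps, thresholding from the detail coefficients
#' actually shrunk. At fixed window/filter sizes every count is proportional
#' to the pixel count, which is the sense in which the pipeline scales
#' linearly in image size.
#'
#' @param vol a 2-D [image_volume] or matrix.
#' @param config a [pipeline_config].
#' @return Named list of per-stage visit counts plus `total` and `n_pixels`.
#' @export
count_operations <- function(vol, config = pipeline_config()) {
  m <- as_image_data(vol)
  if (length(dim(m)) != 2L) stop("count_operations expects a single 2-D slice")
  if (config$filter$search_size > min(dim(m)))
    stop("search window larger than image; nothing to count")
  n <- length(m)
  filtered <- weighted_average(m, config$filter)
  pixsim_visits <- attr(filtered, "pixel_visits")
  coeffs <- wavelet_decompose(filtered, config$wavelet, config$levels)
  L <- wavelet_filters(config$wavelet)$length
  # Each produced coefficient consumed L taps on each of the two passes
  subband_sizes <- c(length(coeffs$approx),
                     vapply(coeffs$details, function(d) sum(lengths(d)), numeric(1)))
  decompose_visits <- sum(subband_sizes) * 2 * L
  detail_count <- sum(vapply(coeffs$details, function(d) sum(lengths(d)), numeric(1)))
  threshold_visits <- detail_count
  reconstruct_visits <- decompose_visits
  list(pixsim = pixsim_visits,
       tau = n,
       decompose = decompose_visits,
       threshold = threshold_visits,
       reconstruct = reconstruct_visits,
       clip = n,
       total = pixsim_visits + n + decompose_visits + threshold_visits +
         reconstruct_visits + n,
       n_pixels = n)
}
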