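#' In-memory image volume
#'
#' The container every stage of the package operates on: a 2-D slice or a
#' 3-D stack of slices of non-negative intensities, together with voxel
#' spacing, the axis that enumerates slices, and the working dynamic range.
#'
#' @param data numeric matrix (2-D) or 3-D array of intensities; must be
#'   finite and non-negative.
#' @param spacing per-axis physical voxel size in mm (recycled to the number
#'   of dimensions; default 1 mm).
#' @param slice_axis index (1-based) of the axis enumerating 2-D slices for
#'   3-D data; ignored for 2-D data.
#' @param intensity_range working dynamic range as `c(min, max)`; defaults to
#'   the data range.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = rep(1, length(dim(data))),
                         slice_axis = 1L, intensity_range = range(data)) {
  if (is.vector(data)) stop("`data` must be a 2-D matrix or 3-D array")
  nd <- length(dim(data))
  if (!nd %in% c(2L, 3L)) stop("`data` must be 2-D or 3-D, got ", nd, " dimensions")
  if (any(!is.finite(data))) stop("`data` contains NaN or Inf values")
  if (min(data) < 0) stop("`data` contains negative intensities")
  spacing <- rep_len(as.numeric(spacing), nd)
  slice_axis <- as.integer(slice_axis)
  if (slice_axis < 1L || slice_axis > nd) stop("`slice_axis` must index a dimension of `data`")
  structure(list(data = data, spacing = spacing, slice_axis = slice_axis,
                 intensity_range = as.numeric(intensity_range)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<image_volume> ", paste(d, collapse = " x "),
      sprintf(" | spacing %s mm | range [%.4g, %.4g]\n",
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  if (length(d) == 3L) cat("  slice axis:", x$slice_axis, "(", d[x$slice_axis], "slices )\n")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

## Accept either an image_volume or a bare matrix/array everywhere.
as_image_data <- function(x) {
  if (inherits(x, "image_volume")) x$data else x
}

n_slices <- function(vol) {
  d <- dim(vol$data)
  if (length(d) == 2L) 1L else d[vol$slice_axis]
}

#' Extract one 2-D slice from a volume
#'
#' @param vol an `image_volume`.
#' @param i slice index along `vol$slice_axis` (1-based). For 2-D input the
#'   only valid index is 1.
#' @return A numeric matrix.
#' @export
get_slice <- function(vol, i = 1L) {
  x <- as_image_data(vol)
  if (length(dim(x)) == 2L) {
    if (i != 1L) stop("2-D image has a single slice")
    return(x)
  }
  ax <- if (inherits(vol, "image_volume")) vol$slice_axis else 1L
  idx <- rep(list(quote(expr = )), 3L)
  idx[[ax]] <- i
  m <- do.call(`[`, c(list(x), idx, list(drop = TRUE)))
  as.matrix(m)
}

set_slice <- function(arr, ax, i, m) {
  idx <- rep(list(quote(expr = )), 3L)
  idx[[ax]] <- i
  do.call(`[<-`, c(list(arr), idx, list(value = m)))
}

## Apply f to every slice, reassembling a volume of the original shape.
map_slices <- function(vol, f, ...) {
  x <- vol$data
  if (length(dim(x)) == 2L) {
    out <- f(x, ...)
  } else {
    out <- x
    for (i in seq_len(n_slices(vol))) {
      out <- set_slice(out, vol$slice_axis, i, f(get_slice(vol, i), ...))
    }
  }
  res <- vol
  res$data <- out
  res$intensity_range <- range(out)
  res
}

file_ext2 <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii\\.gz$", p)) "nii.gz"
  else if (grepl("\\.nii$", p)) "nii"
  else if (grepl("\\.png$", p)) "png"
  else sub(".*\\.", "", p)
}

#' Load an image from disk
#'
#' Reads a NIfTI-1 volume (`.nii`, `.nii.gz`) or an 8/16-bit grayscale PNG
#' into an [image_volume]. NIfTI data are kept in native intensity units with
#' voxel spacing taken from the header; singleton dimensions are dropped and
#' volumes with more than three non-singleton dimensions are rejected. RGB
#' PNGs are converted to grayscale by channel averaging and intensities are
#' scaled to [0, 255].
#'
#' @param path path to a `.nii`, `.nii.gz` or `.png` file.
#' @return An [image_volume].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- file_ext2(path)
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    sp <- RNifti::pixdim(img)
    keep <- which(d > 1L)
    if (length(keep) > 3L) stop("NIfTI with >3 non-singleton dimensions is not supported: ", path)
    arr <- array(as.numeric(img), dim = d)
    if (length(keep) < length(d)) {
      arr <- array(arr, dim = d[keep])
      sp <- sp[keep]
    }
    if (length(dim(arr)) == 1L) arr <- matrix(arr, ncol = 1L)
    image_volume(arr, spacing = rep_len(sp, length(dim(arr))), slice_axis = 1L)
  } else if (ext == "png") {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- apply(m[, , seq_len(min(3L, dim(m)[3])), drop = FALSE], c(1, 2), mean)
    image_volume(m * 255, spacing = c(1, 1), slice_axis = 1L)
  } else {
    stop("unsupported image format '.", ext, "' (expected .nii, .nii.gz or .png)")
  }
}

#' Save an image to disk
#'
#' NIfTI output stores intensities as float64 (bit-exact round trip through
#' [load_image]) with the volume's spacing in the header. PNG output is 8-bit
#' grayscale: intensities are clamped to [0, 255] and quantized on export
#' (the only place the package rounds to integers).
#'
#' @param vol an [image_volume].
#' @param path destination ending in `.nii`, `.nii.gz` or `.png`.
#' @return `path`, invisibly.
#' @export
save_image <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  ext <- file_ext2(path)
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::asNifti(vol$data, pixdim = vol$spacing, datatype = "double")
    RNifti::writeNifti(img, path)
  } else if (ext == "png") {
    if (length(dim(vol$data)) != 2L) stop("PNG export requires a single 2-D slice")
    m <- pmin(pmax(vol$data, 0), 255) / 255
    png::writePNG(m, path)
  } else {
    stop("unsupported image format '.", ext, "' (expected .nii, .nii.gz or .png)")
  }
  invisible(path)
}

#' Rescale intensities to the 8-bit dynamic range
#'
#' Affinely maps intensities onto [0, 255] as floating-point values (no
#' integer quantization, so metric precision is preserved). The original
#' (min, max) is recorded in the `orig_range` field, making the transform
#' invertible. A constant image maps to all zeros with a warning.
#'
#' @param vol an [image_volume].
#' @return An [image_volume] with `intensity_range = c(0, 255)`.
#' @export
normalize_to_8bit <- function(vol) {
  stopifnot(inherits(vol, "image_volume"))
  lo <- min(vol$data); hi <- max(vol$data)
  out <- vol
  if (hi == lo) {
    warning("constant image: normalize_to_8bit maps it to all zeros")
    out$data <- array(0, dim = dim(vol$data))
  } else {
    out$data <- (vol$data - lo) * (255 / (hi - lo))
  }
  out$intensity_range <- c(0, 255)
  out$orig_range <- c(lo, hi)
  out
}

is_normalized <- function(vol) {
  x <- as_image_data(vol)
  min(x) >= 0 && max(x) <= 255 + 1e-9
}
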