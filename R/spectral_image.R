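#' Wavenumber axis
#'
#' Constructs the spectral axis of a hyperspectral cube. The canonical
#' in-memory order is strictly ascending wavenumber (cm^-1); FTIR files are
#' conventionally stored descending and are reversed on read. The axis must
#' be uniformly spaced (mid-IR instruments digitize on a regular grid).
#'
#' @param values Numeric vector of wavenumbers in cm^-1.
#' @return A `wavenumber_axis` object: the numeric vector with a `spacing`
#'   attribute (cm^-1).
#' @examples
#' ax <- wavenumber_axis(seq(900, 1800, by = 2))
#' axis_spacing(ax)
#' @export
wavenumber_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("wavenumber axis needs at least two points", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("wavenumber axis contains non-finite values", call. = FALSE)
  }
  d <- diff(values)
  if (any(d <= 0)) {
    stop("wavenumber axis must be strictly ascending", call. = FALSE)
  }
  spacing <- mean(d)
  if (max(abs(d - spacing)) > 1e-6) {
    stop("wavenumber axis must be uniformly spaced (tolerance 1e-6 cm^-1)",
         call. = FALSE)
  }
  structure(values, spacing = spacing, class = "wavenumber_axis")
}

#' @rdname wavenumber_axis
#' @param axis A `wavenumber_axis`.
#' @export
axis_spacing <- function(axis) attr(axis, "spacing")

#' @export
print.wavenumber_axis <- function(x, ...) {
  cat(sprintf("<wavenumber_axis> %d points, %.6g-%.6g cm^-1, spacing %.6g cm^-1\n",
              length(x), min(x), max(x), axis_spacing(x)))
  invisible(x)
}

#' Hyperspectral absorbance image
#'
#' Container for an FTIR hyperspectral cube: an H x W x B array of absorbance
#' values (AU) with a wavenumber axis, a projected pixel size, a validity
#' mask, and sample metadata. Pixel coordinates are 0-based, row-major,
#' origin top-left.
#'
#' @param cube Numeric array, H x W x B (absorbance units).
#' @param axis A [wavenumber_axis()] of length B.
#' @param pixel_size Projected pixel size in micrometres (e.g. 25 for
#'   whole-sample maps, 2.7 for fibrosis-focused maps).
#' @param mask Logical H x W matrix, `TRUE` at valid tissue pixels.
#'   Defaults to all-`TRUE`.
#' @param sample_id Character sample identifier.
#' @param group Group label, one of `"uncomplicated"`, `"hcc"`, `"unknown"`.
#' @return A `spectral_image` object (list with elements `cube`, `axis`,
#'   `pixel_size`, `mask`, `sample_id`, `group`).
#' @export
spectral_image <- function(cube, axis, pixel_size = NA_real_, mask = NULL,
                           sample_id = "sample", group = "unknown") {
  if (!inherits(axis, "wavenumber_axis")) axis <- wavenumber_axis(axis)
  if (length(dim(cube)) != 3) {
    stop("cube must be a 3-dimensional H x W x B array", call. = FALSE)
  }
  if (dim(cube)[3] != length(axis)) {
    stop(sprintf("cube has %d bands but axis has %d points",
                 dim(cube)[3], length(axis)), call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- matrix(TRUE, dim(cube)[1], dim(cube)[2])
  }
  if (!is.matrix(mask) || !all(dim(mask) == dim(cube)[1:2])) {
    stop("mask shape must equal the cube's spatial dimensions", call. = FALSE)
  }
  mask <- matrix(as.logical(mask), dim(cube)[1], dim(cube)[2])
  group <- match.arg(group, c("uncomplicated", "hcc", "unknown"))
  img <- structure(
    list(cube = cube, axis = axis, pixel_size = as.numeric(pixel_size),
         mask = mask, sample_id = sample_id, group = group),
    class = "spectral_image")
  validate_spectral_image(img)
  img
}

validate_spectral_image <- function(img) {
  bad <- !is.finite(img$cube)
  if (any(bad)) {
    # non-finite values are only allowed at masked-out pixels
    bad_px <- apply(bad, c(1, 2), any)
    if (any(bad_px & img$mask)) {
      stop("non-finite absorbance at valid (masked-true) pixels", call. = FALSE)
    }
  }
  invisible(img)
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("<spectral_image> '%s' (%s): %d x %d pixels, %d bands (%.6g-%.6g cm^-1)\n",
              x$sample_id, x$group, d[1], d[2], d[3], min(x$axis), max(x$axis)))
  cat(sprintf("  pixel size %.3g um, %d/%d valid pixels\n",
              x$pixel_size, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' @export
dim.spectral_image <- function(x) dim(x$cube)

#' Crop a spectral image to a wavenumber window
#'
#' Retains exactly the bands whose wavenumber lies in the closed interval
#' `[lo, hi]`. Mask and metadata are unchanged. Typical windows are the
#' 900-1800 cm^-1 fingerprint region for whole-sample analysis and the
#' 1040-1425 cm^-1 collagen window (which avoids the strong paraffin bands)
#' for fibrosis-focused analysis.
#'
#' @param image A [spectral_image()].
#' @param lo,hi Window bounds in cm^-1, `lo < hi`, both ends inclusive.
#' @return A `spectral_image` restricted to the window.
#' @export
crop_range <- function(image, lo, hi) {
  stopifnot(inherits(image, "spectral_image"))
  if (!(lo < hi)) stop("crop window requires lo < hi", call. = FALSE)
  keep <- image$axis >= lo & image$axis <= hi
  if (!any(keep)) {
    stop(sprintf("crop window [%g, %g] does not overlap axis range [%g, %g]",
                 lo, hi, min(image$axis), max(image$axis)), call. = FALSE)
  }
  image$cube <- image$cube[, , keep, drop = FALSE]
  image$axis <- wavenumber_axis(as.numeric(image$axis)[keep])
  image
}

# Valid-pixel spectra as an N x B matrix (rows ordered by column-major pixel
# index over the mask); used by EMSC and clustering.
pixel_matrix <- function(image) {
  d <- dim(image$cube)
  m <- matrix(image$cube, d[1] * d[2], d[3])
  m[as.vector(image$mask), , drop = FALSE]
}

# Inverse of pixel_matrix: scatter rows back into an H x W x B cube,
# non-valid pixels set to NA.
unpixel_matrix <- function(mat, mask, B) {
  H <- nrow(mask); W <- ncol(mask)
  full <- matrix(NA_real_, H * W, B)
  full[as.vector(mask), ] <- mat
  array(full, c(H, W, B))
}
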