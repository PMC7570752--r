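#' Spectral band and endmember constructors
#'
#' An endmember is a pure-component absorbance spectrum modelled as a sum of
#' Gaussian bands, each with a center (cm^-1), width (Gaussian sigma, cm^-1)
#' and amplitude (AU). Endmembers drive the synthetic phantom generator and
#' serve as annotation templates for cluster centroids.
#'
#' @param center Band center, cm^-1.
#' @param width Gaussian sigma, cm^-1 (> 0).
#' @param amplitude Peak absorbance, AU (>= 0).
#' @return `band_spec()`: a one-row tibble. `endmember()`: an `endmember`
#'   object (name plus a tibble of bands).
#' @export
band_spec <- function(center, width, amplitude) {
  if (any(width <= 0)) stop("band width must be > 0", call. = FALSE)
  if (any(amplitude < 0)) stop("band amplitude must be >= 0", call. = FALSE)
  tibble::tibble(center = as.numeric(center), width = as.numeric(width),
                 amplitude = as.numeric(amplitude))
}

#' @rdname band_spec
#' @param name Endmember name, e.g. `"glycogen_nodule"`, `"collagen_a"`,
#'   `"collagen_b"`, `"paraffin"`.
#' @param bands A tibble of bands as returned by [band_spec()] (rows may be
#'   concatenated with `dplyr::bind_rows()`).
#' @export
endmember <- function(name, bands) {
  if (nrow(bands) < 1) stop("endmember needs at least one band", call. = FALSE)
  structure(list(name = name, bands = bands), class = "endmember")
}

#' @export
print.endmember <- function(x, ...) {
  cat(sprintf("<endmember> %s: %d bands at %s cm^-1\n", x$name, nrow(x$bands),
              paste(x$bands$center, collapse = ", ")))
  invisible(x)
}

#' Default endmember library for cirrhotic liver phantoms
#'
#' Four endmembers emulating the dominant tissue signatures of cirrhosis in
#' the mid-IR fingerprint region:
#'
#' * `glycogen_nodule` — regeneration nodules of glycogenated hepatocytes:
#'   glycogen bands at 1022, 1045, 1080 and 1155 cm^-1 plus the protein
#'   amide I/II envelope shared by all tissue.
#' * `collagen_a` — fibrous septa, early-type collagen profile: collagen
#'   bands at 1174, 1202, 1230, 1250, 1278, 1304 (amide III region), 1340
#'   (collagen CH2) and 1404 cm^-1 (collagen CH3), with weak carbohydrate
#'   features at 1064/1084 cm^-1.
#' * `collagen_b` — advanced-fibrosis variant of `collagen_a`: amide III
#'   amplitudes (1202, 1230, 1278) scaled by 1.3 and the 1250/1340
#'   features downshifted/shifted to 1244/1342 cm^-1, emulating collagen
#'   crosslinking-related profile changes.
#' * `paraffin` — embedding-medium contamination: CH3/CH2 deformation bands
#'   at 1378 and 1462 cm^-1.
#'
#' Band amplitudes are free parameters of the phantom, not literature
#' claims; widths default to sigma = 8 cm^-1 (7 for paraffin).
#'
#' @return Named list of [endmember()] objects.
#' @export
default_endmembers <- function() {
  amide <- dplyr::bind_rows(
    band_spec(1655, 16, 1.00),   # amide I
    band_spec(1548, 13, 0.65),   # amide II
    band_spec(1350, 300, 0.30))  # broad fingerprint absorption envelope
  glyco <- dplyr::bind_rows(
    band_spec(1022, 8, 0.55),
    band_spec(1045, 8, 0.75),
    band_spec(1080, 8, 0.60),
    band_spec(1155, 8, 0.45),
    amide)
  col_a <- dplyr::bind_rows(
    band_spec(1064, 8, 0.18),
    band_spec(1084, 8, 0.22),
    band_spec(1174, 8, 0.30),
    band_spec(1202, 8, 0.45),
    band_spec(1230, 8, 0.55),
    band_spec(1250, 8, 0.38),
    band_spec(1278, 8, 0.45),
    band_spec(1304, 8, 0.40),
    band_spec(1340, 8, 0.35),
    band_spec(1404, 8, 0.30),
    amide)
  col_b <- col_a
  iii <- col_b$center %in% c(1202, 1230, 1278)
  col_b$amplitude[iii] <- col_b$amplitude[iii] * 1.3
  col_b$center[col_b$center == 1250] <- 1244
  col_b$center[col_b$center == 1340] <- 1342
  par <- dplyr::bind_rows(
    band_spec(1378, 7, 0.35),
    band_spec(1462, 7, 1.00))
  list(
    glycogen_nodule = endmember("glycogen_nodule", glyco),
    collagen_a = endmember("collagen_a", col_a),
    collagen_b = endmember("collagen_b", col_b),
    paraffin = endmember("paraffin", par))
}

#' Evaluate an endmember spectrum on a wavenumber axis
#'
#' The spectrum is the sum over bands of
#' `amplitude * exp(-(nu - center)^2 / (2 * width^2))`; it is non-negative
#' by construction.
#'
#' @param endmember An [endmember()].
#' @param axis A [wavenumber_axis()] (or numeric vector of wavenumbers).
#' @return Numeric vector of absorbance values (AU), one per axis point.
#' @examples
#' ax <- wavenumber_axis(seq(900, 1800, by = 2))
#' g <- synth_spectrum(default_endmembers()$glycogen_nodule, ax)
#' @export
synth_spectrum <- function(endmember, axis) {
  stopifnot(inherits(endmember, "endmember"))
  nu <- as.numeric(axis)
  b <- endmember$bands
  out <- numeric(length(nu))
  for (i in seq_len(nrow(b))) {
    out <- out + b$amplitude[i] * exp(-(nu - b$center[i])^2 / (2 * b$width[i]^2))
  }
  out
}
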