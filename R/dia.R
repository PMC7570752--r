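#' Default Masson's-trichrome stain vectors
#'
#' Beer-Lambert optical-density unit vectors (Ruifrok-Johnston convention)
#' for the three trichrome channels: collagen (light green), cytoplasm
#' (pink), nuclei (black hematoxylin-like). Rows are stains, columns the
#' RGB channels; each row has unit Euclidean norm. `I0` is the per-channel
#' background intensity of the scan (default 255). The vectors are package
#' defaults, fully overridable.
#'
#' @param od Optional 3 x 3 matrix of stain OD directions (rows collagen,
#'   cytoplasm, nuclei); rows are renormalized to unit length.
#' @param I0 Per-channel background intensity (length 1 or 3).
#' @return A `stain_vectors` object: list with unit-row matrix `od` and
#'   vector `I0`.
#' @export
default_stain_vectors <- function(od = NULL, I0 = 255) {
  if (is.null(od)) {
    od <- rbind(
      collagen  = c(0.90, 0.10, 0.42),  # light green: absorbs red + blue
      cytoplasm = c(0.10, 0.84, 0.53),  # fuchsin/scarlet: absorbs green
      nuclei    = c(0.65, 0.70, 0.29))  # hematoxylin-like dark nuclei
  }
  od <- as.matrix(od)
  if (!all(dim(od) == c(3, 3))) stop("stain matrix must be 3 x 3", call. = FALSE)
  od <- od / sqrt(rowSums(od^2))
  if (is.null(rownames(od))) rownames(od) <- c("collagen", "cytoplasm", "nuclei")
  colnames(od) <- c("R", "G", "B")
  if (kappa(od) > 1e6) stop("stain matrix is ill-conditioned", call. = FALSE)
  I0 <- rep(as.numeric(I0), length.out = 3)
  structure(list(od = od, I0 = I0), class = "stain_vectors")
}

#' Color deconvolution of a trichrome image
#'
#' Converts each RGB pixel to optical density
#' `OD_c = -log10((pixel_c + 1) / I0_c)` (the +1 offset guards 8-bit
#' zeros) and solves the 3 x 3 Beer-Lambert mixing model
#' `OD = conc %*% od` for the per-stain concentrations. Negative
#' concentrations (noise outside the stain simplex) are clipped to zero.
#'
#' @param rgb An `rgb_image` (see [read_rgb()]).
#' @param vectors A [default_stain_vectors()].
#' @return Named list of H x W concentration maps (`collagen`,
#'   `cytoplasm`, `nuclei`), plus `total_od` (H x W).
#' @export
deconvolve_stains <- function(rgb, vectors = default_stain_vectors()) {
  stopifnot(inherits(vectors, "stain_vectors"))
  d <- dim(rgb)
  px <- matrix(as.numeric(unclass(rgb)), d[1] * d[2], 3)
  od <- -log10(sweep(px + 1, 2, vectors$I0, `/`))
  conc <- od %*% solve(vectors$od)          # rows: pixels, cols: stains
  conc[conc < 0] <- 0
  maps <- lapply(seq_len(3), function(j) matrix(conc[, j], d[1], d[2]))
  names(maps) <- rownames(vectors$od)
  maps$total_od <- matrix(rowSums(od), d[1], d[2])
  maps
}

#' Segment the fibrosis (collagen) area of a trichrome image
#'
#' Reproduces the reference digital-image-analysis procedure: the image is
#' first binarized to remove the near-white paraffin background (total OD
#' below `background_od`), then collagen pixels are those tissue pixels
#' whose collagen concentration exceeds both other stain concentrations
#' and an Otsu threshold computed on collagen concentrations within tissue.
#'
#' @param rgb An `rgb_image`.
#' @param vectors Stain vectors, see [default_stain_vectors()].
#' @param background_od Total-OD threshold below which a pixel is
#'   background (default 0.15).
#' @return A `fibrosis_mask`: list of logical H x W matrices `tissue` and
#'   `collagen` (`collagen` is a subset of `tissue`).
#' @export
segment_fibrosis <- function(rgb, vectors = default_stain_vectors(),
                             background_od = 0.15) {
  stopifnot(background_od >= 0)
  maps <- deconvolve_stains(rgb, vectors)
  tissue <- maps$total_od > background_od
  if (!any(tissue)) stop("no tissue pixels above the background threshold", call. = FALSE)
  col <- maps$collagen
  dominant <- col >= maps$cytoplasm & col >= maps$nuclei
  cmax <- max(col[tissue])
  thr <- if (cmax <= 0) Inf else {
    EBImage::otsu(EBImage::Image(col / cmax), range = c(0, 1)) * cmax
  }
  collagen <- tissue & dominant & col > thr
  # degenerate single-stain image: Otsu splits the collagen mode itself
  if (cmax > 0 && sum(col[tissue] > 0.5 * cmax) > 0.95 * sum(tissue)) {
    collagen <- tissue & dominant & col > 0.5 * cmax
  }
  structure(list(tissue = tissue, collagen = collagen), class = "fibrosis_mask")
}

#' Fibrosis percentage from a segmented trichrome image
#'
#' The ratio of the collagen (fibrosis) area to the total tissue area,
#' as a percentage. Background pixels are excluded from the denominator.
#'
#' @param mask A `fibrosis_mask` from [segment_fibrosis()].
#' @return Percentage in `[0, 100]`.
#' @export
fibrosis_percent_dia <- function(mask) {
  stopifnot(inherits(mask, "fibrosis_mask"))
  n <- sum(mask$tissue)
  if (n == 0) stop("empty tissue mask", call. = FALSE)
  100 * sum(mask$collagen) / n
}
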