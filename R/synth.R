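#' Phantom configuration
#'
#' Parameters of the synthetic cirrhosis phantom: image geometry, spectral
#' axis, the target fibrosis fraction, and the contamination/degradation
#' model (additive paraffin, polynomial baseline, multiplicative scatter,
#' Gaussian noise). All stochastic draws of a phantom flow from `seed`.
#'
#' @param H,W Image height and width in pixels.
#' @param axis_lo,axis_hi,spacing Spectral axis range and point spacing,
#'   cm^-1. The default 2 cm^-1 spacing is the digitized grid of a 4 cm^-1
#'   optical-resolution measurement.
#' @param target_fibrosis Target fibrosis fraction, percent of valid tissue
#'   pixels (0 < x < 100).
#' @param fibrosis_b_share Fraction of fibrosis pixels assigned the
#'   `collagen_b` (advanced) sub-variant, in `[0, 1]`.
#' @param tissue_fraction Fraction of the frame occupied by tissue (the rest
#'   is bare-substrate background).
#' @param paraffin_amp_range Uniform range of the per-pixel additive
#'   paraffin amplitude (AU).
#' @param baseline_degree Degree of the random polynomial baseline (<= 4),
#'   evaluated on the axis rescaled to `[-1, 1]`.
#' @param baseline_coef_range Uniform range of each baseline coefficient (AU).
#' @param scatter_range Uniform range of the per-pixel multiplicative
#'   scatter factor.
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise (AU).
#' @param pixel_size Projected pixel size in micrometres.
#' @param seed Integer seed; generation is fully reproducible from
#'   (config, seed).
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(H = 64, W = 64,
                           axis_lo = 900, axis_hi = 1800, spacing = 2,
                           target_fibrosis = 30,
                           fibrosis_b_share = 0.5,
                           tissue_fraction = 0.88,
                           paraffin_amp_range = c(0.1, 0.5),
                           baseline_degree = 2,
                           baseline_coef_range = c(-0.02, 0.02),
                           scatter_range = c(0.7, 1.3),
                           noise_sd = 0.008,
                           pixel_size = 25,
                           seed = 1L) {
  stopifnot(H >= 8, W >= 8, axis_lo < axis_hi, spacing > 0,
            target_fibrosis > 0, target_fibrosis < 100,
            fibrosis_b_share >= 0, fibrosis_b_share <= 1,
            tissue_fraction > 0, tissue_fraction <= 1,
            diff(paraffin_amp_range) >= 0, paraffin_amp_range[1] >= 0,
            baseline_degree >= 0, baseline_degree <= 4,
            diff(baseline_coef_range) >= 0,
            diff(scatter_range) >= 0, scatter_range[1] > 0,
            noise_sd >= 0)
  structure(list(H = H, W = W, axis_lo = axis_lo, axis_hi = axis_hi,
                 spacing = spacing, target_fibrosis = target_fibrosis,
                 fibrosis_b_share = fibrosis_b_share,
                 tissue_fraction = tissue_fraction,
                 paraffin_amp_range = paraffin_amp_range,
                 baseline_degree = baseline_degree,
                 baseline_coef_range = baseline_coef_range,
                 scatter_range = scatter_range, noise_sd = noise_sd,
                 pixel_size = pixel_size, seed = as.integer(seed)),
            class = "phantom_config")
}

phantom_axis <- function(config) {
  wavenumber_axis(seq(config$axis_lo, config$axis_hi, by = config$spacing))
}

# deterministic per-stage sub-seed so separate generator stages draw from
# independent, reproducible streams
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# smoothed standard-normal random field (separable Gaussian blur,
# replicate-padded edges) -- the geometric primitive behind nodule/septa maps
smooth_field <- function(H, W, sigma) {
  z <- matrix(stats::rnorm(H * W), H, W)
  # kernel must fit inside the image
  radius <- min(2 * ceiling(3 * sigma) + 1, H - 1 + (H %% 2), W - 1 + (W %% 2))
  if (radius %% 2 == 0) radius <- radius - 1
  as.matrix(EBImage::gblur(z, sigma = sigma, radius = radius,
                           boundary = "replicate"))
}

#' Class codes of the phantom label map
#'
#' Integer codes used in `phantom_truth$class_map`: background = 0,
#' nodule = 1, fibrosis_a = 2, fibrosis_b = 3.
#' @return Named integer vector.
#' @export
phantom_classes <- function() {
  c(background = 0L, nodule = 1L, fibrosis_a = 2L, fibrosis_b = 3L)
}

#' Generate a ground-truth phantom label map
#'
#' Emulates cirrhotic morphology: blob-like regeneration nodules separated
#' by a connected network of ribbon-like fibrous septa, inside a tissue
#' region surrounded by bare-substrate background. Septa are the level-set
#' band of a Gaussian-smoothed random field around its median contour, with
#' the band half-width chosen so the achieved fibrosis fraction matches the
#' target; a second smoothed field splits septa pixels into the two
#' collagen sub-variants.
#'
#' @param config A [phantom_config()].
#' @return A `phantom_truth` object: `class_map` (H x W integer matrix, see
#'   [phantom_classes()]), `abundance` (named list of H x W weight
#'   matrices), `fibrosis_fraction` (percent of valid pixels labeled
#'   fibrosis), and `seed`.
#' @export
synth_label_map <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  H <- config$H; W <- config$W
  withr::with_seed(derive_seed(config$seed, "label_map"), {
    tissue <- if (config$tissue_fraction >= 1) {
      matrix(TRUE, H, W)
    } else {
      ft <- smooth_field(H, W, sigma = max(H, W) / 6)
      ft >= stats::quantile(ft, 1 - config$tissue_fraction)
    }
    if (!any(tissue)) stop("phantom generation produced no tissue pixels", call. = FALSE)
    fs <- smooth_field(H, W, sigma = min(H, W) / 14)
    d <- abs(fs - stats::median(fs[tissue]))
    wcut <- stats::quantile(d[tissue], config$target_fibrosis / 100)
    septa <- tissue & (d <= wcut)
    achieved <- 100 * sum(septa) / sum(tissue)
    if (abs(achieved - config$target_fibrosis) > 1) {
      stop(sprintf(
        "could not reach target fibrosis fraction %g%% (achieved %.2f%%)",
        config$target_fibrosis, achieved), call. = FALSE)
    }
    cls <- matrix(phantom_classes()[["background"]], H, W)
    cls[tissue] <- phantom_classes()[["nodule"]]
    cls[septa] <- phantom_classes()[["fibrosis_a"]]
    if (config$fibrosis_b_share > 0 && any(septa)) {
      fb <- smooth_field(H, W, sigma = min(H, W) / 10)
      bcut <- stats::quantile(fb[septa], 1 - config$fibrosis_b_share)
      cls[septa & fb >= bcut] <- phantom_classes()[["fibrosis_b"]]
    }
  })
  new_phantom_truth(cls, config$seed)
}

new_phantom_truth <- function(class_map, seed) {
  codes <- phantom_classes()
  abundance <- lapply(codes, function(code) (class_map == code) * 1)
  valid <- class_map != codes[["background"]]
  fib <- class_map %in% codes[c("fibrosis_a", "fibrosis_b")]
  structure(list(class_map = class_map, abundance = abundance,
                 fibrosis_fraction = 100 * sum(fib) / sum(valid),
                 seed = as.integer(seed)),
            class = "phantom_truth")
}

#' Recompute the fibrosis fraction of a phantom truth
#'
#' Percent of valid (non-background) pixels labeled `fibrosis_a` or
#' `fibrosis_b`, computed directly from the class map. Always equals the
#' stored `fibrosis_fraction`.
#'
#' @param truth A `phantom_truth`.
#' @return Percentage in `[0, 100]`.
#' @export
true_fibrosis_fraction <- function(truth) {
  codes <- phantom_classes()
  valid <- truth$class_map != codes[["background"]]
  fib <- truth$class_map %in% codes[c("fibrosis_a", "fibrosis_b")]
  100 * sum(fib) / sum(valid)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d x %d, fibrosis %.2f%% of tissue, seed %d\n",
              nrow(x$class_map), ncol(x$class_map), x$fibrosis_fraction, x$seed))
  invisible(x)
}

#' Generate paired tissue and pure-paraffin hyperspectral cubes
#'
#' Renders a phantom truth into an FTIR absorbance cube. Each tissue pixel
#' is `scatter * (class endmember + baseline polynomial +
#' paraffin_amp * paraffin spectrum) + Gaussian noise`, with per-pixel
#' scatter, baseline coefficients and paraffin amplitude drawn from the
#' seeded generator; background pixels carry only paraffin, baseline and
#' noise. A second cube of pure paraffin (with its own baseline and noise,
#' plus small per-pixel scale and band-ratio variation) emulates the
#' paraffin reference image collected at the periphery of the tissue.
#'
#' @param truth A `phantom_truth` from [synth_label_map()].
#' @param endmembers Named list of [endmember()]s; must contain `paraffin`
#'   and one entry per tissue class present in the truth
#'   (`glycogen_nodule`, `collagen_a`, `collagen_b`).
#' @param config The [phantom_config()] used to build `truth`.
#' @return List with elements `tissue` and `paraffin`, both
#'   [spectral_image()]s sharing the config axis. The tissue image's mask
#'   marks non-background pixels.
#' @export
synth_cube <- function(truth, endmembers = default_endmembers(), config) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(config, "phantom_config"))
  axis <- phantom_axis(config)
  B <- length(axis)
  codes <- phantom_classes()
  class_names <- c(nodule = "glycogen_nodule", fibrosis_a = "collagen_a",
                   fibrosis_b = "collagen_b")
  present <- names(codes)[codes %in% unique(as.vector(truth$class_map))]
  need <- c(unname(class_names[intersect(present, names(class_names))]), "paraffin")
  miss <- setdiff(need, names(endmembers))
  if (length(miss)) {
    stop(sprintf("missing endmember(s) for classes present in truth: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  spectra <- list(
    nodule = if ("glycogen_nodule" %in% names(endmembers))
      synth_spectrum(endmembers$glycogen_nodule, axis),
    fibrosis_a = if ("collagen_a" %in% names(endmembers))
      synth_spectrum(endmembers$collagen_a, axis),
    fibrosis_b = if ("collagen_b" %in% names(endmembers))
      synth_spectrum(endmembers$collagen_b, axis))
  pspec <- synth_spectrum(endmembers$paraffin, axis)
  H <- nrow(truth$class_map); W <- ncol(truth$class_map)
  N <- H * W
  tpoly <- poly_basis(axis, max(config$baseline_degree, 0))
  cls <- as.vector(truth$class_map)

  withr::with_seed(derive_seed(config$seed, "tissue_cube"), {
    base_pix <- matrix(stats::runif(N * ncol(tpoly),
                                    config$baseline_coef_range[1],
                                    config$baseline_coef_range[2]),
                       N, ncol(tpoly))
    scatter <- stats::runif(N, config$scatter_range[1], config$scatter_range[2])
    pamp <- stats::runif(N, config$paraffin_amp_range[1], config$paraffin_amp_range[2])
    flat <- matrix(0, N, B)
    for (nm in names(spectra)) {
      if (is.null(spectra[[nm]])) next
      idx <- cls == codes[[nm]]
      if (any(idx)) flat[idx, ] <- matrix(spectra[[nm]], sum(idx), B, byrow = TRUE)
    }
    flat <- flat + base_pix %*% t(tpoly) + outer(pamp, pspec)
    flat <- flat * scatter
    if (config$noise_sd > 0) {
      flat <- flat + matrix(stats::rnorm(N * B, sd = config$noise_sd), N, B)
    }
  })
  tissue <- spectral_image(array(flat, c(H, W, B)), axis,
                           pixel_size = config$pixel_size,
                           mask = truth$class_map != codes[["background"]],
                           sample_id = sprintf("phantom_%d", truth$seed),
                           group = "unknown")

  withr::with_seed(derive_seed(config$seed, "paraffin_cube"), {
    pbase <- matrix(stats::runif(N * ncol(tpoly),
                                 config$baseline_coef_range[1],
                                 config$baseline_coef_range[2]),
                    N, ncol(tpoly))
    pscale <- 1 + stats::rnorm(N, sd = 0.05)
    # a second, independent variation mode: band-ratio wobble
    pmode <- pspec * sign(sin(2 * pi * (as.numeric(axis) - config$axis_lo) /
                                (config$axis_hi - config$axis_lo)))
    pcoef <- stats::rnorm(N, sd = 0.02)
    pflat <- outer(pscale, pspec) + outer(pcoef, pmode) + pbase %*% t(tpoly)
    if (config$noise_sd > 0) {
      pflat <- pflat + matrix(stats::rnorm(N * B, sd = config$noise_sd), N, B)
    }
  })
  paraffin <- spectral_image(array(pflat, c(H, W, B)), axis,
                             pixel_size = config$pixel_size,
                             sample_id = sprintf("paraffin_%d", truth$seed),
                             group = "unknown")
  list(tissue = tissue, paraffin = paraffin)
}

# orthonormal-ish polynomial columns, degree 0..D on axis rescaled to [-1, 1]
poly_basis <- function(axis, degree) {
  nu <- as.numeric(axis)
  x <- 2 * (nu - min(nu)) / (max(nu) - min(nu)) - 1
  out <- sapply(0:degree, function(d) x^d)
  matrix(out, length(nu), degree + 1,
         dimnames = list(NULL, paste0("poly", 0:degree)))
}

#' Render a phantom truth as a Masson's-trichrome image
#'
#' Produces the paired histology rendering: collagen (fibrosis pixels)
#' green, hepatocyte cytoplasm (nodule pixels) pink with scattered black
#' nuclei dots, background near-white. Per-pixel color follows the same
#' Beer-Lambert optical-density stain model the DIA module inverts, so
#' color deconvolution recovers the planted fibrosis fraction.
#'
#' @param truth A `phantom_truth`.
#' @param scale Micrometres per pixel of the rendering.
#' @param vectors Stain vectors, see [default_stain_vectors()].
#' @param nuclei_density Fraction of nodule pixels seeded with a nucleus.
#' @return An `rgb_image`.
#' @export
synth_trichrome <- function(truth, scale = 2.7,
                            vectors = default_stain_vectors(),
                            nuclei_density = 0.04) {
  stopifnot(inherits(truth, "phantom_truth"))
  codes <- phantom_classes()
  H <- nrow(truth$class_map); W <- ncol(truth$class_map)
  cls <- as.vector(truth$class_map)
  conc <- matrix(0, H * W, 3,
                 dimnames = list(NULL, rownames(vectors$od)))
  fib <- cls %in% codes[c("fibrosis_a", "fibrosis_b")]
  nod <- cls == codes[["nodule"]]
  conc[fib, "collagen"] <- 0.9
  conc[nod, "cytoplasm"] <- 0.7
  withr::with_seed(derive_seed(truth$seed, "trichrome"), {
    nuc <- which(nod)[stats::runif(sum(nod)) < nuclei_density]
    conc[nuc, "nuclei"] <- 1.3
  })
  od <- conc %*% vectors$od                       # H*W x 3 optical densities
  px <- sweep(10^(-od), 2, vectors$I0, `*`) - 1   # invert OD = -log10((I+1)/I0)
  px <- pmin(pmax(px, 0), 255)
  rgb_image(array(round(px), c(H, W, 3)), scale = scale)
}
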