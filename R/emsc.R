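#' Build the paraffin interference basis
#'
#' Constructs the interference block of the EMSC model from a pure-paraffin
#' reference cube measured on the same slide: the first column is the mean
#' paraffin spectrum; the remaining columns are the leading principal
#' component loadings of the mean-centered paraffin spectra (unit norm,
#' deterministic sign: the largest-magnitude element is positive). The PCA
#' columns absorb pixel-to-pixel variability of the embedding medium.
#'
#' The mean column keeps the full measured paraffin shape (bands plus its
#' smooth component), so projecting the tissue reference orthogonal to the
#' interference subspace removes the complete contamination signature. The
#' PCA columns, in contrast, are computed from baseline-stripped residuals
#' (each paraffin spectrum projected orthogonal to the polynomial block
#' when `poly_degree >= 0`): baselines belong to the EMSC polynomial term,
#' and baseline-shaped interference columns would both collide with it and
#' eat the broad tissue envelope during the reference orthogonalization.
#'
#' @param paraffin A [spectral_image()] of pure paraffin.
#' @param n_components Total number of interference columns J (mean + J - 1
#'   principal components). Default 10.
#' @param poly_degree Degree of the baseline removed from the paraffin
#'   spectra before the PCA (negative to skip). The default 8 is
#'   deliberately higher than the EMSC baseline degree: the purer the
#'   band-only columns, the less the broad tissue envelope biases the
#'   reference orthogonalization.
#' @return B x J numeric matrix.
#' @export
build_paraffin_basis <- function(paraffin, n_components = 10, poly_degree = 8) {
  stopifnot(inherits(paraffin, "spectral_image"), n_components >= 1)
  X <- pixel_matrix(paraffin)            # N x B
  if (nrow(X) < n_components) {
    stop(sprintf("paraffin cube has %d valid pixels, fewer than n_components = %d",
                 nrow(X), n_components), call. = FALSE)
  }
  m <- colMeans(X)
  m_band <- m
  if (poly_degree >= 0) {
    Q <- qr.Q(qr(poly_basis(paraffin$axis, poly_degree)))
    X <- X - (X %*% Q) %*% t(Q)
    m_band <- as.numeric(m - Q %*% crossprod(Q, m))
  }
  P <- matrix(m, ncol = 1)
  P_band <- matrix(m_band, ncol = 1)
  if (n_components > 1) {
    Xc <- sweep(X, 2, colMeans(X))
    sv <- svd(Xc, nu = 0, nv = n_components - 1)
    nz <- sum(sv$d > max(sv$d) * 1e-10)
    if (n_components - 1 > nz) {
      stop(sprintf("requested %d PCA components but paraffin variation has rank %d",
                   n_components - 1, nz), call. = FALSE)
    }
    V <- sv$v[, seq_len(n_components - 1), drop = FALSE]
    V <- apply(V, 2, fix_sign)
    P <- cbind(P, V)
    P_band <- cbind(P_band, V)
  }
  colnames(P) <- c("paraffin_mean",
                   if (n_components > 1) paste0("paraffin_pc", seq_len(n_components - 1)))
  colnames(P_band) <- colnames(P)
  # baseline-free counterpart, used to estimate (not subtract) paraffin
  # coefficients of the tissue reference without envelope bias
  attr(P, "band_only") <- P_band
  P
}

# deterministic sign convention: element of largest magnitude is positive
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' Assemble an EMSC basis
#'
#' Bundles the model components of the extended multiplicative signal
#' correction: a reference spectrum `m`, the paraffin interference matrix
#' `P`, and a polynomial baseline block `T` of degree 0..D on the axis
#' rescaled to `[-1, 1]`.
#'
#' An optional tissue-heterogeneity block `H` extends the design: its
#' columns model legitimate biological variation around the reference
#' (e.g. the collagen-vs-glycogen contrast of heterogeneous tissue). They
#' are fitted alongside the nuisance terms but, unlike paraffin and
#' baseline, are *retained* by [apply_correction()], so the residual RMSE
#' measures genuinely unmodellable signal rather than tissue class
#' structure.
#'
#' @param reference B-vector reference spectrum (AU).
#' @param interference B x J matrix from [build_paraffin_basis()].
#' @param axis The [wavenumber_axis()] shared by all components.
#' @param poly_degree Baseline polynomial degree D (default 4).
#' @param tissue Optional B x K tissue-heterogeneity matrix (columns
#'   orthogonal to the rest of the design; see [tissue_subspace()]).
#' @return An `emsc_basis` object.
#' @export
emsc_basis <- function(reference, interference, axis, poly_degree = 4,
                       tissue = NULL) {
  if (!inherits(axis, "wavenumber_axis")) axis <- wavenumber_axis(axis)
  B <- length(axis)
  stopifnot(length(reference) == B, nrow(interference) == B, poly_degree >= 0)
  if (!is.null(tissue)) {
    tissue <- as.matrix(tissue)
    stopifnot(nrow(tissue) == B)
    if (ncol(tissue) == 0) tissue <- NULL
  }
  poly <- poly_basis(axis, poly_degree)
  structure(list(reference = as.numeric(reference),
                 interference = as.matrix(interference),
                 poly = poly, tissue = tissue, axis = axis),
            class = "emsc_basis")
}

#' Tissue-heterogeneity subspace for the extended EMSC design
#'
#' Principal directions of the (provisionally corrected) tissue spectra
#' after projecting out the reference, interference and baseline columns.
#' Including them in the EMSC design lets the model represent biological
#' variation between tissue classes, so the residual RMSE — and hence the
#' outlier rule — responds to unmodellable spectra (substrate, artifacts)
#' instead of flagging minority tissue classes wholesale.
#'
#' @param corrected A corrected [spectral_image()] (e.g. the provisional
#'   pass of [dewax()]).
#' @param basis The [emsc_basis()] used for the provisional correction.
#' @param n_tissue Maximum number of components K (default 5; limited by
#'   the numerical rank of the residual variation).
#' @return B x K matrix with orthonormal columns orthogonal to the design,
#'   or `NULL` when there is no residual variation.
#' @export
tissue_subspace <- function(corrected, basis, n_tissue = 5) {
  stopifnot(inherits(corrected, "spectral_image"), inherits(basis, "emsc_basis"))
  if (n_tissue < 1) return(NULL)
  X <- pixel_matrix(corrected)
  D <- cbind(basis$reference, basis$interference, basis$poly)
  Q <- qr.Q(qr(D))
  R <- X - (X %*% Q) %*% t(Q)
  sv <- svd(R, nu = 0, nv = min(n_tissue, ncol(R), nrow(R)))
  keep <- sv$d[seq_len(ncol(sv$v))] > max(sv$d) * 1e-8
  if (!any(keep)) return(NULL)
  V <- sv$v[, keep, drop = FALSE]
  apply(V, 2, fix_sign)
}

#' @export
print.emsc_basis <- function(x, ...) {
  cat(sprintf("<emsc_basis> %d bands, %d interference column(s), polynomial degree %d\n",
              length(x$reference), ncol(x$interference), ncol(x$poly) - 1))
  invisible(x)
}

#' Estimate the EMSC reference spectrum from the image itself
#'
#' Two-pass estimate of the tissue reference `m`: pass 1 takes the mean
#' valid spectrum; pass 2 fits the EMSC model against that provisional
#' reference, corrects every spectrum (removing paraffin and baseline), and
#' averages the corrected spectra. At both passes the estimate is
#' orthogonalized against the paraffin interference subspace — a reference
#' computed from a contaminated image necessarily contains paraffin, and
#' any paraffin content left in `m` would be retained (as `a * m`) instead
#' of removed by the correction. The returned reference is normalized to
#' unit mean absorbance over the fitting range.
#'
#' @param image A [spectral_image()] (already cropped to the analysis
#'   window).
#' @param interference B x J paraffin interference matrix.
#' @param poly_degree Baseline polynomial degree.
#' @return B-vector reference with `mean(m) == 1`.
#' @export
estimate_reference <- function(image, interference, poly_degree = 4) {
  stopifnot(inherits(image, "spectral_image"))
  X <- pixel_matrix(image)
  if (nrow(X) == 0) stop("image has no valid pixels", call. = FALSE)
  m0 <- project_out(colMeans(X), interference)
  m0 <- m0 / mean(m0)
  basis0 <- emsc_basis(m0, interference, image$axis, poly_degree)
  fit0 <- fit_emsc(image, basis0)
  corr0 <- apply_correction(image, fit0, basis0, drop_outliers = FALSE)
  m <- project_out(colMeans(pixel_matrix(corr0)), interference)
  m / mean(m)
}

# Remove the paraffin content of a tissue-mean spectrum. The coefficients
# are estimated against the baseline-free interference columns (orthogonal
# to the polynomial span, so the broad tissue envelope cannot bias them)
# and the subtraction uses the full columns, removing the contamination's
# smooth component along with its bands.
project_out <- function(v, P) {
  est <- attr(P, "band_only") %||% P
  gamma <- qr.coef(qr(est), v)
  gamma[is.na(gamma)] <- 0  # redundant columns carry no coefficient
  as.numeric(v - P %*% gamma)
}

#' Fit the EMSC model to every valid pixel
#'
#' Per-pixel ordinary least squares of the extended multiplicative signal
#' correction model `s = a * m + P b + T c + e`: a multiplicative scale `a`
#' on the reference spectrum, additive paraffin interference `P b`, and a
#' polynomial baseline `T c`. The design matrix `[m | P | T]` must be full
#' column rank. Outliers are flagged by [flag_outliers()] with the supplied
#' rule.
#'
#' @param image A [spectral_image()] whose axis equals the basis axis.
#' @param basis An [emsc_basis()].
#' @param a_bounds Admissible interval for the multiplicative coefficient
#'   at non-outlier pixels (default `c(0.2, 5)`).
#' @param kappa Robust residual rule: a pixel is an outlier when its RMSE
#'   exceeds `median(rmse) + kappa * mad(rmse)` (default 5).
#' @return An `emsc_fit`: H x W matrices `a`, `rmse`, `outlier`, arrays `b`
#'   (H x W x J) and `c` (H x W x (D+1)), plus the rule parameters.
#' @export
fit_emsc <- function(image, basis, a_bounds = c(0.2, 5), kappa = 5) {
  stopifnot(inherits(image, "spectral_image"), inherits(basis, "emsc_basis"))
  if (length(image$axis) != length(basis$axis) ||
      max(abs(as.numeric(image$axis) - as.numeric(basis$axis))) > 1e-9) {
    stop("image axis does not match basis axis", call. = FALSE)
  }
  X <- cbind(reference = basis$reference, basis$interference, basis$poly)
  K <- if (is.null(basis$tissue)) 0L else ncol(basis$tissue)
  if (K > 0) {
    tcols <- basis$tissue
    colnames(tcols) <- paste0("tissue", seq_len(K))
    X <- cbind(X, tcols)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(sprintf("EMSC design matrix is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  S <- t(pixel_matrix(image))                       # B x N
  if (ncol(S) == 0) stop("image has no valid pixels", call. = FALSE)
  coef <- qr.coef(qx, S)                            # p x N
  resid <- S - X %*% coef
  rmse_v <- sqrt(colMeans(resid^2))
  H <- nrow(image$mask); W <- ncol(image$mask)
  J <- ncol(basis$interference); D1 <- ncol(basis$poly)
  to_map <- function(v) {
    m <- matrix(NA_real_, H, W); m[image$mask] <- v; m
  }
  b_arr <- array(NA_real_, c(H, W, J))
  c_arr <- array(NA_real_, c(H, W, D1))
  for (j in seq_len(J)) b_arr[, , j] <- to_map(coef[1 + j, ])
  for (j in seq_len(D1)) c_arr[, , j] <- to_map(coef[1 + J + j, ])
  d_arr <- if (K > 0) {
    arr <- array(NA_real_, c(H, W, K))
    for (j in seq_len(K)) arr[, , j] <- to_map(coef[1 + J + D1 + j, ])
    arr
  }
  fit <- structure(list(a = to_map(coef[1, ]), b = b_arr, c = c_arr,
                        d = d_arr,
                        rmse = to_map(rmse_v),
                        outlier = matrix(FALSE, H, W),
                        mask = image$mask,
                        a_bounds = a_bounds, kappa = kappa),
                   class = "emsc_fit")
  flag_outliers(fit, a_bounds = a_bounds, kappa = kappa)
}

#' @export
print.emsc_fit <- function(x, ...) {
  v <- x$mask
  cat(sprintf("<emsc_fit> %d pixels, a in [%.3g, %.3g], median rmse %.3g AU, %d outlier(s)\n",
              sum(v), min(x$a[v]), max(x$a[v]), stats::median(x$rmse[v]),
              sum(x$outlier[v])))
  invisible(x)
}

#' Flag outlier pixels of an EMSC fit
#'
#' A pixel is an outlier when its multiplicative coefficient — taken
#' relative to the image median, `a / median(a)`, so the rule is invariant
#' to the overall absorbance scale as the correction itself is — falls
#' outside `a_bounds`, or when its residual RMSE exceeds
#' `median(rmse) + kappa * MAD(rmse)` over valid pixels. Larger `kappa`
#' flags fewer pixels (flags are monotone in `kappa`). This is the EMSC
#' quality gate that drops bare-substrate and otherwise unmodellable
#' spectra.
#'
#' @param fit An `emsc_fit`.
#' @param a_bounds Admissible interval for the relative coefficient
#'   `a / median(a)`.
#' @param kappa Robust multiplier of the MAD.
#' @return The fit with its `outlier` matrix (and rule parameters) updated.
#' @export
flag_outliers <- function(fit, a_bounds = fit$a_bounds, kappa = fit$kappa) {
  stopifnot(inherits(fit, "emsc_fit"), length(a_bounds) == 2, kappa >= 0)
  v <- fit$mask
  med <- stats::median(fit$rmse[v])
  mad <- stats::mad(fit$rmse[v])
  a_med <- stats::median(fit$a[v])
  a_rel <- fit$a[v] / a_med
  out <- matrix(FALSE, nrow(fit$a), ncol(fit$a))
  # tiny absolute slack so exactly-noise-free fits never self-flag
  out[v] <- a_rel < a_bounds[1] | a_rel > a_bounds[2] |
    fit$rmse[v] > med + kappa * mad + 1e-12
  fit$outlier <- out
  fit$a_bounds <- a_bounds
  fit$kappa <- kappa
  fit
}

#' Apply the EMSC correction (digital dewaxing)
#'
#' Corrected spectrum = `(s - P b - T c) / a`: paraffin interference and
#' baseline are subtracted, then the spectrum is normalized by its
#' multiplicative coefficient. Outlier pixels are removed from the mask of
#' the returned image.
#'
#' @param image The [spectral_image()] the fit was produced from.
#' @param fit The `emsc_fit` for this image and basis.
#' @param basis The [emsc_basis()] used in the fit.
#' @param drop_outliers Remove flagged pixels from the mask (default TRUE).
#' @return A corrected [spectral_image()].
#' @export
apply_correction <- function(image, fit, basis, drop_outliers = TRUE) {
  stopifnot(inherits(image, "spectral_image"), inherits(fit, "emsc_fit"),
            inherits(basis, "emsc_basis"))
  if (!identical(dim(fit$a), dim(image$mask))) {
    stop("fit dimensions do not match image", call. = FALSE)
  }
  v <- image$mask
  S <- t(pixel_matrix(image))                           # B x N
  J <- ncol(basis$interference); D1 <- ncol(basis$poly)
  bmat <- matrix(fit$b[rep(v, J)], ncol = J)            # N x J at valid pixels
  cmat <- matrix(fit$c[rep(v, D1)], ncol = D1)
  a <- fit$a[v]
  if (any(abs(a) < 1e-12 & !fit$outlier[v])) {
    stop("multiplicative coefficient numerically zero at a non-outlier pixel",
         call. = FALSE)
  }
  corr <- (S - basis$interference %*% t(bmat) - basis$poly %*% t(cmat))
  corr <- sweep(corr, 2, a, `/`)
  B <- length(basis$reference)
  cube <- unpixel_matrix(t(corr), v, B)
  mask <- v
  if (drop_outliers) mask <- v & !fit$outlier
  # blank non-finite leftovers at dropped pixels
  spectral_image(cube, basis$axis, pixel_size = image$pixel_size, mask = mask,
                 sample_id = image$sample_id, group = image$group)
}

#' Common EMSC correction across several images
#'
#' Builds one shared EMSC model — pooled paraffin interference basis,
#' pooled two-pass tissue reference, pooled tissue-heterogeneity subspace —
#' and corrects every image against it. Required whenever corrected images
#' are pooled downstream (common k-means): independently estimated
#' references would leave each image in its own corrected space and the
#' pooled clustering would segment images, not tissue.
#'
#' @param images List of tissue [spectral_image()]s sharing one axis.
#' @param paraffins List of pure-paraffin [spectral_image()]s, parallel to
#'   `images` (or a single image used for all).
#' @inheritParams dewax
#' @return List: `corrected` (list of corrected images), `fits` (list of
#'   `emsc_fit`), `basis` (the shared `emsc_basis`).
#' @export
dewax_common <- function(images, paraffins, range = c(1040, 1425),
                         n_components = 10, poly_degree = 4, n_tissue = 5,
                         a_bounds = c(0.2, 5), kappa = 5) {
  stopifnot(length(images) >= 1)
  if (inherits(paraffins, "spectral_image")) {
    paraffins <- rep(list(paraffins), length(images))
  }
  stopifnot(length(paraffins) == length(images))
  imgs <- lapply(images, crop_range, lo = range[1], hi = range[2])
  pars <- lapply(paraffins, crop_range, lo = range[1], hi = range[2])
  ax <- imgs[[1]]$axis
  pool <- function(lst) {
    X <- do.call(rbind, lapply(lst, pixel_matrix))
    spectral_image(array(X, c(nrow(X), 1, ncol(X))), ax,
                   sample_id = "pooled")
  }
  P <- build_paraffin_basis(pool(pars), n_components)
  pooled <- pool(imgs)
  m <- estimate_reference(pooled, P, poly_degree)
  basis <- emsc_basis(m, P, ax, poly_degree)
  if (n_tissue > 0) {
    fit0 <- fit_emsc(pooled, basis, a_bounds = a_bounds, kappa = kappa)
    corr0 <- apply_correction(pooled, fit0, basis, drop_outliers = FALSE)
    H <- tissue_subspace(corr0, basis, n_tissue)
    basis <- emsc_basis(m, P, ax, poly_degree, tissue = H)
  }
  fits <- lapply(imgs, fit_emsc, basis = basis,
                 a_bounds = a_bounds, kappa = kappa)
  corrected <- mapply(function(im, ft) apply_correction(im, ft, basis),
                      imgs, fits, SIMPLIFY = FALSE)
  list(corrected = corrected, fits = fits, basis = basis)
}

#' One-call EMSC digital dewaxing
#'
#' Convenience wrapper chaining the full correction: crop both cubes to the
#' analysis window, build the paraffin interference basis, estimate the
#' tissue reference (two-pass), run a provisional fit/correction to learn
#' the tissue-heterogeneity subspace, then fit the extended model and
#' apply the final correction.
#'
#' @param image Tissue [spectral_image()].
#' @param paraffin Pure-paraffin [spectral_image()] from the same slide.
#' @param range Analysis window `c(lo, hi)` in cm^-1; basis and fit are
#'   restricted to it (default `c(900, 1800)`).
#' @param n_components Interference columns J (default 10).
#' @param poly_degree Baseline degree D (default 4).
#' @param n_tissue Tissue-heterogeneity components K (default 5; 0 to
#'   disable), see [tissue_subspace()].
#' @param a_bounds,kappa Outlier rule, see [flag_outliers()].
#' @return List: `corrected` (a [spectral_image()]), `fit` (`emsc_fit`),
#'   `basis` (`emsc_basis`).
#' @export
dewax <- function(image, paraffin, range = c(900, 1800),
                  n_components = 10, poly_degree = 4, n_tissue = 5,
                  a_bounds = c(0.2, 5), kappa = 5) {
  img <- crop_range(image, range[1], range[2])
  par <- crop_range(paraffin, range[1], range[2])
  P <- build_paraffin_basis(par, n_components)
  m <- estimate_reference(img, P, poly_degree)
  basis <- emsc_basis(m, P, img$axis, poly_degree)
  if (n_tissue > 0) {
    fit0 <- fit_emsc(img, basis, a_bounds = a_bounds, kappa = kappa)
    corr0 <- apply_correction(img, fit0, basis, drop_outliers = FALSE)
    H <- tissue_subspace(corr0, basis, n_tissue)
    basis <- emsc_basis(m, P, img$axis, poly_degree, tissue = H)
  }
  fit <- fit_emsc(img, basis, a_bounds = a_bounds, kappa = kappa)
  list(corrected = apply_correction(img, fit, basis), fit = fit, basis = basis)
}
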