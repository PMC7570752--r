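ax_emsc <- wavenumber_axis(seq(1000, 1600, by = 2))

unit_ref <- function(axis = ax_emsc) {
  m <- synth_spectrum(default_endmembers()$glycogen_nodule, axis)
  m / mean(m)
}

test_that("paraffin basis: zero-variance cube gives the single mean column", {
  p <- synth_spectrum(default_endmembers()$paraffin, ax_emsc)
  cube <- array(rep(p, each = 9), c(3, 3, length(ax_emsc)))
  img <- spectral_image(cube, ax_emsc)
  P <- build_paraffin_basis(img, 1, poly_degree = -1)
  expect_equal(ncol(P), 1)
  expect_equal(as.numeric(P[, 1]), p)
  expect_error(build_paraffin_basis(img, 3, poly_degree = -1), "rank")
})

test_that("paraffin basis recovers planted variation modes (eigen oracle)", {
  p <- synth_spectrum(default_endmembers()$paraffin, ax_emsc)
  mode1 <- sin(seq(0, 2 * pi, length.out = length(ax_emsc)))
  mode2 <- cos(seq(0, 6 * pi, length.out = length(ax_emsc)))
  set.seed(1)
  N <- 50
  X <- outer(rep(1, N), p) + outer(rnorm(N, sd = 0.3), mode1) +
    outer(rnorm(N, sd = 0.1), mode2)
  img <- as_strip_image(X, ax_emsc)
  P <- build_paraffin_basis(img, 3, poly_degree = -1)
  # oracle: eigendecomposition of the covariance
  ev <- eigen(stats::cov(X), symmetric = TRUE)$vectors[, 1:2]
  angles <- svd(crossprod(qr.Q(qr(P[, 2:3])), qr.Q(qr(ev))))$d
  expect_true(all(acos(pmin(angles, 1)) < 1e-6))
  # deterministic sign: applying twice gives an identical matrix
  expect_identical(P, build_paraffin_basis(img, 3, poly_degree = -1))
  expect_true(all(vapply(2:3, function(j) {
    v <- P[, j]; v[which.max(abs(v))] > 0
  }, logical(1))))
  # loadings beyond the first column are mutually orthogonal
  expect_lt(abs(sum(P[, 2] * P[, 3])), 1e-10)
})

test_that("reference estimation: homogeneous cube returns the pixel spectrum", {
  mstar <- synth_spectrum(default_endmembers()$glycogen_nodule, ax_emsc)
  cube <- array(rep(mstar, each = 16), c(4, 4, length(ax_emsc)))
  img <- spectral_image(cube, ax_emsc)
  p <- synth_spectrum(default_endmembers()$paraffin, ax_emsc)
  pcube <- array(rep(p, each = 4), c(2, 2, length(ax_emsc)))
  P <- build_paraffin_basis(spectral_image(pcube, ax_emsc), 1)
  m <- estimate_reference(img, P, poly_degree = 2)
  expect_gt(sum(m * mstar) / sqrt(sum(m^2) * sum(mstar^2)), 0.9999)
  expect_equal(mean(m), 1, tolerance = 1e-9)
  msk <- matrix(FALSE, 4, 4)
  expect_error(estimate_reference(spectral_image(cube, ax_emsc, mask = msk), P),
               "valid pixels")
})

test_that("reference estimation beats the raw mean under varying paraffin", {
  mstar <- synth_spectrum(default_endmembers()$glycogen_nodule, ax_emsc)
  p <- synth_spectrum(default_endmembers()$paraffin, ax_emsc)
  set.seed(2)
  N <- 64
  amps <- runif(N, 0.2, 0.8)
  X <- outer(rep(1, N), mstar) + outer(amps, p)
  img <- as_strip_image(X, ax_emsc)
  # paraffin basis from a slightly varying paraffin cube (scale mode only,
  # so exactly one principal component exists after baseline stripping)
  Xp <- outer(1 + rnorm(N, sd = 0.05), p)
  P <- build_paraffin_basis(as_strip_image(Xp, ax_emsc), 2)
  m <- estimate_reference(img, P, poly_degree = 4)
  cosim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_gt(cosim(m, mstar), cosim(colMeans(X), mstar))
  expect_gt(cosim(m, mstar), 0.999)
})

test_that("EMSC fit recovers planted coefficients exactly", {
  m <- unit_ref()
  p1 <- synth_spectrum(default_endmembers()$paraffin, ax_emsc)
  basis <- emsc_basis(m, matrix(p1, ncol = 1), ax_emsc, poly_degree = 2)
  # identity case
  img1 <- as_strip_image(rbind(m, m), ax_emsc)
  fit1 <- fit_emsc(img1, basis)
  expect_equal(fit1$a[1, 1], 1, tolerance = 1e-10)
  expect_lt(max(abs(fit1$b[1, 1, ])), 1e-10)
  expect_lt(max(abs(fit1$c[1, 1, ])), 1e-10)
  expect_lt(fit1$rmse[1, 1], 1e-10)
  # planted mixture
  s <- 2 * m + 0.5 * p1 + 0.1
  fit2 <- fit_emsc(as_strip_image(rbind(s, s), ax_emsc), basis)
  expect_equal(fit2$a[1, 1], 2, tolerance = 1e-8)
  expect_equal(fit2$b[1, 1, 1], 0.5, tolerance = 1e-8)
  expect_equal(fit2$c[1, 1, 1], 0.1, tolerance = 1e-8)
  # axis mismatch and rank deficiency are reported
  other <- wavenumber_axis(seq(1000, 1598, by = 2))
  expect_error(fit_emsc(as_strip_image(rbind(m[-1]), other), basis), "axis")
  bad <- emsc_basis(m, cbind(p1, rep(1, length(m))), ax_emsc, poly_degree = 2)
  expect_error(fit_emsc(img1, bad), "rank deficient")
})

test_that("EMSC rmse estimates the noise level (Monte Carlo)", {
  axb <- wavenumber_axis(seq(1000, 1798, by = 2))  # 400 bands
  m <- synth_spectrum(default_endmembers()$glycogen_nodule, axb)
  m <- m / mean(m)
  p1 <- synth_spectrum(default_endmembers()$paraffin, axb)
  basis <- emsc_basis(m, matrix(p1, ncol = 1), axb, poly_degree = 2)
  sigma <- 0.02
  set.seed(3)
  X <- outer(rep(1, 100), m) + matrix(rnorm(100 * length(m), sd = sigma), 100)
  fit <- fit_emsc(as_strip_image(X, axb), basis)
  expect_lt(abs(mean(fit$rmse[fit$mask]) - sigma) / sigma, 0.1)
})

test_that("correction inverts the model and is idempotent", {
  m <- unit_ref()
  p1 <- synth_spectrum(default_endmembers()$paraffin, ax_emsc)
  basis <- emsc_basis(m, matrix(p1, ncol = 1), ax_emsc, poly_degree = 2)
  s <- 2 * m + 0.5 * p1 + 0.1
  img <- as_strip_image(rbind(s, m), ax_emsc)
  fit <- fit_emsc(img, basis)
  corr <- apply_correction(img, fit, basis)
  expect_lt(max(abs(corr$cube[1, 1, ] - m)), 1e-8)
  expect_lt(max(abs(corr$cube[2, 1, ] - m)), 1e-10)
  refit <- fit_emsc(corr, basis)
  expect_lt(max(abs(refit$a[corr$mask] - 1)), 1e-6)
  expect_lt(max(abs(refit$b[, , 1][corr$mask])), 1e-6)
})

test_that("correction is equivariant to a global intensity scale", {
  ph <- tiny_phantom(seed = 4, H = 12, W = 12)
  dw1 <- dewax(ph$tissue, ph$paraffin, range = c(1000, 1600))
  scaled <- ph$tissue
  scaled$cube <- scaled$cube * 3
  dw2 <- dewax(scaled, ph$paraffin, range = c(1000, 1600))
  expect_equal(dw2$fit$a[dw2$fit$mask], 3 * dw1$fit$a[dw1$fit$mask],
               tolerance = 1e-6)
  expect_identical(dw2$fit$outlier, dw1$fit$outlier)
  expect_equal(dw2$corrected$cube[dw2$corrected$mask],
               dw1$corrected$cube[dw1$corrected$mask], tolerance = 1e-6)
})

test_that("outlier rule flags planted substrate pixels and is monotone in kappa", {
  ph <- tiny_phantom(seed = 6, H = 12, W = 12)
  # replace one tissue pixel with a flat near-zero spectrum (bare substrate)
  idx <- which(ph$tissue$mask, arr.ind = TRUE)[5, ]
  ph$tissue$cube[idx[1], idx[2], ] <- 1e-4
  dw <- dewax(ph$tissue, ph$paraffin, range = c(1000, 1600))
  expect_true(dw$fit$outlier[idx[1], idx[2]])
  expect_equal(sum(dw$fit$outlier), 1)
  # monotone: flags at kappa = 3 contain flags at kappa = 5
  f3 <- flag_outliers(dw$fit, kappa = 3)
  f5 <- flag_outliers(dw$fit, kappa = 5)
  expect_true(all(f3$outlier[f5$outlier]))
  # homogeneous noise-free cube: zero outliers
  m <- unit_ref()
  basis <- emsc_basis(m, matrix(synth_spectrum(default_endmembers()$paraffin,
                                               ax_emsc), ncol = 1),
                      ax_emsc, poly_degree = 2)
  fit <- fit_emsc(as_strip_image(rbind(m, m, m, m), ax_emsc), basis)
  expect_equal(sum(fit$outlier), 0)
})

test_that("dewax suppresses paraffin at its band centers", {
  cfg1 <- phantom_config(H = 24, W = 24, seed = 8, paraffin_amp_range = c(0.5, 0.5))
  cfg0 <- phantom_config(H = 24, W = 24, seed = 8, paraffin_amp_range = c(0, 0))
  tr <- synth_label_map(cfg1)
  contam <- synth_cube(tr, config = cfg1)
  free <- synth_cube(synth_label_map(cfg0), config = cfg0)$tissue
  dwc <- dewax(contam$tissue, contam$paraffin)
  dwf <- dewax(free, contam$paraffin)
  nu <- as.numeric(dwc$corrected$axis)
  bidx <- vapply(c(1378, 1462), function(b) which.min(abs(nu - b)), integer(1))
  band_mean <- function(img) {
    X <- tidy_pixels(img)
    mean(X[, bidx])
  }
  tidy_pixels <- function(img) spectrofibro:::pixel_matrix(img)
  norm_mean <- function(img) {
    X <- spectrofibro:::pixel_matrix(crop_range(img, 900, 1800))
    X <- X / rowMeans(X)
    mean(X[, bidx])
  }
  excess_before <- norm_mean(contam$tissue) - norm_mean(free)
  excess_after <- band_mean(dwc$corrected) - band_mean(dwf$corrected)
  expect_lt(abs(excess_after), 0.05 * abs(excess_before))
})
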