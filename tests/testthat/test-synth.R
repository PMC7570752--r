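test_that("endmember spectra follow the Gaussian band model", {
  ax <- wavenumber_axis(seq(1000, 1100, by = 1))
  em <- endmember("test", band_spec(1045, 10, 1))
  s <- synth_spectrum(em, ax)
  expect_equal(s[ax == 1045], 1)
  expect_equal(s[ax == 1055], exp(-0.5))
  expect_equal(s[ax == 1035], exp(-0.5))
  expect_true(all(s >= 0))
  # additivity over bands
  em2 <- endmember("two", dplyr::bind_rows(band_spec(1020, 5, 0.3),
                                           band_spec(1080, 5, 0.7)))
  s2 <- synth_spectrum(em2, ax)
  expect_equal(s2, 0.3 * exp(-(as.numeric(ax) - 1020)^2 / 50) +
                   0.7 * exp(-(as.numeric(ax) - 1080)^2 / 50))
  expect_error(band_spec(1000, -1, 1), "width")
  expect_error(band_spec(1000, 1, -1), "amplitude")
})

test_that("default glycogen endmember peaks at its band centers", {
  ax <- wavenumber_axis(seq(900, 1800, by = 2))
  s <- synth_spectrum(default_endmembers()$glycogen_nodule, ax)
  nu <- as.numeric(ax)
  for (center in c(1022, 1045, 1080, 1155)) {
    w <- which(abs(nu - center) <= 6)
    i <- w[which.max(s[w])]
    expect_lte(abs(nu[i] - center), 2)
  }
})

test_that("label maps hit the target fraction and are reproducible", {
  cfg <- phantom_config(H = 32, W = 32, target_fibrosis = 30, seed = 1)
  tr <- synth_label_map(cfg)
  expect_gte(tr$fibrosis_fraction, 29)
  expect_lte(tr$fibrosis_fraction, 31)
  expect_identical(tr$class_map, synth_label_map(cfg)$class_map)
  # stored fraction always recomputable from the class map
  expect_equal(tr$fibrosis_fraction, true_fibrosis_fraction(tr), tolerance = 1e-12)
  # achieved fraction is monotone in the target
  achieved <- vapply(c(5, 15, 25, 35, 45), function(t) {
    synth_label_map(phantom_config(H = 32, W = 32, target_fibrosis = t,
                                   seed = 2))$fibrosis_fraction
  }, numeric(1))
  expect_true(all(diff(achieved) > 0))
  # abundance weights are one-hot and non-negative
  tot <- Reduce(`+`, tr$abundance)
  expect_true(all(tot == 1))
})

test_that("degenerate config reproduces endmembers exactly and seeds are exact", {
  ph <- clean_phantom(seed = 3)
  ax <- ph$tissue$axis
  em <- default_endmembers()
  specs <- list(synth_spectrum(em$glycogen_nodule, ax),
                synth_spectrum(em$collagen_a, ax),
                synth_spectrum(em$collagen_b, ax))
  for (cl in 1:3) {
    idx <- which(ph$truth$class_map == cl, arr.ind = TRUE)[1, ]
    expect_equal(ph$tissue$cube[idx[1], idx[2], ], specs[[cl]], tolerance = 1e-12)
  }
  # determinism of the full cube
  again <- synth_cube(ph$truth, config = ph$cfg)
  expect_identical(again$tissue$cube, ph$tissue$cube)
  expect_identical(again$paraffin$cube, ph$paraffin$cube)
})

test_that("paraffin contamination raises absorbance at paraffin bands", {
  cfg1 <- phantom_config(H = 16, W = 16, seed = 5, paraffin_amp_range = c(0.5, 0.5))
  cfg0 <- phantom_config(H = 16, W = 16, seed = 5, paraffin_amp_range = c(0, 0))
  tr <- synth_label_map(cfg1)
  with_par <- synth_cube(tr, config = cfg1)$tissue
  without <- synth_cube(synth_label_map(cfg0), config = cfg0)$tissue
  nu <- as.numeric(with_par$axis)
  bidx <- vapply(c(1378, 1462), function(b) which.min(abs(nu - b)), integer(1))
  expect_gt(mean(with_par$cube[, , bidx]), mean(without$cube[, , bidx]))
})

test_that("noise and contamination vanish in the degenerate limit", {
  cfg <- phantom_config(H = 12, W = 12, seed = 9, tissue_fraction = 1)
  tr <- synth_label_map(cfg)
  sds <- c(0.02, 0.005, 0.001, 0)
  devs <- vapply(sds, function(sd) {
    c2 <- phantom_config(H = 12, W = 12, seed = 9, tissue_fraction = 1,
                         noise_sd = sd, paraffin_amp_range = c(0, 0),
                         baseline_coef_range = c(0, 0), scatter_range = c(1, 1))
    cb <- synth_cube(tr, config = c2)$tissue
    em <- default_endmembers()
    specs <- list(synth_spectrum(em$glycogen_nodule, cb$axis),
                  synth_spectrum(em$collagen_a, cb$axis),
                  synth_spectrum(em$collagen_b, cb$axis))
    mx <- 0
    for (cl in 1:3) {
      px <- which(tr$class_map == cl)
      if (!length(px)) next
      flat <- matrix(cb$cube, 144, length(cb$axis))
      mx <- max(mx, max(abs(sweep(flat[px, , drop = FALSE], 2, specs[[cl]]))))
    }
    mx
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_equal(devs[length(devs)], 0, tolerance = 1e-12)
})

test_that("trichrome rendering matches the stain model it claims", {
  ph <- tiny_phantom(seed = 13, H = 32, W = 32, target = 25)
  tri <- synth_trichrome(ph$truth)
  # background near-white
  bg <- which(ph$truth$class_map == 0, arr.ind = TRUE)[1, ]
  expect_true(all(abs(unclass(tri)[bg[1], bg[2], ] - 255) <= 3))
  # rendering inverts through the DIA pipeline
  pct <- fibrosis_percent_dia(segment_fibrosis(tri))
  expect_lt(abs(pct - ph$truth$fibrosis_fraction), 2)
  # determinism
  expect_identical(unclass(synth_trichrome(ph$truth))[],
                   unclass(tri)[])
})

test_that("an all-nodule truth yields near-zero DIA fibrosis", {
  cfg <- phantom_config(H = 24, W = 24, target_fibrosis = 30, seed = 17)
  tr <- synth_label_map(cfg)
  tr$class_map[tr$class_map %in% c(2L, 3L)] <- 1L
  tr <- spectrofibro:::new_phantom_truth(tr$class_map, tr$seed)
  tri <- synth_trichrome(tr)
  pct <- fibrosis_percent_dia(segment_fibrosis(tri))
  expect_lt(pct, 2)
})
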