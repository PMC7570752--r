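ax_cl <- wavenumber_axis(seq(1000, 1398, by = 2))

two_pop_image <- function(n1 = 40, n2 = 20, sd = 0.01, seed = 1) {
  em <- default_endmembers()
  g <- synth_spectrum(em$glycogen_nodule, ax_cl)
  c1 <- synth_spectrum(em$collagen_a, ax_cl)
  withr::with_seed(seed, {
    X <- rbind(outer(rep(1, n1), g), outer(rep(1, n2), c1)) +
      matrix(rnorm((n1 + n2) * length(ax_cl), sd = sd), n1 + n2)
  })
  list(img = as_strip_image(X, ax_cl), truth = rep(1:2, c(n1, n2)), X = X)
}

test_that("k = 1 returns the mean spectrum and full coverage", {
  tp <- two_pop_image()
  res <- fit_kmeans(tp$img, 1, seed = 0)
  expect_equal(res$model$sizes, 60)
  expect_equal(as.numeric(res$model$centroids[1, ]), colMeans(tp$X))
  expect_true(all(res$labels$labels == 0))
  expect_error(fit_kmeans(tp$img, 100, seed = 0), "exceeds")
})

test_that("well-separated populations are recovered perfectly (ARI = 1)", {
  skip_if_not_installed("mclust")
  tp <- two_pop_image()
  res <- fit_kmeans(tp$img, 2, seed = 0)
  lab <- res$labels$labels[res$labels$labels >= 0]
  expect_equal(mclust::adjustedRandIndex(lab, tp$truth), 1)
  # centroids equal the class means of their assignments
  for (i in 0:1) {
    expect_equal(as.numeric(res$model$centroids[i + 1, ]),
                 colMeans(tp$X[lab == i, , drop = FALSE]), tolerance = 1e-8)
  }
})

test_that("small-instance inertia equals the exhaustive bipartition optimum", {
  for (seed in 1:3) {
    tp <- two_pop_image(n1 = 7, n2 = 5, sd = 0.05, seed = seed)
    res <- fit_kmeans(tp$img, 2, seed = seed)
    expect_equal(res$model$inertia, exhaustive_two_means(tp$X),
                 tolerance = 1e-8)
  }
})

test_that("inertia agrees with an independent k-means engine", {
  tp <- two_pop_image(sd = 0.02)
  res <- fit_kmeans(tp$img, 2, seed = 0)
  ref <- stats::kmeans(tp$X, centers = 2, nstart = 10)
  expect_equal(res$model$inertia, ref$tot.withinss, tolerance = 1e-6)
})

test_that("k-means is deterministic given the seed", {
  tp <- two_pop_image()
  r1 <- fit_kmeans(tp$img, 3, seed = 7)
  r2 <- fit_kmeans(tp$img, 3, seed = 7)
  expect_identical(r1$model$centroids, r2$model$centroids)
  expect_identical(r1$labels$labels, r2$labels$labels)
  # random-spectra initialization also works and is seeded
  r3 <- fit_kmeans(tp$img, 2, seed = 7, init = "random_spectra")
  expect_identical(r3$model$centroids,
                   fit_kmeans(tp$img, 2, seed = 7,
                              init = "random_spectra")$model$centroids)
})

test_that("common k-means on one image reduces to per-image k-means", {
  tp <- two_pop_image()
  single <- fit_kmeans(tp$img, 2, seed = 0)
  common <- fit_common_kmeans(list(tp$img), 2, seed = 0)
  expect_equal(common$model$centroids, single$model$centroids)
  expect_identical(common$labels[[1]]$labels, single$labels$labels)
})

test_that("common k-means shares classes and conserves pixels", {
  tpa <- two_pop_image(seed = 2)
  tpb <- two_pop_image(n1 = 10, n2 = 35, seed = 3)
  res <- fit_common_kmeans(list(tpa$img, tpb$img), 2, seed = 0)
  expect_length(res$labels, 2)
  pooled_counts <- res$model$sizes
  per_image <- vapply(0:1, function(i) {
    sum(res$labels[[1]]$labels == i) + sum(res$labels[[2]]$labels == i)
  }, numeric(1))
  expect_equal(per_image, pooled_counts)
  # permuting the pooling order leaves canonical centroids unchanged
  perm <- fit_common_kmeans(list(tpb$img, tpa$img), 2, seed = 0)
  expect_equal(perm$model$centroids, res$model$centroids, tolerance = 1e-8)
  # axis mismatch is an alignment error
  other <- as_strip_image(tpb$X[, -1], wavenumber_axis(seq(1002, 1398, 2)))
  expect_error(fit_common_kmeans(list(tpa$img, other), 2, seed = 0), "axis")
})

test_that("annotation maps centroids to tissue labels by template correlation", {
  em <- default_endmembers()
  tmpl <- annotation_templates(ax_cl)
  centroids <- rbind(synth_spectrum(em$collagen_a, ax_cl),
                     synth_spectrum(em$glycogen_nodule, ax_cl) +
                       rnorm(length(ax_cl), sd = 0.005))
  model <- structure(list(k = 2, centroids = centroids, axis = ax_cl,
                          seed = 0L, inertia = 0, sizes = c(1, 1),
                          colors = c("#000000", "#FFFFFF")),
                     class = "kmeans_model")
  ann <- annotate_clusters(model, tmpl)
  expect_equal(unname(ann["0"]), "fibrosis")
  expect_equal(unname(ann["1"]), "nodule")
  # manual mapping wins verbatim
  man <- annotate_clusters(model, tmpl,
                           manual = c("0" = "nodule", "1" = "fibrosis"))
  expect_equal(unname(man["0"]), "nodule")
  # identical templates tie -> ambiguous annotation error
  expect_error(annotate_clusters(model, list(fibrosis = tmpl$nodule,
                                             nodule = tmpl$nodule)),
               "ambiguous|tie")
})

test_that("area percentages are conserved and recover planted fractions", {
  lab <- structure(list(labels = matrix(c(0L, 0L, 1L, -1L), 2, 2), k = 2,
                        sample_id = "x"), class = "label_image")
  ann <- structure(c("0" = "fibrosis", "1" = "nodule"),
                   class = "cluster_annotation")
  expect_equal(area_percent(lab, ann, "fibrosis") +
                 area_percent(lab, ann, "nodule") +
                 area_percent(lab, ann, "other"), 100, tolerance = 1e-9)
  all_fib <- structure(list(labels = matrix(0L, 2, 2), k = 1,
                            sample_id = "x"), class = "label_image")
  ann1 <- structure(c("0" = "fibrosis"), class = "cluster_annotation")
  expect_equal(area_percent(all_fib, ann1, "fibrosis"), 100)
  # planted truth recovered through the full chain
  ph <- tiny_phantom(seed = 10, H = 32, W = 32, target = 30, noise_sd = 0.02)
  dw <- dewax(ph$tissue, ph$paraffin)
  km <- fit_kmeans(dw$corrected, 3, seed = 0)
  ann3 <- annotate_clusters(km$model, annotation_templates(dw$corrected$axis),
                           basis = dw$basis)
  expect_lt(abs(area_percent(km$labels, ann3, "fibrosis") -
                  ph$truth$fibrosis_fraction), 2)
})

test_that("fibrosis stays within two classes while nodules subdivide", {
  ph <- tiny_phantom(seed = 11, H = 32, W = 32, target = 30)
  dw <- dewax(ph$tissue, ph$paraffin)
  tmpl <- annotation_templates(dw$corrected$axis)
  truth_fib <- ph$truth$class_map %in% c(2L, 3L)
  for (k in 2:5) {
    km <- fit_kmeans(dw$corrected, k, seed = 0)
    lab <- km$labels$labels
    fib_classes <- unique(lab[truth_fib & lab >= 0])
    # classes covering >= 5% of fibrosis pixels
    major <- fib_classes[vapply(fib_classes, function(cl) {
      mean(lab[truth_fib] == cl) >= 0.05
    }, logical(1))]
    expect_lte(length(major), 2)
  }
})
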