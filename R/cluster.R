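#' Per-image k-means clustering of a spectral image
#'
#' Partitions the valid-pixel spectra of a (corrected) spectral image into
#' `k` classes by Lloyd's algorithm with Euclidean distance: each spectrum
#' is allocated to the nearest centroid, centroids are recomputed as class
#' mean spectra, and the loop repeats until the relative inertia change
#' drops below `tol` or `max_iter` iterations. The best of `n_init`
#' seeded restarts (lowest inertia) is kept. After the fit, classes are
#' relabeled in canonical order (descending size) so ids are stable across
#' seeds and pooling orders, and each class gets a fixed pseudo-color.
#'
#' @param image A [spectral_image()] (typically EMSC-corrected and cropped
#'   to the analysis window).
#' @param k Number of classes (>= 1; at most the number of valid pixels).
#' @param seed Integer seed driving all initializations.
#' @param n_init Number of restarts (default 10).
#' @param init `"kmeanspp"` (default) or `"random_spectra"`, which
#'   reproduces the classical choice of k random spectra as the starting
#'   centroids.
#' @param tol Relative inertia change declaring convergence (default 1e-6).
#' @param max_iter Iteration cap per restart (default 300).
#' @return List with `model` (a `kmeans_model`: `k`, `centroids` k x B,
#'   `axis`, `inertia`, `sizes`, `colors`, `seed`) and `labels` (a
#'   `label_image`: H x W integer matrix with classes `0..k-1` and `-1` at
#'   masked pixels).
#' @export
fit_kmeans <- function(image, k, seed = 0L, n_init = 10,
                       init = c("kmeanspp", "random_spectra"),
                       tol = 1e-6, max_iter = 300) {
  stopifnot(inherits(image, "spectral_image"), k >= 1)
  init <- match.arg(init)
  X <- pixel_matrix(image)
  if (nrow(X) < k) {
    stop(sprintf("k = %d exceeds the %d valid pixels", k, nrow(X)), call. = FALSE)
  }
  res <- kmeans_core(X, k, seed = seed, n_init = n_init, init = init,
                     tol = tol, max_iter = max_iter)
  out <- build_kmeans_result(res, list(image), image$axis, k, seed)
  list(model = out$model, labels = out$labels[[1]])
}

#' Common k-means over several spectral images
#'
#' Fits one centroid set on the pooled valid-pixel spectra of all images,
#' then labels every image against it, so class identities (and colors)
#' are directly comparable across samples. This is the multi-image
#' clustering used to compare fibrosis composition between patient groups.
#'
#' @param images List of [spectral_image()]s sharing one wavenumber axis.
#' @inheritParams fit_kmeans
#' @return List with `model` (one `kmeans_model`) and `labels` (list of
#'   `label_image`s, one per input image, sharing class ids and colors).
#' @export
fit_common_kmeans <- function(images, k, seed = 0L, n_init = 10,
                              init = c("kmeanspp", "random_spectra"),
                              tol = 1e-6, max_iter = 300) {
  stopifnot(length(images) >= 1, k >= 1)
  init <- match.arg(init)
  ax <- images[[1]]$axis
  for (im in images) {
    if (length(im$axis) != length(ax) ||
        max(abs(as.numeric(im$axis) - as.numeric(ax))) > 1e-9) {
      stop("all images must share one wavenumber axis", call. = FALSE)
    }
  }
  X <- do.call(rbind, lapply(images, pixel_matrix))
  if (nrow(X) < k) {
    stop(sprintf("k = %d exceeds the %d pooled valid pixels", k, nrow(X)),
         call. = FALSE)
  }
  res <- kmeans_core(X, k, seed = seed, n_init = n_init, init = init,
                     tol = tol, max_iter = max_iter)
  build_kmeans_result(res, images, ax, k, seed)
}

# shared post-processing: canonical ordering, colors, per-image label maps
build_kmeans_result <- function(res, images, axis, k, seed) {
  ord <- order(-tabulate(res$cluster, nbins = k))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  cl <- relabel[res$cluster]
  centroids <- res$centroids[ord, , drop = FALSE]
  dimnames(centroids) <- NULL
  sizes <- tabulate(cl, nbins = k)
  model <- structure(
    list(k = k, centroids = centroids, axis = axis, seed = as.integer(seed),
         inertia = res$inertia, sizes = sizes, colors = class_palette(k)),
    class = "kmeans_model")
  labels <- vector("list", length(images))
  off <- 0L
  for (i in seq_along(images)) {
    msk <- images[[i]]$mask
    n <- sum(msk)
    lab <- matrix(-1L, nrow(msk), ncol(msk))
    lab[msk] <- cl[(off + 1L):(off + n)] - 1L
    off <- off + n
    labels[[i]] <- structure(list(labels = lab, k = k,
                                  sample_id = images[[i]]$sample_id),
                             class = "label_image")
  }
  list(model = model, labels = labels)
}

# fixed palette by class id (reproducible pseudo-colors; id 1 = largest class)
class_palette <- function(k) {
  pal <- c("#00008B", "#FF0000", "#00CD00", "#ADD8E6", "#FF00FF",
           "#FFA500", "#00CED1", "#8B4513")
  rep_len(pal, k)
}

# Lloyd's algorithm with k-means++ / random-spectra init, best of n_init.
# Tie-break on equidistant centroids: lowest class id. Empty cluster:
# reseed to the point farthest from its centroid.
kmeans_core <- function(X, k, seed, n_init, init, tol, max_iter) {
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_init)) {
      C <- if (init == "kmeanspp") init_kmeanspp(X, k) else
        X[sample.int(nrow(X), k), , drop = FALSE]
      run <- lloyd(X, C, tol, max_iter)
      if (is.null(best) || run$inertia < best$inertia) best <- run
    }
  })
  best
}

init_kmeanspp <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[idx[1], ])^2)
  if (k > 1) for (j in 2:k) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) {
      idx[j] <- sample.int(n, 1)
    } else {
      idx[j] <- sample.int(n, 1, prob = p)
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[j], ])^2))
  }
  X[idx, , drop = FALSE]
}

lloyd <- function(X, C, tol, max_iter) {
  n <- nrow(X); k <- nrow(C)
  xs <- rowSums(X^2)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    D <- outer(xs, rowSums(C^2), `+`) - 2 * X %*% t(C)
    cl <- max.col(-D, ties.method = "first")
    # handle empty clusters: reseed to the farthest point from its centroid
    sizes <- tabulate(cl, nbins = k)
    while (any(sizes == 0)) {
      dmin <- D[cbind(seq_len(n), cl)]
      far <- which.max(dmin)
      empty <- which(sizes == 0)[1]
      cl[far] <- empty
      sizes <- tabulate(cl, nbins = k)
    }
    C <- rowsum(X, cl) / sizes
    D <- outer(xs, rowSums(C^2), `+`) - 2 * X %*% t(C)
    cl <- max.col(-D, ties.method = "first")
    inertia <- sum(pmax(D[cbind(seq_len(n), cl)], 0))
    if (is.finite(prev) && prev - inertia <= tol * max(inertia, .Machine$double.eps)) break
    prev <- inertia
  }
  list(cluster = cl, centroids = C, inertia = inertia, iterations = it)
}

#' @export
print.kmeans_model <- function(x, ...) {
  cat(sprintf("<kmeans_model> k = %d, %d bands, inertia %.6g, sizes: %s\n",
              x$k, ncol(x$centroids), x$inertia, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("<label_image> '%s': %d x %d, %d classes, %d labeled pixels\n",
              x$sample_id, nrow(x$labels), ncol(x$labels), x$k,
              sum(x$labels >= 0)))
  invisible(x)
}

#' Annotate spectral classes with tissue labels
#'
#' Maps each k-means class to a tissue label (`"fibrosis"`, `"nodule"`, or
#' `"other"`). A manual mapping — the analyst's reading of the adjacent
#' stained section — wins when supplied. Otherwise each centroid receives
#' the label of the template spectrum with the highest Pearson correlation
#' over the analysis range.
#'
#' Corrected spectra live in the geometry of the EMSC model — their
#' baseline-span and interference-span components are removed and their
#' reference-direction component is absorbed into the scale. Raw template
#' spectra do not, so the comparison must be made in a common space. When
#' the `basis` used for the correction is supplied, each template is
#' passed through the same correction a pixel would receive (fit against
#' the design, subtract interference and baseline, divide by the scale),
#' which is the exact counterpart. Otherwise both sides are detrended by
#' a common polynomial (degree `detrend_degree`) so the comparison rests
#' on band structure.
#'
#' @param model A `kmeans_model`.
#' @param templates Named list of reference spectra on the model axis
#'   (names are tissue labels; must cover `fibrosis` and `nodule`).
#'   See [annotation_templates()].
#' @param manual Optional named mapping, e.g. `c("0" = "fibrosis",
#'   "1" = "nodule")`; class ids as names.
#' @param detrend_degree Polynomial degree removed from centroids and
#'   templates before correlating when no `basis` is given (default 4;
#'   negative to disable).
#' @param basis Optional [emsc_basis()] the clustered image was corrected
#'   with; when supplied, templates are mapped through the same correction
#'   instead of detrended.
#' @return A `cluster_annotation`: named character vector, one tissue label
#'   per class id `0..k-1`.
#' @export
annotate_clusters <- function(model, templates = NULL, manual = NULL,
                              detrend_degree = 4, basis = NULL) {
  stopifnot(inherits(model, "kmeans_model"))
  ids <- as.character(0:(model$k - 1))
  if (!is.null(manual)) {
    if (!all(ids %in% names(manual))) {
      stop("manual mapping must cover every class id", call. = FALSE)
    }
    ann <- as.character(manual[ids])
  } else {
    if (is.null(templates) || !all(c("fibrosis", "nodule") %in% names(templates))) {
      stop("templates must cover 'fibrosis' and 'nodule' (or supply a manual mapping)",
           call. = FALSE)
    }
    if (!is.null(basis)) {
      templates <- lapply(templates, correct_template, basis = basis)
      detrend <- identity
    } else {
      detrend <- if (detrend_degree >= 0) {
        Q <- qr.Q(qr(poly_basis(model$axis, detrend_degree)))
        function(y) as.numeric(y - Q %*% crossprod(Q, y))
      } else identity
      templates <- lapply(templates, detrend)
    }
    ann <- character(model$k)
    for (i in seq_len(model$k)) {
      cen <- detrend(model$centroids[i, ])
      r <- vapply(templates, function(t) stats::cor(cen, t), numeric(1))
      top <- sort(r, decreasing = TRUE)
      if (length(top) > 1 && top[1] - top[2] < 1e-12) {
        stop(sprintf("ambiguous annotation for class %d (correlation tie); supply a manual mapping",
                     i - 1), call. = FALSE)
      }
      ann[i] <- names(which.max(r))
    }
  }
  structure(stats::setNames(ann, ids), class = "cluster_annotation")
}

# Map a raw template spectrum through the EMSC correction a pixel would
# receive: fit against [m | P | T | H], subtract interference and baseline,
# divide by the fitted scale.
correct_template <- function(t, basis) {
  X <- cbind(basis$reference, basis$interference, basis$poly, basis$tissue)
  coef <- qr.coef(qr(X), t)
  coef[is.na(coef)] <- 0
  J <- ncol(basis$interference); D1 <- ncol(basis$poly)
  a <- coef[1]
  if (abs(a) < 1e-8) {
    stop("template has no component along the EMSC reference", call. = FALSE)
  }
  as.numeric((t - basis$interference %*% coef[1 + seq_len(J)] -
                basis$poly %*% coef[1 + J + seq_len(D1)]) / a)
}

#' Default annotation templates from the endmember library
#'
#' Builds template spectra for [annotate_clusters()] on a given axis:
#' `fibrosis` is the mean of the two collagen endmembers, `nodule` the
#' glycogen endmember.
#'
#' @param axis A [wavenumber_axis()].
#' @param endmembers Endmember library (default [default_endmembers()]).
#' @return Named list of numeric spectra.
#' @export
annotation_templates <- function(axis, endmembers = default_endmembers()) {
  list(
    fibrosis = (synth_spectrum(endmembers$collagen_a, axis) +
                  synth_spectrum(endmembers$collagen_b, axis)) / 2,
    nodule = synth_spectrum(endmembers$glycogen_nodule, axis))
}

#' Area percentage of a tissue label
#'
#' Percentage of valid (labeled) pixels whose class maps to `target` under
#' the annotation. Percentages over all tissue labels sum to 100.
#'
#' @param labels A `label_image`.
#' @param annotation A `cluster_annotation` for the same model.
#' @param target Tissue label, e.g. `"fibrosis"`.
#' @return Percentage in `[0, 100]`.
#' @export
area_percent <- function(labels, annotation, target = "fibrosis") {
  stopifnot(inherits(labels, "label_image"), inherits(annotation, "cluster_annotation"))
  lab <- labels$labels
  valid <- lab >= 0
  if (!any(valid)) stop("label image has no valid pixels", call. = FALSE)
  hit <- annotation[as.character(lab[valid])] == target
  100 * sum(hit) / sum(valid)
}
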