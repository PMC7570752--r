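#' Whole-sample analysis pipeline
#'
#' Runs the complete low-magnification analysis for every sample of a
#' manifest: crop to the fingerprint window, EMSC digital dewaxing against
#' the sample's paraffin reference, k-means clustering at each requested
#' k, annotation of the classes, and the spectral fibrosis-area
#' percentage; in parallel, color-deconvolution DIA of the paired
#' trichrome image. The per-sample results are then correlated across
#' methods ([compare_methods()]).
#'
#' @param manifest Tibble/data frame with one row per sample and columns
#'   `sample_id`, `group`, `cube`, `paraffin`, `trichrome`. The last three
#'   may be file paths (read with [read_cube()] / [read_rgb()]) or
#'   in-memory `spectral_image` / `rgb_image` objects in list-columns.
#' @param range Analysis window, cm^-1 (default `c(900, 1800)`).
#' @param k Clustering granularities (default `2:5`).
#' @param seed Integer seed for all k-means initializations.
#' @param exclude Sample ids excluded from the correlation stage.
#' @param templates Annotation templates; default built on the cropped
#'   axis via [annotation_templates()].
#' @param n_components,poly_degree,a_bounds,kappa EMSC parameters, see
#'   [dewax()].
#' @return A `run_report`: list with `areas` (tibble: sample_id, group,
#'   dia_percent, spectral_k<k>...), `comparison` (a `method_comparison`),
#'   `qc` (tibble of per-sample EMSC quality), `failures` (tibble of
#'   failed samples and stages), `params`.
#' @export
run_whole_sample <- function(manifest, range = c(900, 1800), k = 2:5,
                             seed = 0L, exclude = NULL, templates = NULL,
                             n_components = 10, poly_degree = 4,
                             a_bounds = c(0.2, 5), kappa = 5) {
  manifest <- tibble::as_tibble(manifest)
  stopifnot(all(c("sample_id", "group", "cube", "paraffin", "trichrome") %in%
                  names(manifest)), all(k >= 1))
  rows <- list(); qc <- list(); fail <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    stage <- "load"
    res <- tryCatch({
      img <- load_cube(manifest$cube[[i]])
      par <- load_cube(manifest$paraffin[[i]])
      tri <- load_rgb(manifest$trichrome[[i]])
      stage <- "emsc"
      dw <- dewax(img, par, range = range, n_components = n_components,
                  poly_degree = poly_degree, a_bounds = a_bounds, kappa = kappa)
      stage <- "cluster"
      tmpl <- templates %||% annotation_templates(dw$corrected$axis)
      spectral <- stats::setNames(numeric(length(k)), paste0("spectral_k", k))
      for (kk in k) {
        km <- fit_kmeans(dw$corrected, kk, seed = seed)
        ann <- annotate_clusters(km$model, templates = tmpl, basis = dw$basis)
        spectral[paste0("spectral_k", kk)] <-
          area_percent(km$labels, ann, "fibrosis")
      }
      stage <- "dia"
      dia <- fibrosis_percent_dia(segment_fibrosis(tri))
      v <- dw$fit$mask
      qc[[sid]] <- tibble::tibble(
        sample_id = sid, n_pixels = sum(v),
        n_outliers = sum(dw$fit$outlier[v]),
        rmse_median = stats::median(dw$fit$rmse[v]),
        a_median = stats::median(dw$fit$a[v]))
      c(list(sample_id = sid, group = manifest$group[i], dia_percent = dia),
        as.list(spectral))
    }, error = function(e) {
      fail[[sid]] <<- tibble::tibble(sample_id = sid, stage = stage,
                                     message = conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[sid]] <- tibble::as_tibble(res)
  }
  if (!length(rows)) stop("every sample failed; nothing to report", call. = FALSE)
  areas <- dplyr::bind_rows(rows)
  # with fewer than 3 usable samples the correlation stage is undefined;
  # report the areas anyway
  comparison <- tryCatch(compare_methods(areas, exclude = exclude),
                         error = function(e) NULL)
  structure(list(areas = areas, comparison = comparison,
                 qc = dplyr::bind_rows(qc),
                 failures = if (length(fail)) dplyr::bind_rows(fail)
                 else tibble::tibble(sample_id = character(0),
                                     stage = character(0),
                                     message = character(0)),
                 params = list(range = range, k = k, seed = seed,
                               exclude = exclude, n_components = n_components,
                               poly_degree = poly_degree, a_bounds = a_bounds,
                               kappa = kappa)),
            class = "run_report")
}

load_cube <- function(x) {
  if (inherits(x, "spectral_image")) return(x)
  read_cube(as.character(x))
}

load_rgb <- function(x) {
  if (inherits(x, "rgb_image")) return(x)
  read_rgb(as.character(x))
}

#' Fibrosis-focused common k-means pipeline
#'
#' Runs the high-magnification analysis on a set of fibrosis-region cubes:
#' each region is dewaxed against its paraffin reference over the collagen
#' window (1040-1425 cm^-1 by default, which avoids the strong paraffin
#' bands), all regions are pooled into one common k-means (k = 4 by
#' default) so class identities are shared, the centroid spectra are
#' second-derivative analyzed and hierarchically clustered into two groups
#' at the dendrogram root, and the per-group fibrosis sub-cluster
#' proportion table is computed.
#'
#' @param manifest Tibble with columns `sample_id`, `group`, `cube`,
#'   `paraffin` (paths or in-memory objects), one row per region.
#' @param range Analysis window (default `c(1040, 1425)`).
#' @param k Number of common classes (default 4).
#' @param seed Integer seed.
#' @param templates Annotation templates (default from the cropped axis).
#' @param window,polyorder Savitzky-Golay parameters for the centroid
#'   second derivatives.
#' @param n_components,poly_degree,a_bounds,kappa EMSC parameters.
#' @return A `focus_report`: list with `model` (`kmeans_model`), `labels`
#'   (list of `label_image`), `annotation`, `dendrogram`
#'   (`centroid_dendrogram`), `band_tables` (per-class `band_table`),
#'   `proportions` (`proportion_table`), `failures`, `params`.
#' @export
run_fibrosis_focus <- function(manifest, range = c(1040, 1425), k = 4,
                               seed = 0L, templates = NULL,
                               window = 9, polyorder = 3,
                               n_components = 10, poly_degree = 4,
                               a_bounds = c(0.2, 5), kappa = 5) {
  manifest <- tibble::as_tibble(manifest)
  stopifnot(all(c("sample_id", "group", "cube", "paraffin") %in% names(manifest)))
  imgs <- list(); pars <- list(); groups <- character(0); fail <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    ok <- tryCatch({
      img <- load_cube(manifest$cube[[i]])
      par <- load_cube(manifest$paraffin[[i]])
      img$sample_id <- sid
      imgs[[sid]] <- img
      pars[[sid]] <- par
      groups <- c(groups, manifest$group[i])
      TRUE
    }, error = function(e) {
      fail[[sid]] <<- tibble::tibble(sample_id = sid, stage = "load",
                                     message = conditionMessage(e))
      FALSE
    })
  }
  if (!length(imgs)) stop("every region failed; nothing to pool", call. = FALSE)
  # one shared EMSC model: pooled corrected spectra must be comparable
  dw <- dewax_common(imgs, pars, range = range, n_components = n_components,
                     poly_degree = poly_degree, a_bounds = a_bounds,
                     kappa = kappa)
  corrected <- dw$corrected
  ck <- fit_common_kmeans(corrected, k = k, seed = seed)
  tmpl <- templates %||% annotation_templates(ck$model$axis)
  annotation <- annotate_clusters(ck$model, templates = tmpl,
                                  basis = dw$basis)
  dend <- cluster_centroids(ck$model)
  band_tables <- lapply(seq_len(k), function(i) {
    d2 <- second_derivative(ck$model$centroids[i, ], ck$model$axis,
                            window = window, polyorder = polyorder)
    pick_bands(d2)
  })
  names(band_tables) <- paste0("class_", 0:(k - 1))
  proportions <- class_proportions(ck$labels, annotation, groups)
  structure(list(model = ck$model, labels = ck$labels,
                 annotation = annotation, dendrogram = dend,
                 band_tables = band_tables, proportions = proportions,
                 failures = if (length(fail)) dplyr::bind_rows(fail)
                 else tibble::tibble(sample_id = character(0),
                                     stage = character(0),
                                     message = character(0)),
                 params = list(range = range, k = k, seed = seed,
                               window = window, polyorder = polyorder,
                               n_components = n_components,
                               poly_degree = poly_degree,
                               a_bounds = a_bounds, kappa = kappa)),
            class = "focus_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d sample(s), k = %s\n", nrow(x$areas),
              paste(x$params$k, collapse = ",")))
  print(x$comparison$correlations)
  invisible(x)
}

#' @export
print.focus_report <- function(x, ...) {
  cat(sprintf("<focus_report> %d region(s), k = %d\n", length(x$labels),
              x$params$k))
  print(x$proportions)
  invisible(x)
}

#' Build a phantom fibrosis-region manifest
#'
#' Generates the high-magnification counterpart of [phantom_manifest()]:
#' small fibrosis-focused region cubes (fully tissue-covered, fine pixel
#' size) for each group, with group-specific `collagen_b` shares — the
#' planted analogue of qualitatively different fibrosis between
#' uncomplicated and complicated cirrhosis. Regions are mostly fibrous but
#' include adjacent nodule tissue, as real region selections do.
#'
#' @param n_per_group Regions per group.
#' @param fibrosis_b_share Named list of `collagen_b` shares per group.
#' @param target_fibrosis Fibrosis percentage of each region (default 70:
#'   fibrosis-focused but with nodule margins).
#' @param H,W Region size in pixels (default 32).
#' @param pixel_size Micrometres per pixel (default 2.7).
#' @param seed Master seed.
#' @return List with `manifest` (tibble: sample_id, group, cube, paraffin)
#'   and `truths`.
#' @export
phantom_regions <- function(n_per_group = 6,
                            fibrosis_b_share = list(uncomplicated = 0.3,
                                                    hcc = 0.8),
                            target_fibrosis = 70,
                            H = 32, W = 32, pixel_size = 2.7, seed = 1L) {
  rows <- list(); truths <- list()
  for (g in names(fibrosis_b_share)) {
    for (j in seq_len(n_per_group)) {
      sid <- sprintf("%s_r%02d", g, j)
      cfg <- phantom_config(H = H, W = W, target_fibrosis = target_fibrosis,
                            fibrosis_b_share = fibrosis_b_share[[g]],
                            tissue_fraction = 1, pixel_size = pixel_size,
                            seed = derive_seed(seed, sid))
      truth <- synth_label_map(cfg)
      cubes <- synth_cube(truth, config = cfg)
      cubes$tissue$group <- if (g %in% c("uncomplicated", "hcc")) g else "unknown"
      truths[[sid]] <- truth
      rows[[sid]] <- tibble::tibble(sample_id = sid, group = g,
                                    cube = list(cubes$tissue),
                                    paraffin = list(cubes$paraffin))
    }
  }
  list(manifest = dplyr::bind_rows(rows), truths = truths)
}

#' Build a phantom study manifest
#'
#' Generates a complete in-memory synthetic study: for each requested
#' sample, a phantom truth, its paired tissue + paraffin cubes and
#' trichrome rendering, under per-sample seeds derived from `seed`. The
#' default layout mirrors a two-group design (uncomplicated vs HCC
#' cirrhosis) with higher fibrosis targets in the complicated group.
#'
#' @param n_per_group Samples per group (default 5).
#' @param fibrosis_targets Named list with numeric target vectors
#'   `uncomplicated` and `hcc` (recycled to `n_per_group`).
#' @param fibrosis_b_share Named list of `collagen_b` shares per group.
#' @param seed Master seed.
#' @param config_fn Function `(target, share, seed)` returning the
#'   [phantom_config()] for one sample; replace to change geometry.
#' @return List with `manifest` (tibble: sample_id, group, cube, paraffin,
#'   trichrome as list-columns) and `truths` (named list of
#'   `phantom_truth`).
#' @export
phantom_manifest <- function(n_per_group = 5,
                             fibrosis_targets = list(
                               uncomplicated = c(8, 14, 20, 26, 32),
                               hcc = c(18, 26, 32, 38, 44)),
                             fibrosis_b_share = list(uncomplicated = 0.3,
                                                     hcc = 0.8),
                             seed = 1L,
                             config_fn = NULL) {
  if (is.null(config_fn)) {
    config_fn <- function(target, share, seed) {
      phantom_config(H = 48, W = 48, target_fibrosis = target,
                     fibrosis_b_share = share, seed = seed)
    }
  }
  rows <- list(); truths <- list()
  idx <- 0L
  for (g in c("uncomplicated", "hcc")) {
    targets <- rep_len(fibrosis_targets[[g]], n_per_group)
    for (j in seq_len(n_per_group)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", g, j)
      cfg <- config_fn(targets[j], fibrosis_b_share[[g]],
                       derive_seed(seed, sid))
      truth <- synth_label_map(cfg)
      cubes <- synth_cube(truth, config = cfg)
      cubes$tissue$group <- g
      cubes$tissue$sample_id <- sid
      tri <- synth_trichrome(truth, scale = cfg$pixel_size)
      truths[[sid]] <- truth
      rows[[sid]] <- tibble::tibble(
        sample_id = sid, group = g,
        cube = list(cubes$tissue), paraffin = list(cubes$paraffin),
        trichrome = list(tri))
    }
  }
  list(manifest = dplyr::bind_rows(rows), truths = truths)
}
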