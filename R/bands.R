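#' Savitzky-Golay second derivative of a spectrum
#'
#' Second derivative with respect to wavenumber (units AU/cm^-2), computed
#' with a Savitzky-Golay filter and scaled by the axis spacing. Second
#' derivatives sharpen and separate overlapping absorption bands:
#' absorbance maxima become derivative minima. The operator is linear in
#' the input spectrum.
#'
#' @param spectrum Numeric B-vector of absorbance values.
#' @param axis The [wavenumber_axis()] of the spectrum.
#' @param window Filter window length in points; odd, greater than
#'   `polyorder` (default 9).
#' @param polyorder Fitting polynomial degree (default 3).
#' @return A `derivative_spectrum`: list with `values` (AU/cm^-2), `axis`,
#'   `window`, `polyorder`.
#' @export
second_derivative <- function(spectrum, axis, window = 9, polyorder = 3) {
  if (!inherits(axis, "wavenumber_axis")) axis <- wavenumber_axis(axis)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (window <= polyorder) stop("window must exceed polyorder", call. = FALSE)
  if (length(spectrum) < window) {
    stop("spectrum shorter than the filter window", call. = FALSE)
  }
  if (length(spectrum) != length(axis)) {
    stop("spectrum length does not match axis", call. = FALSE)
  }
  vals <- signal::sgolayfilt(spectrum, p = polyorder, n = window, m = 2,
                             ts = axis_spacing(axis))
  structure(list(values = as.numeric(vals), axis = axis,
                 window = window, polyorder = polyorder),
            class = "derivative_spectrum")
}

#' @export
print.derivative_spectrum <- function(x, ...) {
  cat(sprintf("<derivative_spectrum> %d points, SG window %d / polyorder %d\n",
              length(x$values), x$window, x$polyorder))
  invisible(x)
}

#' Built-in infrared band assignment table
#'
#' Reference positions and tentative assignments of the glycogen, collagen
#' (amide III, CH2/CH3), paraffin and protein amide bands used to annotate
#' picked bands. Shipped as plain CSV with the package.
#'
#' @return Tibble with columns `position` (cm^-1), `assignment`,
#'   `component`.
#' @export
band_assignments <- function() {
  path <- system.file("extdata", "band_assignments.csv",
                      package = "spectrofibro", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Pick absorption bands from a second-derivative spectrum
#'
#' Bands are local minima of the second derivative deeper than
#' `-prominence`. Each picked position is annotated with the nearest entry
#' of the built-in assignment table within `tol` cm^-1 (default 6, which
#' absorbs the few-cm^-1 range notation of literature assignments), or
#' `"unassigned"`.
#'
#' @param derivative A `derivative_spectrum` from [second_derivative()].
#' @param prominence Depth threshold (AU/cm^-2, > 0); only minima below
#'   `-prominence` are reported.
#' @param assignments Assignment table (default [band_assignments()]).
#' @param tol Assignment matching tolerance, cm^-1.
#' @return A `band_table` tibble: `position` (cm^-1, ascending), `depth`
#'   (second-derivative value, < 0), `assignment`, `component`.
#' @export
pick_bands <- function(derivative, prominence = 1e-5,
                       assignments = band_assignments(), tol = 6) {
  stopifnot(inherits(derivative, "derivative_spectrum"), prominence > 0)
  v <- derivative$values
  nu <- as.numeric(derivative$axis)
  n <- length(v)
  if (n < 3) {
    return(empty_band_table())
  }
  i <- 2:(n - 1)
  is_min <- v[i] < v[i - 1] & v[i] < v[i + 1] & v[i] < -prominence
  idx <- i[is_min]
  if (!length(idx)) return(empty_band_table())
  pos <- nu[idx]
  dep <- v[idx]
  assn <- character(length(pos)); comp <- character(length(pos))
  for (j in seq_along(pos)) {
    d <- abs(assignments$position - pos[j])
    if (min(d) <= tol) {
      hit <- which.min(d)
      assn[j] <- assignments$assignment[hit]
      comp[j] <- assignments$component[hit]
    } else {
      assn[j] <- "unassigned"; comp[j] <- "unassigned"
    }
  }
  tbl <- tibble::tibble(position = pos, depth = dep,
                        assignment = assn, component = comp)
  tbl <- tbl[order(tbl$position), ]
  class(tbl) <- c("band_table", class(tbl))
  tbl
}

empty_band_table <- function() {
  tbl <- tibble::tibble(position = numeric(0), depth = numeric(0),
                        assignment = character(0), component = character(0))
  class(tbl) <- c("band_table", class(tbl))
  tbl
}

#' Hierarchical clustering of centroid spectra
#'
#' Agglomerative clustering of the k centroid spectra (default Ward
#' linkage on Euclidean distances) with a two-group cut at the root split.
#' On centroids from a common k-means of cirrhotic tissue, the root split
#' separates nodule-like (glycogen) from fibrosis-like (collagen)
#' signatures.
#'
#' @param centroids k x B matrix of centroid spectra (or a
#'   `kmeans_model`).
#' @param linkage `"ward"` (default; `hclust` method `"ward.D2"`),
#'   `"average"` or `"complete"`.
#' @return A `centroid_dendrogram`: list with `hclust` (the tree),
#'   `groups` (two-group cut, named by class id `0..k-1`), `linkage`.
#' @export
cluster_centroids <- function(centroids, linkage = c("ward", "average", "complete")) {
  if (inherits(centroids, "kmeans_model")) centroids <- centroids$centroids
  linkage <- match.arg(linkage)
  k <- nrow(centroids)
  if (k < 2) stop("need at least two centroids", call. = FALSE)
  rownames(centroids) <- as.character(0:(k - 1))
  method <- switch(linkage, ward = "ward.D2", average = "average",
                   complete = "complete")
  hc <- stats::hclust(stats::dist(centroids), method = method)
  groups <- stats::cutree(hc, k = 2)
  structure(list(hclust = hc, groups = groups, linkage = linkage),
            class = "centroid_dendrogram")
}

#' @export
print.centroid_dendrogram <- function(x, ...) {
  g1 <- names(x$groups)[x$groups == 1]
  g2 <- names(x$groups)[x$groups == 2]
  cat(sprintf("<centroid_dendrogram> %s linkage; root split: {%s} vs {%s}\n",
              x$linkage, paste(g1, collapse = ","), paste(g2, collapse = ",")))
  invisible(x)
}
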