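#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a k-means model into long centroid spectra
#'
#' @param x A `kmeans_model`.
#' @param ... Unused.
#' @return Tibble with columns `class_id`, `wavenumber`, `absorbance`.
#' @export
tidy.kmeans_model <- function(x, ...) {
  tibble::tibble(
    class_id = rep(0:(x$k - 1), each = ncol(x$centroids)),
    wavenumber = rep(as.numeric(x$axis), x$k),
    absorbance = as.vector(t(x$centroids)))
}

#' One-row summary of a k-means model
#'
#' @param x A `kmeans_model`.
#' @param ... Unused.
#' @return Tibble with `k`, `inertia`, `n_pixels`, `largest_class_share`.
#' @export
glance.kmeans_model <- function(x, ...) {
  tibble::tibble(k = x$k, inertia = x$inertia, n_pixels = sum(x$sizes),
                 largest_class_share = max(x$sizes) / sum(x$sizes))
}

#' Tidy an EMSC fit into a per-pixel coefficient table
#'
#' @param x An `emsc_fit`.
#' @param ... Unused.
#' @return Tibble with 0-based `row`, `col`, `a`, `rmse`, `outlier`
#'   (valid pixels only).
#' @export
tidy.emsc_fit <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  tibble::tibble(row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                 a = x$a[x$mask], rmse = x$rmse[x$mask],
                 outlier = x$outlier[x$mask])
}

#' One-row summary of an EMSC fit
#'
#' @param x An `emsc_fit`.
#' @param ... Unused.
#' @return Tibble with pixel/outlier counts and coefficient summaries.
#' @export
glance.emsc_fit <- function(x, ...) {
  v <- x$mask
  tibble::tibble(n_pixels = sum(v), n_outliers = sum(x$outlier[v]),
                 a_median = stats::median(x$a[v]),
                 rmse_median = stats::median(x$rmse[v]),
                 rmse_max = max(x$rmse[v]))
}

#' Tidy a correlation result
#'
#' @param x A `correlation_result`.
#' @param ... Unused.
#' @return One-row tibble with `r`, `p`, `n`, `n_excluded`.
#' @export
tidy.correlation_result <- function(x, ...) {
  tibble::tibble(r = x$r, p = x$p, n = x$n, n_excluded = length(x$excluded))
}

#' Tidy a method comparison into the per-k correlation table
#'
#' @param x A `method_comparison`.
#' @param ... Unused.
#' @return Tibble with `k`, `r`, `p`, `n`.
#' @export
tidy.method_comparison <- function(x, ...) x$correlations

#' Tidy a label image into a long pixel table
#'
#' @param x A `label_image`.
#' @param ... Unused.
#' @return Tibble with 0-based `row`, `col` and `class_id` (`-1` masked).
#' @export
tidy.label_image <- function(x, ...) {
  d <- dim(x$labels)
  tibble::tibble(row = rep(0:(d[1] - 1), d[2]),
                 col = rep(0:(d[2] - 1), each = d[1]),
                 class_id = as.vector(x$labels))
}
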