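#' Pearson correlation with explicit outlier exclusion
#'
#' Product-moment correlation between two percentage vectors with a
#' two-sided p-value from the exact t transformation
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom
#' (the standard small-sample Pearson inference; delegated to
#' [stats::cor.test()]). Exclusions are an explicit, auditable caller
#' input — identified outliers are removed by id, never automatically.
#'
#' @param x,y Numeric vectors of equal length (e.g. fibrosis percentages
#'   by two methods).
#' @param ids Optional identifiers, parallel to `x`/`y` (defaults to
#'   indices).
#' @param exclude Ids to drop before the analysis.
#' @return A `correlation_result`: list with `r`, `p`, `n`, `excluded`.
#' @export
pearson_corr <- function(x, y, ids = NULL, exclude = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_along(x))
  keep <- !(ids %in% exclude)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("fewer than 3 pairs after exclusion", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n,
                 excluded = intersect(exclude, ids[!keep]) %||% character(0)),
            class = "correlation_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f, p = %.4g, n = %d%s\n",
              x$r, x$p, x$n,
              if (length(x$excluded)) sprintf(" (excluded: %s)",
                                              paste(x$excluded, collapse = ", "))
              else ""))
  invisible(x)
}

#' Two-sided Pearson p-value from a printed (r, n) pair
#'
#' Computes the two-sided p-value implied by a reported correlation
#' coefficient and sample size, via the exact t transformation. Useful for
#' consistency checks of published correlation tables.
#'
#' @param r Correlation coefficient, `|r| < 1`.
#' @param n Number of pairs, `n >= 3`.
#' @return The two-sided p-value.
#' @examples
#' pearson_p_value(0.64, 9)  # ~0.06
#' @export
pearson_p_value <- function(r, n) {
  stopifnot(abs(r) < 1, n >= 3)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Compare spectral and histological fibrosis estimates
#'
#' Takes the paired area table of a study — one row per sample with the
#' DIA percentage and the spectral (k-means) percentage at each k — and
#' returns the per-k Pearson correlations plus per-group means and SDs of
#' every percentage column. Exclusions apply uniformly to all analyses.
#'
#' @param table Data frame / tibble with columns `sample_id`, `group`,
#'   `dia_percent`, and one `spectral_k<k>` column per clustering
#'   granularity (e.g. `spectral_k2` .. `spectral_k5`).
#' @param exclude Sample ids to exclude (explicit outlier handling).
#' @return A `method_comparison`: list with `correlations` (tibble: k, r,
#'   p, n), `group_means` (tibble: group, metric, mean, sd, n) and
#'   `excluded`.
#' @export
compare_methods <- function(table, exclude = NULL) {
  table <- tibble::as_tibble(table)
  need <- c("sample_id", "group", "dia_percent")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop(sprintf("paired table missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  kcols <- grep("^spectral_k[0-9]+$", names(table), value = TRUE)
  if (!length(kcols)) stop("paired table has no spectral_k<k> columns", call. = FALSE)
  used <- dplyr::filter(table, !(.data$sample_id %in% exclude))
  if (nrow(used) == 0) stop("all rows excluded", call. = FALSE)
  correlations <- purrr::map_dfr(kcols, function(col) {
    cr <- pearson_corr(used$dia_percent, used[[col]], ids = used$sample_id)
    tibble::tibble(k = as.integer(sub("spectral_k", "", col)),
                   r = cr$r, p = cr$p, n = cr$n)
  })
  group_means <- used |>
    tidyr::pivot_longer(dplyr::all_of(c("dia_percent", kcols)),
                        names_to = "metric", values_to = "percent") |>
    dplyr::group_by(.data$group, .data$metric) |>
    dplyr::summarise(mean = mean(.data$percent), sd = stats::sd(.data$percent),
                     n = dplyr::n(), .groups = "drop")
  structure(list(correlations = correlations, group_means = group_means,
                 excluded = exclude %||% character(0)),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  print(x$correlations)
  invisible(x)
}

#' Fibrosis sub-cluster proportion table by group
#'
#' Within each group, pools all pixels belonging to fibrosis-annotated
#' classes across its label images and reports each fibrosis class's
#' share of that pool as a percentage. Columns (groups) sum to 100. This
#' is the group-wise composition of the fibrous tissue across the two
#' collagen sub-signatures.
#'
#' @param labels List of `label_image`s from a common k-means.
#' @param annotation A `cluster_annotation` of the shared model with at
#'   least two fibrosis classes.
#' @param groups Character vector of group labels, parallel to `labels`.
#' @return A `proportion_table` tibble: `class_id`, one percentage column
#'   per group.
#' @export
class_proportions <- function(labels, annotation, groups) {
  stopifnot(length(labels) == length(groups), length(labels) >= 1)
  fib_ids <- names(annotation)[annotation == "fibrosis"]
  if (length(fib_ids) < 2) {
    stop("need at least two fibrosis-annotated classes", call. = FALSE)
  }
  out <- tibble::tibble(class_id = as.integer(fib_ids))
  for (g in unique(groups)) {
    counts <- stats::setNames(numeric(length(fib_ids)), fib_ids)
    for (i in which(groups == g)) {
      lab <- labels[[i]]$labels
      for (id in fib_ids) counts[id] <- counts[id] + sum(lab == as.integer(id))
    }
    if (sum(counts) == 0) {
      stop(sprintf("group '%s' has no fibrosis-class pixels", g), call. = FALSE)
    }
    out[[g]] <- 100 * unname(counts) / sum(counts)
  }
  class(out) <- c("proportion_table", class(out))
  out
}
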