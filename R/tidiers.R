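#' Tidy a connectivity map into a voxel table
#'
#' @param x A `connectivity_map`.
#' @param valid_only Drop invalid voxels (default `TRUE`).
#' @param ... Unused.
#' @return Tibble: `i`, `j`, `k`, `z`, `valid` plus metadata columns.
#' @exportS3Method generics::tidy
tidy.connectivity_map <- function(x, valid_only = TRUE, ...) {
  sel <- if (valid_only) x$valid else array(TRUE, dim(x$z))
  ijk <- which_ijk(sel)
  tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
         z = x$z[sel], valid = x$valid[sel],
         subject_id = x$subject_id, drug = x$drug)
}

#' @describeIn tidy.connectivity_map One-row summary of a map.
#' @exportS3Method generics::glance
glance.connectivity_map <- function(x, ...) {
  z <- x$z[x$valid]
  tibble(n_voxels = length(x$valid), n_valid = sum(x$valid),
         mean_z = mean(z), max_z = max(z), min_z = min(z))
}

#' Tidy a statistic map into a voxel table
#'
#' @param x A `stat_map`.
#' @param ... Unused.
#' @return Tibble: voxel indices, statistic, p-value and estimate (when
#'   present) over valid voxels.
#' @exportS3Method generics::tidy
tidy.stat_map <- function(x, ...) {
  ijk <- which_ijk(x$valid)
  out <- tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                stat = x$stat[x$valid], p = x$p[x$valid])
  if (!is.null(x$estimate)) out$estimate <- x$estimate[x$valid]
  out
}

#' @describeIn tidy.stat_map One-row summary: contrast, df, valid-voxel
#'   count, extreme statistic, minimum p.
#' @exportS3Method generics::glance
glance.stat_map <- function(x, ...) {
  s <- x$stat[x$valid]
  tibble(contrast = x$contrast, df = x$df,
         n_valid = sum(x$valid),
         max_stat = if (length(s)) max(s) else NA_real_,
         min_p = if (length(s)) min(x$p[x$valid]) else NA_real_)
}

#' One-row summary of a pipeline report
#'
#' @param x A `mesoconn_report`.
#' @param ... Unused.
#' @return Tibble with the headline quantities of the run: set sizes,
#'   overlap percentages, span correlations per condition and their
#'   comparison, and recovery metrics for synthetic cohorts.
#' @exportS3Method generics::glance
glance.mesoconn_report <- function(x, ...) {
  v1 <- x$venn$connectivity_vs_invertedU
  v2 <- x$venn$span_vs_invertedU
  out <- tibble(
    n_connectivity = length(x$sets$connectivity),
    n_invertedU = length(x$sets$invertedU),
    n_invertedU_loose = length(x$sets$invertedU_loose),
    n_span = length(x$sets$span),
    pct_conn_in_invertedU = v1$percent_of_a,
    pct_span_in_invertedU = v2$percent_of_a,
    chi2_regions = x$chi_square$chi2,
    chi2_p = x$chi_square$p)
  if (!is.null(x$span_correlations)) {
    out$r_placebo <- x$span_correlations$placebo$r
    out$r_drug <- x$span_correlations$drug$r
    out$z_comparison <- x$span_correlations$comparison$z
  }
  if (!is.null(x$recovery)) {
    out$sensitivity <- x$recovery$sensitivity
    out$false_positive_rate <- x$recovery$false_positive_rate
  }
  out
}
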