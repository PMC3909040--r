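#' Construct a statistic map
#'
#' @param stat 3D array of test statistics.
#' @param p 3D array of p-values.
#' @param df Degrees of freedom.
#' @param valid 3D logical array of voxels with a defined statistic.
#' @param contrast Character label describing the contrast.
#' @param estimate Optional 3D array of contrast estimates.
#' @return A `stat_map` object.
#' @export
stat_map <- function(stat, p, df, valid, contrast = "unnamed", estimate = NULL) {
  stopifnot(identical(dim(stat), dim(p)), identical(dim(stat), dim(valid)))
  if (df <= 0) abort("`df` must be positive")
  pv <- p[valid]
  if (any(!is.finite(pv)) || any(pv < 0) || any(pv > 1)) {
    abort("p-values must lie in [0, 1] on valid voxels")
  }
  structure(list(stat = stat, p = p, df = df, valid = valid,
                 contrast = contrast, estimate = estimate),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> contrast '%s', df = %g, %d/%d valid voxels\n",
              x$contrast, x$df, sum(x$valid), length(x$valid)))
  invisible(x)
}

# stack the z volumes of a list of connectivity maps into maps x voxel
# matrix; also returns the conjunction validity mask
stack_maps <- function(maps) {
  stopifnot(length(maps) >= 1L, all(vapply(maps, inherits, TRUE, "connectivity_map")))
  dims <- lapply(maps, function(m) dim(m$z))
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    abort("all maps must share one grid")
  }
  Z <- do.call(rbind, lapply(maps, function(m) as.numeric(m$z)))
  valid <- Reduce(`&`, lapply(maps, function(m) m$valid))
  list(Z = Z, valid = valid, dim = dims[[1]])
}

#' Voxelwise one-sample t map
#'
#' Tests the Fisher z values against zero at every voxel across maps (the
#' overall connectivity map, treating each session's map as an
#' observation). Voxels invalid in any input map, or with zero sample
#' variance across maps, are marked invalid.
#'
#' @param maps List of `connectivity_map` objects (at least 3).
#' @return A `stat_map` with `df = length(maps) - 1` and two-tailed p.
#' @export
one_sample_t_map <- function(maps) {
  if (length(maps) < 3L) abort("need at least 3 maps for a one-sample t-test")
  st <- stack_maps(maps)
  m <- nrow(st$Z)
  idx <- which(st$valid)
  Z <- st$Z[, idx, drop = FALSE]
  mu <- colMeans(Z)
  s <- sqrt(colSums(sweep(Z, 2, mu)^2) / (m - 1))
  degen <- s == 0
  if (any(degen)) {
    warn(sprintf("%d voxel(s) with zero between-map variance marked invalid",
                 sum(degen)))
  }
  tval <- rep(NA_real_, length(idx))
  tval[!degen] <- mu[!degen] / (s[!degen] / sqrt(m))
  d3 <- st$dim
  stat <- array(NA_real_, d3); p <- array(NA_real_, d3)
  valid <- array(FALSE, d3); est <- array(NA_real_, d3)
  valid[idx[!degen]] <- TRUE
  stat[idx[!degen]] <- tval[!degen]
  p[idx[!degen]] <- 2 * pt(-abs(tval[!degen]), df = m - 1)
  est[idx[!degen]] <- mu[!degen]
  stat_map(stat, p, df = m - 1, valid = valid, contrast = "one_sample_mean",
           estimate = est)
}

# match each map in `maps` to its design row; returns the index of the map
# for a given subject/drug
map_lookup <- function(maps, design) {
  key_map <- vapply(maps, function(m) paste(m$subject_id, m$drug, sep = "|"), "")
  key_des <- paste(design$subject_id, design$drug, sep = "|")
  miss <- setdiff(key_des, key_map)
  if (length(miss)) {
    abort(sprintf("missing map(s) for subject-session: %s",
                  paste(miss, collapse = ", ")))
  }
  match(key_des, key_map)
}

#' Drug-by-span interaction (inverted-U) contrast map
#'
#' Per voxel, forms each subject's paired difference
#' `d = z(drug) - z(placebo)` and compares the low-span and high-span
#' groups with a pooled-variance two-sample t-test
#' (`df = n_low + n_high - 2`). For the default quadratic weights
#' `(-0.5, 0.5, 0.5, -0.5)` over the canonical cells, the reported contrast
#' estimate equals `(mean d_low - mean d_high) / 2`; this is the exact test
#' of the drug-by-span interaction in the mixed 2x2 design. Positive
#' statistics indicate the inverted-U pattern (the drug raises connectivity
#' in low-span subjects and lowers it in high-span subjects).
#'
#' @param maps List of `connectivity_map` objects, one per subject-session.
#' @param design A validated [cohort_design()] table covering every map.
#' @param contrast Length-4 weight vector over the canonical cells
#'   (low-placebo, low-drug, high-placebo, high-drug); must sum to 0.
#' @return A `stat_map` with the t statistic, two-tailed p, and the
#'   weighted cell-mean estimate.
#' @export
interaction_contrast_map <- function(maps, design,
                                     contrast = c(-0.5, 0.5, 0.5, -0.5)) {
  design <- validate_cohort_design(design)
  if (length(contrast) != 4L || abs(sum(contrast)) > 1e-12) {
    abort("`contrast` must be four weights summing to 0")
  }
  subjects <- design |> dplyr::distinct(.data$subject_id, .data$span_group)
  n_low <- sum(subjects$span_group == "low")
  n_high <- sum(subjects$span_group == "high")
  if (n_low < 2L || n_high < 2L) {
    abort("each span group needs at least 2 subjects")
  }
  st <- stack_maps(maps)
  idx_drug <- map_lookup(maps, subjects |>
                           dplyr::mutate(drug = "bromocriptine"))
  idx_plac <- map_lookup(maps, subjects |> dplyr::mutate(drug = "placebo"))
  vx <- which(st$valid)
  Zd <- st$Z[idx_drug, vx, drop = FALSE]
  Zp <- st$Z[idx_plac, vx, drop = FALSE]
  D <- Zd - Zp
  low <- subjects$span_group == "low"

  d_low <- colMeans(D[low, , drop = FALSE])
  d_high <- colMeans(D[!low, , drop = FALSE])
  ss_low <- colSums(sweep(D[low, , drop = FALSE], 2, d_low)^2)
  ss_high <- colSums(sweep(D[!low, , drop = FALSE], 2, d_high)^2)
  df <- n_low + n_high - 2L
  sp <- sqrt((ss_low + ss_high) / df)
  se <- sp * sqrt(1 / n_low + 1 / n_high)
  degen <- se == 0
  tval <- rep(NA_real_, length(vx))
  tval[!degen] <- (d_low[!degen] - d_high[!degen]) / se[!degen]

  # cell means of z for the reported contrast estimate
  cm <- rbind(low_placebo = colMeans(Zp[low, , drop = FALSE]),
              low_drug = colMeans(Zd[low, , drop = FALSE]),
              high_placebo = colMeans(Zp[!low, , drop = FALSE]),
              high_drug = colMeans(Zd[!low, , drop = FALSE]))
  estv <- drop(contrast %*% cm)

  d3 <- st$dim
  stat <- array(NA_real_, d3); p <- array(NA_real_, d3)
  valid <- array(FALSE, d3); est <- array(NA_real_, d3)
  keep <- vx[!degen]
  valid[keep] <- TRUE
  stat[keep] <- tval[!degen]
  p[keep] <- 2 * pt(-abs(tval[!degen]), df = df)
  est[keep] <- estv[!degen]
  if (any(degen)) {
    warn(sprintf("%d voxel(s) with zero pooled variance marked invalid",
                 sum(degen)))
  }
  stat_map(stat, p, df = df, valid = valid,
           contrast = "drug_by_span_invertedU", estimate = est)
}

#' Span main-effect map in one drug condition
#'
#' Two-sample t-test (high minus low span, pooled variance) on the Fisher z
#' maps of one session type, used to build the span-only voxel set of the
#' overlap analysis.
#'
#' @param maps List of `connectivity_map` objects.
#' @param design A validated [cohort_design()] table.
#' @param drug Which condition's maps to compare (default `"placebo"`).
#' @return A `stat_map`, positive where high-span connectivity exceeds
#'   low-span.
#' @export
span_effect_map <- function(maps, design, drug = "placebo") {
  design <- validate_cohort_design(design)
  subjects <- design |> dplyr::distinct(.data$subject_id, .data$span_group)
  dv <- .env_drug(drug)
  st <- stack_maps(maps)
  idx <- map_lookup(maps, subjects |> dplyr::mutate(drug = dv))
  vx <- which(st$valid)
  Z <- st$Z[idx, vx, drop = FALSE]
  low <- subjects$span_group == "low"
  n_low <- sum(low); n_high <- sum(!low)
  if (n_low < 2L || n_high < 2L) abort("each span group needs at least 2 subjects")
  m_low <- colMeans(Z[low, , drop = FALSE])
  m_high <- colMeans(Z[!low, , drop = FALSE])
  ss <- colSums(sweep(Z[low, , drop = FALSE], 2, m_low)^2) +
    colSums(sweep(Z[!low, , drop = FALSE], 2, m_high)^2)
  df <- n_low + n_high - 2L
  se <- sqrt(ss / df) * sqrt(1 / n_low + 1 / n_high)
  degen <- se == 0
  tval <- rep(NA_real_, length(vx))
  tval[!degen] <- (m_high[!degen] - m_low[!degen]) / se[!degen]
  d3 <- st$dim
  stat <- array(NA_real_, d3); p <- array(NA_real_, d3); valid <- array(FALSE, d3)
  keep <- vx[!degen]
  valid[keep] <- TRUE
  stat[keep] <- tval[!degen]
  p[keep] <- 2 * pt(-abs(tval[!degen]), df = df)
  stat_map(stat, p, df = df, valid = valid,
           contrast = sprintf("span_high_minus_low_%s", drug))
}

.env_drug <- function(drug) {
  if (!drug %in% c("placebo", "bromocriptine")) {
    abort(sprintf("unknown drug label '%s'", drug))
  }
  drug
}

#' Benjamini-Hochberg FDR step-up procedure
#'
#' Sorts the p-values ascending, finds the largest `i` with
#' `p(i) <= i * q / m`, and rejects all hypotheses with `p <= p(i)`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return List with `rejected` (integer indices into `p_values`, in input
#'   order) and `threshold` (the realised p cutoff, `NA` when nothing is
#'   rejected).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (!length(p_values)) abort("empty p-value vector")
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  if (q <= 0 || q >= 1) abort("`q` must lie strictly in (0, 1)")
  m <- length(p_values)
  ord <- order(p_values)
  ps <- p_values[ord]
  below <- which(ps <= seq_len(m) * q / m)
  if (!length(below)) {
    return(list(rejected = integer(0), threshold = NA_real_))
  }
  k <- max(below)
  list(rejected = sort(ord[seq_len(k)]), threshold = ps[k])
}

#' Threshold specification for voxelwise correction
#'
#' @param q FDR level (default 0.05).
#' @param small_volume_mask Optional 3D logical array restricting the
#'   multiple-comparisons correction to an a priori region.
#' @param min_cluster Minimum cluster extent in voxels (default 20).
#' @param connectivity Cluster neighbourhood: 6, 18 or 26 (default 6).
#' @param direction Sign restriction applied to the statistic before
#'   thresholding: `"both"`, `"positive"` or `"negative"`.
#' @return A `threshold_spec` list.
#' @export
threshold_spec <- function(q = 0.05, small_volume_mask = NULL,
                           min_cluster = 20L, connectivity = 6,
                           direction = c("both", "positive", "negative")) {
  if (q <= 0 || q >= 1) abort("`q` must lie strictly in (0, 1)")
  if (min_cluster < 1L) abort("`min_cluster` must be at least 1")
  neighbor_offsets(connectivity)  # validates
  structure(list(q = q, small_volume_mask = small_volume_mask,
                 min_cluster = as.integer(min_cluster),
                 connectivity = as.integer(connectivity),
                 direction = match.arg(direction)),
            class = "threshold_spec")
}

#' FDR correction with small-volume restriction and cluster filtering
#'
#' Applies [bh_fdr()] to the p-values of a statistic map, restricted to the
#' small-volume mask when one is supplied (otherwise the whole valid
#' volume), then removes clusters smaller than `min_cluster`. Invalid
#' (degenerate) voxels carry no p-value and do not count toward the number
#' of tests.
#'
#' @param map A `stat_map`.
#' @param spec A [threshold_spec()].
#' @return A `voxel_set` of surviving voxels with full provenance.
#' @export
small_volume_threshold <- function(map, spec = threshold_spec()) {
  stopifnot(inherits(map, "stat_map"), inherits(spec, "threshold_spec"))
  sel <- map$valid
  if (!is.null(spec$small_volume_mask)) {
    if (!identical(dim(spec$small_volume_mask), dim(map$valid))) {
      abort("small-volume mask grid does not match the map")
    }
    sel <- sel & spec$small_volume_mask
    if (!any(sel)) abort("small-volume mask is disjoint from valid voxels")
  }
  if (spec$direction == "positive") sel <- sel & !is.na(map$stat) & map$stat > 0
  if (spec$direction == "negative") sel <- sel & !is.na(map$stat) & map$stat < 0
  idx <- which(sel)
  prov <- list(contrast = map$contrast, correction = "BH-FDR", q = spec$q,
               small_volume = !is.null(spec$small_volume_mask),
               direction = spec$direction, n_tests = length(idx))
  if (!length(idx)) {
    return(voxel_set(NULL, dim(map$valid), c(prov, list(p_threshold = NA_real_))))
  }
  res <- bh_fdr(map$p[idx], spec$q)
  prov$p_threshold <- res$threshold
  vs <- voxel_set(linear_to_ijk(idx[res$rejected], dim(map$valid)),
                  dim(map$valid), prov)
  cluster_filter(vs, spec$min_cluster, spec$connectivity)
}

#' Uncorrected p-value thresholding
#'
#' Loose thresholding used for the overlap (Venn) analyses: keeps voxels
#' with `p < p_threshold`, optionally restricted by mask and sign.
#'
#' @param map A `stat_map`.
#' @param p_threshold Uncorrected p cutoff (default 0.05).
#' @param mask Optional 3D logical restriction.
#' @param direction `"both"`, `"positive"` or `"negative"`.
#' @return A `voxel_set` with provenance.
#' @export
uncorrected_threshold <- function(map, p_threshold = 0.05, mask = NULL,
                                  direction = c("both", "positive", "negative")) {
  stopifnot(inherits(map, "stat_map"))
  direction <- match.arg(direction)
  sel <- map$valid
  if (!is.null(mask)) sel <- sel & mask
  if (direction == "positive") sel <- sel & !is.na(map$stat) & map$stat > 0
  if (direction == "negative") sel <- sel & !is.na(map$stat) & map$stat < 0
  sel <- sel & !is.na(map$p) & map$p < p_threshold
  voxel_set_from_mask(sel, provenance = list(
    contrast = map$contrast, correction = "uncorrected",
    p_threshold = p_threshold, direction = direction))
}

#' Correlate per-subject connectivity with span scores
#'
#' Pearson correlation with a two-tailed p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param per_subject_values Numeric vector (e.g. mean Fisher z over a
#'   voxel set, one value per subject).
#' @param span_scores Numeric vector of the same length (n >= 4).
#' @return A one-row tibble: `r`, `t`, `p`, `n`, `df`.
#' @export
correlate_with_span <- function(per_subject_values, span_scores) {
  n <- length(span_scores)
  if (length(per_subject_values) != n) abort("input lengths differ")
  if (n < 4L) abort("need at least 4 subjects")
  if (sd(span_scores) == 0) abort("span scores are constant")
  if (sd(per_subject_values) == 0) abort("connectivity values are constant")
  r <- stats::cor(per_subject_values, span_scores)
  df <- n - 2L
  if (abs(r) >= 1) {
    tval <- sign(r) * Inf
    p <- .Machine$double.xmin  # reported as below machine floor
  } else {
    tval <- r * sqrt(df) / sqrt(1 - r^2)
    p <- 2 * pt(-abs(tval), df)
  }
  tibble(r = r, t = tval, p = p, n = n, df = df)
}

#' Compare two independent correlations (Fisher z test)
#'
#' `Z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-tailed normal p-value.
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes (each at least 4).
#' @return A one-row tibble: `z`, `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (n1 <= 3L || n2 <= 3L) abort("sample sizes must exceed 3")
  if (abs(r1) >= 1 || abs(r2) >= 1) abort("correlations must lie strictly inside (-1, 1)")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' Assign span groups by cutoff
#'
#' Subjects scoring at or above the cutoff are high-span (the cutoff is
#' inclusive), all others low-span.
#'
#' @param span_scores Numeric scores.
#' @param cutoff Inclusive high-span cutoff (default 3.5).
#' @return Character vector `"low"`/`"high"`.
#' @export
assign_span_groups <- function(span_scores, cutoff = 3.5) {
  stopifnot_scalar(cutoff, "cutoff")
  ifelse(span_scores >= cutoff, "high", "low")
}
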