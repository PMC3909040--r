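#' Integer overlap percentage
#'
#' `100 * n_intersection / n_total`, rounded half away from zero to the
#' nearest integer (so 61/122 gives 50 and 4/28 gives 14).
#'
#' @param n_intersection Count of overlapping voxels.
#' @param n_total Reference total (at least 1, `>= n_intersection`).
#' @return Integer percentage.
#' @export
overlap_percent <- function(n_intersection, n_total) {
  if (n_total < 1L) abort("`n_total` must be at least 1")
  if (n_intersection < 0L || n_intersection > n_total) {
    abort("`n_intersection` must lie in [0, n_total]")
  }
  as.integer(round_half_away(100 * n_intersection / n_total))
}

#' Venn overlap between two voxel sets
#'
#' Exact set intersection and differences. The reported percentage takes
#' `set_a` as the reference: the share of A's voxels that also belong to B.
#'
#' @param set_a,set_b `voxel_set` objects on the same grid.
#' @return An `overlap_result`: list with `n_only_a`, `n_only_b`,
#'   `n_intersection`, `percent_of_a`, and the two provenance records.
#' @export
overlap_counts <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "voxel_set"), inherits(set_b, "voxel_set"))
  if (!identical(as.integer(set_a$shape), as.integer(set_b$shape))) {
    abort("voxel sets are on different grids")
  }
  la <- vs_linear(set_a); lb <- vs_linear(set_b)
  ni <- length(intersect(la, lb))
  na_only <- length(la) - ni
  nb_only <- length(lb) - ni
  pct <- if (ni + na_only >= 1L) overlap_percent(ni, ni + na_only) else NA_integer_
  structure(list(n_only_a = na_only, n_only_b = nb_only, n_intersection = ni,
                 percent_of_a = pct,
                 provenance_a = set_a$provenance, provenance_b = set_b$provenance),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> A-only %d | intersection %d | B-only %d (%s%% of A in B)\n",
              x$n_only_a, x$n_intersection, x$n_only_b,
              ifelse(is.na(x$percent_of_a), "-", x$percent_of_a)))
  invisible(x)
}

#' @describeIn overlap_counts Tidy an overlap result into a one-row tibble.
#' @param x An `overlap_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.overlap_result <- function(x, ...) {
  tibble(n_only_a = x$n_only_a, n_intersection = x$n_intersection,
         n_only_b = x$n_only_b, percent_of_a = x$percent_of_a)
}

#' Split a caudate mask into head/body and tail at a coronal plane
#'
#' A voxel belongs to the head/body when its world y coordinate is strictly
#' greater than `y_boundary_mm` (anterior); voxels at or behind the plane
#' form the tail. The two outputs partition the input mask.
#'
#' @param caudate_mask Nonempty 3D logical array.
#' @param affine 4x4 voxel-to-world matrix (1-based voxel indices).
#' @param y_boundary_mm Coronal boundary in mm (default 2, the approximate
#'   position of the interventricular foramina of Monro in MNI space).
#' @return List with logical arrays `headbody` and `tail`.
#' @export
split_caudate <- function(caudate_mask, affine, y_boundary_mm = 2) {
  if (!any(caudate_mask)) abort("caudate mask is empty")
  if (abs(det(affine)) < .Machine$double.eps) abort("affine is not invertible")
  ijk <- which_ijk(caudate_mask)
  y <- voxel_to_world(ijk, affine)[, 2]
  headbody <- array(FALSE, dim(caudate_mask))
  tail <- array(FALSE, dim(caudate_mask))
  lin <- ijk_to_linear(ijk, dim(caudate_mask))
  headbody[lin[y > y_boundary_mm]] <- TRUE
  tail[lin[y <= y_boundary_mm]] <- TRUE
  list(headbody = headbody, tail = tail)
}

#' Chi-square test comparing overlap proportions of two regions
#'
#' Pearson chi-square on the 2x2 table of (overlap, non-overlap) counts,
#' without continuity correction by default:
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1.
#'
#' @param region1_counts,region2_counts Length-2 vectors
#'   `(overlap, non_overlap)` for each region.
#' @param correct Apply the Yates continuity correction.
#' @return A one-row tibble: `chi2`, `p`, `df`, the two overlap
#'   proportions, and `higher` naming the region with the larger
#'   proportion (`"tie"` when equal).
#' @export
chi_square_overlap <- function(region1_counts, region2_counts,
                               correct = FALSE) {
  a <- as.numeric(region1_counts[1]); b <- as.numeric(region1_counts[2])
  c_ <- as.numeric(region2_counts[1]); d <- as.numeric(region2_counts[2])
  counts <- c(a, b, c_, d)
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("counts must be finite and nonnegative")
  }
  if (a + b < 1 || c_ + d < 1) abort("both row totals must be at least 1")
  if (a + c_ == 0 || b + d == 0) {
    abort("a column marginal total is zero: chi-square undefined")
  }
  n <- sum(counts)
  num <- abs(a * d - b * c_)
  if (correct) num <- max(0, num - n / 2)
  chi2 <- n * num^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  p1 <- a / (a + b); p2 <- c_ / (c_ + d)
  tibble(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE), df = 1L,
         prop_region1 = p1, prop_region2 = p2,
         higher = ifelse(p1 > p2, "region1", ifelse(p2 > p1, "region2", "tie")))
}
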