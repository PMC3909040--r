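#' Sample Pearson correlation of two series
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   positive variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3L) abort("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: an input has zero variance")
  }
  min(1, max(-1, stats::cor(x, y)))
}

#' Fisher z transformation of a correlation
#'
#' `atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilising
#' transform applied to every correlation map before group statistics.
#'
#' @param r Correlation value(s).
#' @param clamp When `TRUE`, values with `|r| >= 1` are clamped to
#'   `1 - 1e-7` in magnitude (with a warning) instead of erroring.
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r, clamp = FALSE) {
  bad <- abs(r) >= 1
  if (any(bad)) {
    if (!clamp) abort("|r| >= 1: Fisher z undefined (set `clamp = TRUE` to clamp)")
    warn(sprintf("%d correlation(s) with |r| >= 1 clamped before Fisher transform",
                 sum(bad)))
    r[bad] <- sign(r[bad]) * (1 - 1e-7)
  }
  atanh(r)
}

#' Construct a connectivity map
#'
#' @param z 3D array of Fisher z values.
#' @param valid 3D logical array marking voxels with a defined z value.
#' @param subject_id,session,drug,seed_name Provenance metadata.
#' @return A `connectivity_map` object.
#' @export
connectivity_map <- function(z, valid, subject_id = NA_character_,
                             session = NA_integer_, drug = NA_character_,
                             seed_name = "seed") {
  stopifnot(identical(dim(z), dim(valid)))
  if (any(!is.finite(z[valid]))) abort("z must be finite on valid voxels")
  structure(list(z = z, valid = valid, subject_id = subject_id,
                 session = session, drug = drug, seed_name = seed_name),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("<connectivity_map> %s ses%s (%s), seed '%s': %d/%d valid voxels\n",
              x$subject_id, x$session, x$drug, x$seed_name,
              sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Seed-based connectivity map of one run
#'
#' Correlates the mean seed time series with every voxel series inside the
#' brain mask and Fisher-transforms the result. Voxels with zero temporal
#' variance are marked invalid rather than silently zeroed; correlations at
#' or beyond |r| = 1 follow the clamp policy.
#'
#' @param run A (preprocessed) `bold_run`.
#' @param seed_mask 3D logical mask of the seed region (nonempty).
#' @param brain_mask 3D logical mask of voxels to map (nonempty).
#' @param clamp When `TRUE` (default), |r| >= 1 voxels are clamped to the
#'   largest representable correlation and kept valid (with a warning);
#'   when `FALSE` they are marked invalid.
#' @param seed_name Label stored in the map's provenance.
#' @return A `connectivity_map`.
#' @export
seed_connectivity_map <- function(run, seed_mask, brain_mask, clamp = TRUE,
                                  seed_name = "midbrain") {
  stopifnot(inherits(run, "bold_run"))
  d <- dim(run$data)
  if (!identical(dim(seed_mask), d[1:3]) || !identical(dim(brain_mask), d[1:3])) {
    abort("masks must be on the run's grid")
  }
  if (!any(seed_mask)) abort("seed mask is empty")
  if (!any(brain_mask)) abort("brain mask is empty")
  s <- extract_mean_timeseries(run, seed_mask)
  if (sd(s) == 0) abort("seed mean series has zero variance")
  nt <- d[4]
  idx <- which(brain_mask)
  X <- matrix(run$data, prod(d[1:3]), nt)[idx, , drop = FALSE]
  Xc <- X - rowMeans(X)
  sc <- s - mean(s)
  ssd <- sqrt(rowSums(Xc^2))
  ok <- ssd > 0
  r <- rep(NA_real_, length(idx))
  r[ok] <- drop(Xc[ok, , drop = FALSE] %*% sc) / (ssd[ok] * sqrt(sum(sc^2)))
  r[ok] <- pmin(1, pmax(-1, r[ok]))

  at_bound <- ok & abs(r) >= 1 - 1e-12
  if (any(at_bound, na.rm = TRUE)) {
    if (clamp) {
      warn(sprintf("%d voxel(s) with |r| >= 1 clamped", sum(at_bound)))
      r[at_bound] <- sign(r[at_bound]) * (1 - 1e-7)
    } else {
      ok[at_bound] <- FALSE
    }
  }
  z <- array(NA_real_, d[1:3])
  valid <- array(FALSE, d[1:3])
  z[idx[ok]] <- atanh(r[ok])
  valid[idx[ok]] <- TRUE
  connectivity_map(z, valid, subject_id = run$subject_id,
                   session = run$session, drug = run$drug,
                   seed_name = seed_name)
}
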