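#' Region names used by the synthetic phantom
#'
#' Integer label codes for the regions of a [make_phantom_geometry()] label
#' volume. `0` is background (outside the head).
#'
#' @format Named integer vector.
#' @export
phantom_regions <- c(
  midbrain_seed    = 1L,
  caudate_headbody = 2L,
  caudate_tail     = 3L,
  putamen          = 4L,
  ventral_striatum = 5L,
  white_matter     = 6L,
  csf              = 7L,
  other_brain      = 8L
)

#' Ground-truth voxel classes planted in the caudate
#'
#' @format Named integer vector: `null` voxels carry no seed coupling,
#'   `connected_constant` voxels have the same planted correlation in every
#'   design cell, `dopaminergic_invertedU` voxels follow the inverted-U
#'   cell pattern of the [effect_spec()].
#' @export
gt_classes <- c(
  null                   = 1L,
  connected_constant     = 2L,
  dopaminergic_invertedU = 3L
)

#' Default region layout for the synthetic phantom
#'
#' Axis-aligned boxes (1-based inclusive index ranges) for each labelled
#' region. The caudate head/body box sits anterior (larger `j`) to the tail
#' box so that the default world-coordinate split at y = 2 mm separates them
#' exactly. `other_brain` is the special value `"fill"`: every voxel inside
#' `brain_box` not claimed by another region.
#'
#' @param shape Grid dimensions the spec must fit into.
#' @return Named list of boxes suitable for [make_phantom_geometry()].
#' @export
default_region_spec <- function(shape = c(20L, 24L, 10L)) {
  list(
    midbrain_seed    = list(i = c(9L, 11L),  j = c(3L, 5L),   k = c(4L, 5L)),
    caudate_tail     = list(i = c(4L, 9L),   j = c(9L, 12L),  k = c(5L, 8L)),
    caudate_headbody = list(i = c(4L, 9L),   j = c(13L, 20L), k = c(5L, 8L)),
    putamen          = list(i = c(12L, 17L), j = c(11L, 18L), k = c(4L, 7L)),
    ventral_striatum = list(i = c(10L, 11L), j = c(14L, 16L), k = c(2L, 3L)),
    white_matter     = list(i = c(2L, 17L),  j = c(2L, 22L),  k = c(9L, 10L)),
    csf              = list(i = c(2L, 17L),  j = c(2L, 22L),  k = c(1L, 1L)),
    other_brain      = "fill"
  )
}

box_mask <- function(box, shape) {
  m <- array(FALSE, shape)
  m[box$i[1]:box$i[2], box$j[1]:box$j[2], box$k[1]:box$k[2]] <- TRUE
  m
}

#' Construct a synthetic phantom geometry
#'
#' Builds a labelled 3D grid standing in for the anatomical ROIs of the
#' analysis: a midbrain seed, caudate head/body and tail, putamen, ventral
#' striatum, white matter and CSF nuisance slabs, and generic brain tissue.
#' The voxel-to-world affine is chosen so that the boundary between the two
#' caudate boxes falls exactly at world y = `y_boundary` mm, mirroring the
#' coronal head/body-vs-tail split used downstream.
#'
#' @param shape Integer grid dimensions (x, y, z).
#' @param voxel_size Voxel edge lengths in mm. Defaults to the anisotropic
#'   1.8 x 1.8 x 3.45 mm acquisition grid.
#' @param region_spec Named list of boxes (see [default_region_spec()]).
#'   Entries other than `other_brain = "fill"` must be pairwise disjoint.
#' @param brain_box Box delimiting the head; used only when
#'   `region_spec$other_brain == "fill"`. Default: the whole grid minus a
#'   one-voxel frame in x and y.
#' @param world_origin World coordinates (mm) of voxel (1,1,1). When `NULL`
#'   it is chosen to centre x/z and to place the caudate box boundary at
#'   `y_boundary`.
#' @param y_boundary Coronal split coordinate in mm (head/body anterior).
#' @return A `phantom_geometry` object: list with `labels` (3D integer
#'   array), `shape`, `voxel_size`, `affine` (4x4, maps 1-based voxel
#'   indices to mm) and `y_boundary`.
#' @export
make_phantom_geometry <- function(shape = c(20L, 24L, 10L),
                                  voxel_size = c(1.8, 1.8, 3.45),
                                  region_spec = default_region_spec(shape),
                                  brain_box = NULL,
                                  world_origin = NULL,
                                  y_boundary = 2) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), length(voxel_size) == 3L,
            all(voxel_size > 0))
  fill_other <- identical(region_spec$other_brain, "fill")
  boxes <- region_spec[!vapply(region_spec, identical, logical(1), "fill")]
  if (!all(names(boxes) %in% names(phantom_regions))) {
    abort(sprintf("unknown region(s): %s",
                  paste(setdiff(names(boxes), names(phantom_regions)),
                        collapse = ", ")))
  }
  for (nm in names(boxes)) {
    b <- boxes[[nm]]
    lo <- c(b$i[1], b$j[1], b$k[1]); hi <- c(b$i[2], b$j[2], b$k[2])
    if (any(lo < 1L) || any(hi > shape) || any(lo > hi)) {
      abort(sprintf("region '%s' extent does not fit inside shape [%s]",
                    nm, paste(shape, collapse = " x ")))
    }
  }
  # pairwise disjointness, reported by name
  masks <- lapply(boxes, box_mask, shape = shape)
  nms <- names(masks)
  if (length(nms) > 1L) {
    for (p in seq_len(length(nms) - 1L)) {
      for (q in seq(p + 1L, length(nms))) {
        if (any(masks[[p]] & masks[[q]])) {
          abort(sprintf("regions '%s' and '%s' overlap", nms[p], nms[q]))
        }
      }
    }
  }
  if (is.null(world_origin)) {
    ctr <- (shape + 1) / 2
    oy <- -voxel_size[2] * (ctr[2] - 1)
    if (!is.null(boxes$caudate_tail) && !is.null(boxes$caudate_headbody)) {
      j_split <- (boxes$caudate_tail$j[2] + boxes$caudate_headbody$j[1]) / 2
      oy <- y_boundary - voxel_size[2] * (j_split - 1)
    }
    world_origin <- c(-voxel_size[1] * (ctr[1] - 1), oy,
                      -voxel_size[3] * (ctr[3] - 1))
  }
  affine <- diag(c(voxel_size, 1))
  affine[1:3, 4] <- world_origin - voxel_size  # maps 1-based indices

  labels <- array(0L, shape)
  if (fill_other) {
    if (is.null(brain_box)) {
      brain_box <- list(i = c(min(2L, shape[1]), max(1L, shape[1] - 1L)),
                        j = c(min(2L, shape[2]), max(1L, shape[2] - 1L)),
                        k = c(1L, shape[3]))
    }
    labels[box_mask(brain_box, shape)] <- phantom_regions[["other_brain"]]
  }
  for (nm in names(masks)) labels[masks[[nm]]] <- phantom_regions[[nm]]

  geom <- structure(
    list(labels = labels, shape = shape, voxel_size = voxel_size,
         affine = affine, y_boundary = y_boundary),
    class = "phantom_geometry")

  present <- intersect(names(phantom_regions),
                       c(names(boxes), if (fill_other) "other_brain"))
  for (nm in present) {
    if (!any(labels == phantom_regions[[nm]])) {
      abort(sprintf("region '%s' is empty", nm))
    }
  }
  # caudate boxes must sit on opposite sides of the y boundary
  if (all(c("caudate_headbody", "caudate_tail") %in% present)) {
    yh <- voxel_to_world(which_ijk(labels == phantom_regions[["caudate_headbody"]]),
                         affine)[, 2]
    yt <- voxel_to_world(which_ijk(labels == phantom_regions[["caudate_tail"]]),
                         affine)[, 2]
    if (min(yh) <= y_boundary || max(yt) > y_boundary) {
      abort("caudate head/body and tail are not separated by the y boundary")
    }
  }
  geom
}

# 1-based (i,j,k) coordinates of TRUE voxels
which_ijk <- function(mask) {
  w <- which(mask)
  linear_to_ijk(w, dim(mask))
}

#' Logical mask of one or more phantom regions
#'
#' @param geometry A `phantom_geometry`.
#' @param regions Character vector of region names (see [phantom_regions]).
#' @return 3D logical array.
#' @export
region_mask <- function(geometry, regions) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  bad <- setdiff(regions, names(phantom_regions))
  if (length(bad)) abort(sprintf("unknown region(s): %s", paste(bad, collapse = ", ")))
  array(geometry$labels %in% phantom_regions[regions], geometry$shape)
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat("<phantom_geometry> ", paste(x$shape, collapse = " x "),
      " voxels of ", paste(format(x$voxel_size), collapse = " x "), " mm\n", sep = "")
  tab <- table(factor(x$labels[x$labels > 0], levels = phantom_regions,
                      labels = names(phantom_regions)))
  for (nm in names(tab)) cat(sprintf("  %-18s %5d voxels\n", nm, tab[[nm]]))
  invisible(x)
}

#' Planted effect specification
#'
#' Describes the connectivity structure planted in the caudate of a
#' synthetic cohort. `r_cells` gives the population seed-voxel correlation
#' in each design cell, in canonical order (low-span placebo, low-span drug,
#' high-span placebo, high-span drug). The default is an inverted-U pattern:
#' the dopamine agonist raises midbrain-caudate coupling in low-span
#' subjects and lowers it in high-span subjects.
#'
#' @param r_cells Numeric length-4 vector of planted correlations, all in
#'   (-1, 1), canonical cell order.
#' @param frac_dopaminergic Fraction of caudate voxels planted with the
#'   inverted-U pattern (grown as one connected block).
#' @param frac_constant Fraction of caudate voxels with constant (cell-
#'   independent) seed coupling `r_constant`.
#' @param r_constant Planted correlation for connected-but-unmodulated
#'   voxels.
#' @param noise_sd Standard deviation of the white voxel noise.
#' @param confound_weight Coupling of gray-matter voxels to the shared
#'   physiological confound series.
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(r_cells = c(low_placebo = 0.1, low_drug = 0.5,
                                    high_placebo = 0.5, high_drug = 0.1),
                        frac_dopaminergic = 0.15,
                        frac_constant = 0.45,
                        r_constant = 0.5,
                        noise_sd = 1,
                        confound_weight = 0.3) {
  r_cells <- unname(as.numeric(r_cells))
  if (length(r_cells) != 4L || any(!is.finite(r_cells)) || any(abs(r_cells) >= 1)) {
    abort("`r_cells` must be four correlations strictly inside (-1, 1)")
  }
  if (abs(r_constant) >= 1) abort("`r_constant` must lie strictly inside (-1, 1)")
  if (frac_dopaminergic < 0 || frac_constant < 0 ||
      frac_dopaminergic + frac_constant > 1) {
    abort("class fractions must be nonnegative and sum to at most 1")
  }
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative")
  structure(list(r_cells = stats::setNames(r_cells, design_cells()),
                 frac_dopaminergic = frac_dopaminergic,
                 frac_constant = frac_constant,
                 r_constant = r_constant,
                 noise_sd = noise_sd,
                 confound_weight = confound_weight),
            class = "effect_spec")
}

#' Canonical design-cell order
#' @return Character vector of the four drug-by-span cells.
#' @export
design_cells <- function() {
  c("low_placebo", "low_drug", "high_placebo", "high_drug")
}

#' Does an effect spec encode an inverted-U pattern?
#'
#' TRUE when the drug raises the planted correlation for low-span subjects
#' and lowers it for high-span subjects.
#' @param effect An `effect_spec`.
#' @export
is_inverted_u <- function(effect) {
  r <- effect$r_cells
  r[[2]] > r[[1]] && r[[3]] > r[[4]]
}

#' Simulate a cohort design table
#'
#' One row per subject-session: `n_low + n_high` subjects, each scanned in a
#' placebo and a drug session with counterbalanced order. Span scores are
#' drawn uniformly on 1.5-3.4 (low group) and 3.5-5.5 (high group);
#' groups are assigned with [assign_span_groups()] at `span_cutoff`.
#'
#' @param n_low,n_high Subjects per span group.
#' @param rng_seed Integer seed; the table is fully reproducible.
#' @param span_cutoff Score at or above which a subject is high-span.
#' @return A tibble with columns `subject_id`, `session`, `drug`,
#'   `span_score`, `span_group`.
#' @export
cohort_design <- function(n_low = 8L, n_high = 8L, rng_seed = 1L,
                          span_cutoff = 3.5) {
  stopifnot(n_low >= 1L, n_high >= 1L)
  n <- n_low + n_high
  subj <- sprintf("sub%02d", seq_len(n))
  scores <- with_seed(derive_seed(rng_seed, "design"), {
    c(runif(n_low, 1.5, 3.4), runif(n_high, 3.5, 5.5))
  })
  groups <- assign_span_groups(scores, cutoff = span_cutoff)
  drug_first <- rep(c(TRUE, FALSE), length.out = n)  # counterbalanced order
  per_subj <- tibble(
    subject_id = subj, span_score = scores, span_group = groups,
    drug_first = drug_first)
  design <- tidyr::crossing(per_subj, session = 1:2)
  design$drug <- ifelse((design$session == 1L) == design$drug_first,
                        "bromocriptine", "placebo")
  design <- design[order(design$subject_id, design$session),
                   c("subject_id", "session", "drug", "span_score", "span_group")]
  attr(design, "span_cutoff") <- span_cutoff
  validate_cohort_design(design)
}

#' Validate a cohort design table
#'
#' Checks the schema and the design invariants: every subject has exactly
#' two sessions with distinct drug labels, drug labels are known, and
#' `span_group` is consistent with the cutoff.
#'
#' @param design A data frame of subject-sessions.
#' @param span_cutoff Cutoff used to check `span_group` consistency.
#' @return The design as a validated tibble (invisibly classed).
#' @export
validate_cohort_design <- function(design,
                                   span_cutoff = attr(design, "span_cutoff") %||% 3.5) {
  design <- as_tibble(design)
  req <- c("subject_id", "session", "drug", "span_score", "span_group")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols)) {
    abort(sprintf("design is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  bad_drug <- setdiff(unique(design$drug), c("placebo", "bromocriptine"))
  if (length(bad_drug)) {
    abort(sprintf("unknown drug label(s): %s", paste(bad_drug, collapse = ", ")))
  }
  dup <- design |> dplyr::count(.data$subject_id, .data$session) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf("duplicate subject-session row(s): %s",
                  paste(dup$subject_id, dup$session, sep = "/", collapse = ", ")))
  }
  per <- design |> dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_sess = dplyr::n(),
                     n_drug = dplyr::n_distinct(.data$drug), .groups = "drop")
  bad <- per |> dplyr::filter(.data$n_sess != 2L | .data$n_drug != 2L)
  if (nrow(bad)) {
    abort(sprintf("subject(s) without two sessions under distinct drugs: %s",
                  paste(bad$subject_id, collapse = ", ")))
  }
  expected <- assign_span_groups(design$span_score, cutoff = span_cutoff)
  if (!all(expected == design$span_group)) {
    abort(sprintf("span_group inconsistent with the %.3g cutoff for: %s",
                  span_cutoff,
                  paste(unique(design$subject_id[expected != design$span_group]),
                        collapse = ", ")))
  }
  attr(design, "span_cutoff") <- span_cutoff
  design
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate code under a temporary RNG seed, restoring global state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# nv independent band-limited unit-variance series using the current RNG
# state; exact spectral control by FFT masking of white noise
band_limited_matrix <- function(n, tr, band, nv) {
  f <- (seq_len(n) - 1) / (n * tr)
  f_fold <- pmin(f, 1 / tr - f)
  keep <- f_fold >= band[1] & f_fold <= band[2]
  if (!any(keep)) abort("no DFT frequencies fall inside the requested band")
  W <- stats::mvfft(matrix(rnorm(n * nv), n, nv))
  W[!keep, ] <- 0 + 0i
  X <- Re(stats::mvfft(W, inverse = TRUE)) / n
  X <- sweep(X, 2, colMeans(X))
  sweep(X, 2, apply(X, 2, sd), `/`)
}

#' Simulate a band-limited BOLD-like signal
#'
#' Generates a zero-mean, unit-variance time series whose spectral power is
#' confined to the given frequency band, by FFT masking of white Gaussian
#' noise followed by renormalisation. This emulates resting-state BOLD
#' fluctuations inside the standard 0.009-0.08 Hz analysis band.
#'
#' @param n_timepoints Number of samples.
#' @param tr Repetition time in seconds (sampling interval).
#' @param band Length-2 Hz vector `(low, high)`; `high` must be below the
#'   Nyquist frequency `1/(2 tr)`.
#' @param rng_seed Integer seed; output is reproducible.
#' @return Numeric vector of length `n_timepoints`.
#' @export
simulate_band_limited_signal <- function(n_timepoints, tr,
                                         band = c(0.009, 0.08), rng_seed) {
  stopifnot_scalar(tr, "tr")
  if (n_timepoints < 8L) abort("`n_timepoints` must be at least 8")
  check_band(band, tr)
  with_seed(rng_seed, band_limited_matrix(n_timepoints, tr, band, 1L)[, 1])
}

check_band <- function(band, tr) {
  if (length(band) != 2L || any(!is.finite(band))) {
    abort("`band` must be two finite frequencies (Hz)")
  }
  nyq <- 1 / (2 * tr)
  if (band[1] <= 0 || band[1] >= band[2] || band[2] >= nyq) {
    abort(sprintf(
      "band (%g, %g) Hz invalid: need 0 < low < high < Nyquist = %g Hz",
      band[1], band[2], nyq))
  }
  invisible(band)
}

#' Population correlation of the linear signal model
#'
#' For a voxel generated as `a * seed + b * confound + noise` with mutually
#' independent components, the population Pearson correlation between the
#' voxel and the seed is
#' `a * sigma_s / sqrt(a^2 sigma_s^2 + b^2 sigma_c^2 + sigma_e^2)`.
#'
#' @param a Seed coupling weight.
#' @param b Confound coupling weight.
#' @param sigma_s,sigma_c,sigma_e Standard deviations of seed, confound and
#'   noise components.
#' @return The planted correlation.
#' @export
planted_correlation <- function(a, b, sigma_s = 1, sigma_c = 1, sigma_e = 1) {
  denom2 <- a^2 * sigma_s^2 + b^2 * sigma_c^2 + sigma_e^2
  if (denom2 <= 0) abort("all variance components are zero: correlation undefined")
  a * sigma_s / sqrt(denom2)
}

# invert planted_correlation for the seed coupling a; errors when the
# requested r is unreachable (no non-seed variance to dilute the signal)
solve_seed_coupling <- function(r, b, sigma_c = 1, sigma_e = 1, sigma_s = 1,
                                label = "r") {
  if (abs(r) >= 1) abort(sprintf("planted correlation %s = %g not in (-1, 1)", label, r))
  other <- b^2 * sigma_c^2 + sigma_e^2
  if (other <= 0 && r != 0) {
    abort(sprintf(
      "planted correlation %s = %g unreachable: noise_sd and confound_weight are both zero",
      label, r))
  }
  r / sqrt(1 - r^2) * sqrt(other) / sigma_s
}

# deterministic connected growth over a voxel graph (face adjacency)
grow_connected <- function(candidates_lin, shape, n_target, start_lin) {
  inset <- logical(prod(shape)); inset[candidates_lin] <- TRUE
  chosen <- integer(0); visited <- logical(prod(shape))
  queue <- start_lin; visited[start_lin] <- TRUE
  offs <- neighbor_offsets(6L)
  while (length(chosen) < n_target) {
    if (!length(queue)) {
      remaining <- candidates_lin[!(candidates_lin %in% chosen) &
                                    !visited[candidates_lin]]
      if (!length(remaining)) break
      queue <- remaining[1]; visited[queue] <- TRUE
    }
    v <- queue[1]; queue <- queue[-1]
    chosen <- c(chosen, v)
    ijk <- linear_to_ijk(v, shape)
    nb <- sweep(offs, 2, as.numeric(ijk), `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] & nb[, 2] >= 1 &
      nb[, 2] <= shape[2] & nb[, 3] >= 1 & nb[, 3] <= shape[3]
    nb_lin <- ijk_to_linear(nb[ok, , drop = FALSE], shape)
    nb_lin <- nb_lin[inset[nb_lin] & !visited[nb_lin]]
    visited[nb_lin] <- TRUE
    queue <- c(queue, sort(nb_lin))
  }
  sort(chosen)
}

#' Simulate a synthetic BOLD cohort with planted connectivity
#'
#' Generates one 4D BOLD run per subject-session on the phantom grid. Every
#' voxel series is a linear mixture of a seed signal (shared by the midbrain
#' seed region), a run-wide physiological confound (carried strongly by the
#' white-matter and CSF slabs) and white Gaussian noise. Caudate voxels are
#' partitioned into ground-truth classes: a connected block of
#' `dopaminergic_invertedU` voxels whose population seed correlation follows
#' `effect$r_cells` across the drug-by-span design cells, a block of
#' `connected_constant` voxels with cell-independent correlation
#' `effect$r_constant`, and `null` voxels with no seed coupling. Seed
#' couplings are solved in closed form from [planted_correlation()].
#'
#' @param geometry A [make_phantom_geometry()] object.
#' @param design A validated [cohort_design()] table.
#' @param effect An [effect_spec()].
#' @param n_timepoints Samples per run (default 150, i.e. 5 min at TR 2 s).
#' @param tr Repetition time in seconds.
#' @param rng_seed Integer master seed. Per-run child streams are derived by
#'   stable hashing of subject and session identifiers, so any subset of
#'   runs is reproducible independently of generation order.
#' @param band Frequency band of the generated signals (Hz).
#' @return A `bold_cohort`: list with `runs` (named list of `bold_run`),
#'   `design`, `geometry`, and `ground_truth` (class map, effect, seed).
#' @export
simulate_cohort <- function(geometry, design, effect = effect_spec(),
                            n_timepoints = 150L, tr = 2,
                            rng_seed, band = c(0.009, 0.08)) {
  stopifnot(inherits(geometry, "phantom_geometry"), inherits(effect, "effect_spec"))
  design <- validate_cohort_design(design)
  check_band(band, tr)
  if (n_timepoints < 8L) abort("`n_timepoints` must be at least 8")

  shape <- geometry$shape
  nvox <- prod(shape)
  lab <- as.integer(geometry$labels)
  caud <- which(lab %in% phantom_regions[c("caudate_headbody", "caudate_tail")])
  if (!length(caud)) abort("geometry has no caudate voxels")

  # couplings per class x cell; errors name the offending cell
  sd_e <- effect$noise_sd; b_gm <- effect$confound_weight
  a_cells <- vapply(seq_along(effect$r_cells), function(i) {
    solve_seed_coupling(effect$r_cells[[i]], b_gm, sigma_e = sd_e,
                        label = names(effect$r_cells)[i])
  }, numeric(1))
  names(a_cells) <- names(effect$r_cells)
  a_const <- solve_seed_coupling(effect$r_constant, b_gm, sigma_e = sd_e,
                                 label = "r_constant")

  # ground-truth class map: connected blocks grown from seeded starts
  n_dopa <- round(effect$frac_dopaminergic * length(caud))
  n_const <- round(effect$frac_constant * length(caud))
  picks <- with_seed(derive_seed(rng_seed, "ground_truth"), {
    dopa <- if (n_dopa > 0)
      grow_connected(caud, shape, n_dopa, sample(caud, 1L)) else integer(0)
    rest <- setdiff(caud, dopa)
    const <- if (n_const > 0 && length(rest))
      grow_connected(rest, shape, min(n_const, length(rest)), sample(rest, 1L))
    else integer(0)
    list(dopa = dopa, const = const)
  })
  class_map <- array(0L, shape)
  class_map[caud] <- gt_classes[["null"]]
  class_map[picks$const] <- gt_classes[["connected_constant"]]
  class_map[picks$dopa] <- gt_classes[["dopaminergic_invertedU"]]

  # per-voxel couplings independent of cell
  is_seed <- lab == phantom_regions[["midbrain_seed"]]
  is_nuis <- lab %in% phantom_regions[c("white_matter", "csf")]
  is_brain_other <- lab %in% phantom_regions[c("putamen", "ventral_striatum",
                                               "other_brain")]
  is_caud <- logical(nvox); is_caud[caud] <- TRUE
  b_v <- numeric(nvox)
  b_v[is_nuis] <- 1
  b_v[is_brain_other | is_caud] <- b_gm
  sd_v <- numeric(nvox)
  sd_v[is_seed] <- 0.1
  sd_v[is_nuis] <- 0.2
  sd_v[is_brain_other] <- sd_e
  sd_v[caud] <- sd_e
  a_base <- numeric(nvox)
  a_base[is_seed] <- 1
  a_base[picks$const] <- a_const

  runs <- list()
  for (row in seq_len(nrow(design))) {
    subj <- design$subject_id[row]; sess <- design$session[row]
    drug <- design$drug[row]; grp <- design$span_group[row]
    cell <- paste(grp, ifelse(drug == "placebo", "placebo", "drug"), sep = "_")
    a_v <- a_base
    a_v[picks$dopa] <- a_cells[[cell]]
    child <- derive_seed(rng_seed, subj, sprintf("session%d", sess))
    X <- with_seed(child, {
      SC <- band_limited_matrix(n_timepoints, tr, band, 2L)
      eps <- matrix(rnorm(n_timepoints * nvox), n_timepoints, nvox)
      tcrossprod(SC[, 1], a_v) + tcrossprod(SC[, 2], b_v) +
        sweep(eps, 2, sd_v, `*`)
    })
    run <- bold_run(array(t(X), c(shape, n_timepoints)), tr = tr,
                    affine = geometry$affine, subject_id = subj,
                    session = sess, drug = drug)
    runs[[sprintf("%s_ses%d", subj, sess)]] <- run
  }

  structure(
    list(runs = runs, design = design, geometry = geometry,
         ground_truth = structure(
           list(class_map = class_map, effect = effect, rng_seed = rng_seed,
                n_timepoints = n_timepoints, tr = tr, band = band),
           class = "ground_truth")),
    class = "bold_cohort")
}

#' Tidy the planted ground truth of a cohort
#'
#' @param cohort A `bold_cohort`.
#' @return Tibble with one row per caudate voxel: indices and class label.
#' @export
ground_truth_table <- function(cohort) {
  stopifnot(inherits(cohort, "bold_cohort"))
  cm <- cohort$ground_truth$class_map
  idx <- which(cm > 0L)
  ijk <- linear_to_ijk(idx, dim(cm))
  tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
         class = names(gt_classes)[match(cm[idx], gt_classes)])
}

#' @export
print.bold_cohort <- function(x, ...) {
  cat("<bold_cohort> ", length(x$runs), " runs, ",
      dplyr::n_distinct(x$design$subject_id), " subjects\n", sep = "")
  cat("  grid ", paste(x$geometry$shape, collapse = " x "),
      ", ", x$ground_truth$n_timepoints, " timepoints, TR ",
      x$ground_truth$tr, " s\n", sep = "")
  tab <- table(ground_truth_table(x)$class)
  cat("  caudate ground truth:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
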