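#' Pipeline configuration
#'
#' Collects every tunable setting of the end-to-end analysis, prefilled
#' with the standard values: 0.009-0.08 Hz band, 4 mm FWHM smoothing,
#' quadratic contrast weights (-0.5, 0.5, 0.5, -0.5), q = 0.05 FDR with a
#' 20-voxel cluster extent, caudate split at y = 2 mm, span cutoff 3.5.
#'
#' @param rng_seed Integer master seed (required; drives simulation).
#' @param input_dir Optional directory of a cohort written by
#'   [write_cohort()]; when `NULL` a cohort is simulated.
#' @param output_dir Optional directory for artifacts and the report.
#' @param n_low,n_high Simulated subjects per span group.
#' @param n_timepoints,tr Run length and repetition time (s).
#' @param effect An [effect_spec()] for simulation.
#' @param geometry Optional [make_phantom_geometry()]; default geometry
#'   otherwise.
#' @param band Temporal filter band (Hz).
#' @param fwhm_mm Spatial smoothing FWHM (mm); 0 disables smoothing.
#' @param contrast Quadratic contrast weights (canonical cell order).
#' @param q FDR level.
#' @param min_cluster Cluster-extent threshold (voxels).
#' @param connectivity Cluster neighbourhood (6, 18 or 26).
#' @param uncorrected_p Loose threshold for the Venn overlap sets.
#' @param y_boundary Caudate head/body vs tail split (mm).
#' @param span_cutoff Inclusive high-span cutoff.
#' @return A `run_config` list, validated against every stage's
#'   preconditions.
#' @export
run_config <- function(rng_seed,
                       input_dir = NULL, output_dir = NULL,
                       n_low = 8L, n_high = 8L,
                       n_timepoints = 150L, tr = 2,
                       effect = effect_spec(), geometry = NULL,
                       band = c(0.009, 0.08), fwhm_mm = 4,
                       contrast = c(-0.5, 0.5, 0.5, -0.5),
                       q = 0.05, min_cluster = 20L, connectivity = 6,
                       uncorrected_p = 0.05,
                       y_boundary = 2, span_cutoff = 3.5) {
  stopifnot_scalar(rng_seed, "rng_seed")
  check_band(band, tr)
  if (fwhm_mm < 0) abort("`fwhm_mm` must be nonnegative")
  if (length(contrast) != 4L || abs(sum(contrast)) > 1e-12) {
    abort("`contrast` must be four weights summing to 0")
  }
  if (q <= 0 || q >= 1) abort("`q` must lie in (0, 1)")
  if (uncorrected_p <= 0 || uncorrected_p >= 1) {
    abort("`uncorrected_p` must lie in (0, 1)")
  }
  if (min_cluster < 1L) abort("`min_cluster` must be at least 1")
  neighbor_offsets(connectivity)
  if (n_timepoints < 8L) abort("`n_timepoints` must be at least 8")
  stopifnot(inherits(effect, "effect_spec"))
  if (!is.null(geometry)) stopifnot(inherits(geometry, "phantom_geometry"))
  structure(list(rng_seed = as.integer(rng_seed), input_dir = input_dir,
                 output_dir = output_dir, n_low = as.integer(n_low),
                 n_high = as.integer(n_high),
                 n_timepoints = as.integer(n_timepoints), tr = tr,
                 effect = effect, geometry = geometry, band = band,
                 fwhm_mm = fwhm_mm, contrast = contrast, q = q,
                 min_cluster = as.integer(min_cluster),
                 connectivity = as.integer(connectivity),
                 uncorrected_p = uncorrected_p, y_boundary = y_boundary,
                 span_cutoff = span_cutoff),
            class = "run_config")
}

#' Per-subject mean Fisher z over a voxel set
#'
#' @param maps List of `connectivity_map` objects.
#' @param design Validated design table.
#' @param vs A nonempty `voxel_set`.
#' @return Tibble: `subject_id`, `drug`, `span_score`, `span_group`,
#'   `mean_z`.
#' @export
mean_z_by_subject <- function(maps, design, vs) {
  design <- validate_cohort_design(design)
  if (!length(vs)) abort("voxel set is empty")
  lin <- vs_linear(vs)
  rows <- purrr::map_dfr(maps, function(m) {
    tibble(subject_id = m$subject_id, drug = m$drug,
           mean_z = mean(m$z[lin][m$valid[lin]]))
  })
  dplyr::left_join(rows,
                   design |> dplyr::distinct(.data$subject_id, .data$span_score,
                                             .data$span_group),
                   by = "subject_id")
}

#' Cell means of connectivity over a voxel set
#'
#' @inheritParams mean_z_by_subject
#' @return Tibble with one row per canonical design cell: `cell`,
#'   `mean_z`, `se`, `n`.
#' @export
cell_means <- function(maps, design, vs) {
  values <- mean_z_by_subject(maps, design, vs)
  values$cell <- paste(values$span_group,
                       ifelse(values$drug == "placebo", "placebo", "drug"),
                       sep = "_")
  values |>
    dplyr::group_by(cell = factor(.data$cell, levels = design_cells())) |>
    dplyr::summarise(n = dplyr::n(),
                     se = stats::sd(.data$mean_z) / sqrt(dplyr::n()),
                     mean_z = mean(.data$mean_z), .groups = "drop") |>
    dplyr::select("cell", "mean_z", "se", "n")
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, preprocesses every run (band-pass filter,
#' spatial smoothing, white-matter/CSF nuisance regression), computes
#' seed-based Fisher z connectivity maps, then the group statistics: the
#' overall one-sample t map across all sessions, the drug-by-span
#' inverted-U interaction contrast, and the placebo span effect. Voxel sets
#' are thresholded (FDR small-volume corrected on the caudate, plus the
#' loose uncorrected inverted-U set), overlap Venn counts and the caudate
#' head/body-vs-tail chi-square are computed, and span-connectivity
#' correlations are compared between conditions.
#'
#' @param config A [run_config()].
#' @return A `mesoconn_report`: nested list of every result; written to
#'   `config$output_dir` (JSON + text + NIfTI artifacts) when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  # ---- stage: cohort -------------------------------------------------------
  cohort <- if (!is.null(config$input_dir)) {
    read_cohort(config$input_dir)
  } else {
    geom <- config$geometry %||%
      make_phantom_geometry(y_boundary = config$y_boundary)
    design <- cohort_design(config$n_low, config$n_high,
                            rng_seed = config$rng_seed,
                            span_cutoff = config$span_cutoff)
    simulate_cohort(geom, design, config$effect,
                    n_timepoints = config$n_timepoints, tr = config$tr,
                    rng_seed = config$rng_seed, band = config$band)
  }
  geometry <- cohort$geometry
  design <- cohort$design
  seed_mask <- region_mask(geometry, "midbrain_seed")
  wm_mask <- region_mask(geometry, "white_matter")
  csf_mask <- region_mask(geometry, "csf")
  caudate <- region_mask(geometry, c("caudate_headbody", "caudate_tail"))
  brain <- geometry$labels > 0L & !seed_mask

  # ---- stage: preprocess + connectivity ------------------------------------
  pp_runs <- preprocess_runs(cohort$runs, wm_mask, csf_mask,
                             band = config$band, fwhm_mm = config$fwhm_mm)
  maps <- purrr::map(pp_runs, seed_connectivity_map,
                     seed_mask = seed_mask, brain_mask = brain)

  # ---- stage: group statistics ---------------------------------------------
  t_map <- one_sample_t_map(unname(maps))
  inter_map <- interaction_contrast_map(unname(maps), design,
                                        contrast = config$contrast)
  span_map <- span_effect_map(unname(maps), design, drug = "placebo")

  svc <- function(map) small_volume_threshold(
    map, threshold_spec(q = config$q, small_volume_mask = caudate,
                        min_cluster = config$min_cluster,
                        connectivity = config$connectivity,
                        direction = "positive"))
  conn_set <- svc(t_map)
  invu_set <- svc(inter_map)
  span_set <- svc(span_map)
  invu_loose <- uncorrected_threshold(inter_map, config$uncorrected_p,
                                      mask = caudate, direction = "positive")

  # ---- stage: overlap ------------------------------------------------------
  venn_conn <- overlap_counts(conn_set, invu_loose)
  venn_span <- overlap_counts(span_set, invu_loose)
  halves <- split_caudate(caudate, geometry$affine, config$y_boundary)
  conn_mask <- as_mask(conn_set); invu_mask <- as_mask(invu_loose)
  region_tab <- purrr::map_dfr(c("headbody", "tail"), function(rg) {
    m <- halves[[rg]]
    tibble(region = rg, n_voxels = sum(m),
           n_connectivity = sum(m & conn_mask),
           n_invertedU = sum(m & invu_mask),
           n_overlap = sum(m & conn_mask & invu_mask))
  })
  chi <- chi_square_overlap(
    region1_counts = c(region_tab$n_overlap[region_tab$region == "tail"],
                       region_tab$n_voxels[region_tab$region == "tail"] -
                         region_tab$n_overlap[region_tab$region == "tail"]),
    region2_counts = c(region_tab$n_overlap[region_tab$region == "headbody"],
                       region_tab$n_voxels[region_tab$region == "headbody"] -
                         region_tab$n_overlap[region_tab$region == "headbody"]))

  # ---- stage: span correlations over the inverted-U voxels -----------------
  span_result <- NULL
  cells <- NULL
  value_set <- if (length(invu_set)) invu_set else invu_loose
  if (length(value_set)) {
    values <- mean_z_by_subject(unname(maps), design, value_set)
    pl <- values[values$drug == "placebo", ]
    dr <- values[values$drug == "bromocriptine", ]
    cor_pl <- correlate_with_span(pl$mean_z, pl$span_score)
    cor_dr <- correlate_with_span(dr$mean_z, dr$span_score)
    cmp <- compare_correlations(cor_pl$r, cor_pl$n, cor_dr$r, cor_dr$n)
    span_result <- list(placebo = cor_pl, drug = cor_dr, comparison = cmp,
                        values = values)
    cells <- cell_means(unname(maps), design, value_set)
  }

  # ---- stage: ground-truth recovery (synthetic cohorts only) ---------------
  recovery <- NULL
  if (!is.null(cohort$ground_truth)) {
    cm <- cohort$ground_truth$class_map
    dopa <- which(cm == gt_classes[["dopaminergic_invertedU"]])
    nondopa <- which(cm > 0L & cm != gt_classes[["dopaminergic_invertedU"]])
    rec <- vs_linear(invu_set)
    recovery <- tibble(
      n_dopaminergic = length(dopa),
      n_null_caudate = length(nondopa),
      n_recovered = length(rec),
      sensitivity = if (length(dopa)) length(intersect(rec, dopa)) / length(dopa)
      else NA_real_,
      false_positive_rate = if (length(nondopa))
        length(intersect(rec, nondopa)) / length(nondopa) else NA_real_)
  }

  report <- structure(list(
    config = config,
    design = design,
    group_t = list(map = t_map, n_valid = sum(t_map$valid),
                   max_t = suppressWarnings(max(t_map$stat, na.rm = TRUE))),
    interaction = list(map = inter_map, n_valid = sum(inter_map$valid)),
    sets = list(connectivity = conn_set, invertedU = invu_set,
                invertedU_loose = invu_loose, span = span_set),
    venn = list(connectivity_vs_invertedU = venn_conn,
                span_vs_invertedU = venn_span),
    caudate_regions = region_tab,
    chi_square = chi,
    span_correlations = span_result,
    cell_means = cells,
    recovery = recovery,
    maps = maps), class = "mesoconn_report")

  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.mesoconn_report <- function(x, ...) {
  cat("<mesoconn_report>\n")
  cat(sprintf("  group t map: %d valid voxels, max t = %.2f\n",
              x$group_t$n_valid, x$group_t$max_t))
  cat(sprintf("  voxel sets: connectivity %d | invertedU (svc) %d | invertedU (p<%g) %d | span %d\n",
              length(x$sets$connectivity), length(x$sets$invertedU),
              x$config$uncorrected_p, length(x$sets$invertedU_loose),
              length(x$sets$span)))
  v <- x$venn$connectivity_vs_invertedU
  cat(sprintf("  overlap conn vs inverted-U: %d/%d voxels (%s%%)\n",
              v$n_intersection, v$n_intersection + v$n_only_a,
              ifelse(is.na(v$percent_of_a), "-", v$percent_of_a)))
  if (!is.null(x$span_correlations)) {
    cat(sprintf("  span correlation: placebo r = %.3f (p = %.4g), drug r = %.3f (p = %.4g), Z = %.3f\n",
                x$span_correlations$placebo$r, x$span_correlations$placebo$p,
                x$span_correlations$drug$r, x$span_correlations$drug$p,
                x$span_correlations$comparison$z))
  }
  if (!is.null(x$recovery)) {
    cat(sprintf("  recovery: sensitivity %.3f, false-positive rate %.3f\n",
                x$recovery$sensitivity, x$recovery$false_positive_rate))
  }
  invisible(x)
}

report_summary_list <- function(report) {
  v1 <- report$venn$connectivity_vs_invertedU
  v2 <- report$venn$span_vs_invertedU
  out <- list(
    config = config_as_list(report$config),
    group_t = list(n_valid = report$group_t$n_valid,
                   max_t = report$group_t$max_t,
                   df = report$group_t$map$df),
    set_sizes = list(connectivity = length(report$sets$connectivity),
                     invertedU = length(report$sets$invertedU),
                     invertedU_loose = length(report$sets$invertedU_loose),
                     span = length(report$sets$span)),
    venn = list(connectivity_vs_invertedU = tidy(v1),
                span_vs_invertedU = tidy(v2)),
    caudate_regions = report$caudate_regions,
    chi_square = report$chi_square)
  if (!is.null(report$span_correlations)) {
    out$span_correlations <- list(
      placebo = report$span_correlations$placebo,
      drug = report$span_correlations$drug,
      comparison = report$span_correlations$comparison)
    out$cell_means <- report$cell_means
  }
  if (!is.null(report$recovery)) out$recovery <- report$recovery
  out
}

config_as_list <- function(config) {
  cl <- unclass(config)
  cl$effect <- unclass(cl$effect)
  cl$geometry <- NULL
  cl
}

#' Write a pipeline report
#'
#' Writes `report.json` (machine-readable summary), `report.txt`
#' (human-readable), `config.json` (the exact configuration used), and the
#' thresholded voxel sets as NIfTI masks + TSV index lists.
#'
#' @param report A `mesoconn_report`.
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mesoconn_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config_as_list(report$config),
                       file.path(dir, "config.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  jsonlite::write_json(report_summary_list(report),
                       file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows",
                       null = "null")
  aff <- if (!is.null(report$config$geometry)) report$config$geometry$affine
  else diag(4)
  for (nm in names(report$sets)) {
    write_voxel_set(report$sets[[nm]], file.path(dir, paste0("set_", nm)), aff)
  }
  txt <- utils::capture.output(print(report))
  writeLines(c(txt, "", "caudate regions:",
               utils::capture.output(print(as.data.frame(report$caudate_regions))),
               "", "chi-square (tail vs head/body overlap proportion):",
               utils::capture.output(print(as.data.frame(report$chi_square)))),
             file.path(dir, "report.txt"))
  invisible(dir)
}
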