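# NIfTI-1, TSV and JSON readers/writers. Volumes are stored with the
# standard 0-based NIfTI voxel convention on disk; in memory the package
# uses 1-based voxel indices, so the affine translation is shifted by one
# voxel on the way in and out.

affine_to_disk <- function(affine) {
  a <- affine
  a[1:3, 4] <- a[1:3, 4] + rowSums(a[1:3, 1:3])
  a
}

affine_from_disk <- function(affine) {
  a <- affine
  a[1:3, 4] <- a[1:3, 4] - rowSums(a[1:3, 1:3])
  a
}

write_nifti_vol <- function(data, affine, path, datatype, tr = NULL) {
  img <- RNifti::asNifti(data)
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  pd <- if (is.null(tr)) vs else c(vs, tr)
  RNifti::pixdim(img) <- pd
  RNifti::`sform<-`(img, structure(affine_to_disk(affine), code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a BOLD run as NIfTI-1
#'
#' 4D float32 volume; the TR is stored in `pixdim[4]`.
#'
#' @param run A `bold_run`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_bold_run <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  write_nifti_vol(run$data, run$affine, path, "float", tr = run$tr)
}

#' Read a BOLD run from NIfTI-1
#'
#' @param path NIfTI file.
#' @param subject_id,session,drug Metadata to attach (not stored in the
#'   NIfTI header).
#' @return A `bold_run`.
#' @export
read_bold_run <- function(path, subject_id = NA_character_,
                          session = NA_integer_, drug = NA_character_) {
  img <- RNifti::readNifti(path)
  tr <- RNifti::pixdim(img)[4]
  affine <- affine_from_disk(structure(RNifti::xform(img), dim = c(4L, 4L)))
  bold_run(array(as.numeric(img), dim(img)), tr = tr, affine = affine,
           subject_id = subject_id, session = session, drug = drug)
}

#' Write a phantom geometry (labels plus JSON sidecar)
#'
#' @param geometry A `phantom_geometry`.
#' @param prefix Output path prefix; writes `<prefix>_labels.nii.gz` and
#'   `<prefix>_geometry.json`.
#' @export
write_phantom_geometry <- function(geometry, prefix) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  write_nifti_vol(geometry$labels, geometry$affine,
                  paste0(prefix, "_labels.nii.gz"), "int16")
  jsonlite::write_json(
    list(shape = geometry$shape, voxel_size = geometry$voxel_size,
         affine = geometry$affine, y_boundary = geometry$y_boundary,
         regions = as.list(phantom_regions)),
    paste0(prefix, "_geometry.json"), digits = NA, auto_unbox = TRUE,
    matrix = "rowmajor")
  invisible(prefix)
}

#' Read a phantom geometry written by [write_phantom_geometry()]
#' @param prefix Path prefix used when writing.
#' @return A `phantom_geometry`.
#' @export
read_phantom_geometry <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_geometry.json"),
                              simplifyVector = TRUE)
  img <- RNifti::readNifti(paste0(prefix, "_labels.nii.gz"))
  structure(list(labels = array(as.integer(img), dim(img)),
                 shape = as.integer(meta$shape),
                 voxel_size = as.numeric(meta$voxel_size),
                 affine = matrix(as.numeric(meta$affine), 4L, 4L, byrow = FALSE),
                 y_boundary = meta$y_boundary),
            class = "phantom_geometry")
}

#' Read and validate a subject table
#'
#' Tab-separated table with columns `subject_id`, `session`, `drug`,
#' `span_score` and optionally `path` (per-run NIfTI file) and
#' `span_group`. When `span_group` is absent it is assigned from
#' `span_score` at `span_cutoff`.
#'
#' @param path TSV file.
#' @param span_cutoff Inclusive high-span cutoff.
#' @return A validated design tibble.
#' @export
read_subject_table <- function(path, span_cutoff = 3.5) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("subject_id", "session", "drug", "span_score")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols)) {
    abort(sprintf("subject table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"span_group" %in% names(tab)) {
    tab$span_group <- assign_span_groups(tab$span_score, span_cutoff)
  }
  attr(tab, "span_cutoff") <- span_cutoff
  validate_cohort_design(tab, span_cutoff)
}

#' Write a design table as TSV
#' @param design A design tibble.
#' @param path Output TSV path.
#' @export
write_subject_table <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Writes one float32 NIfTI per run, the label volume, the design TSV
#' (with a `path` column) and the ground-truth manifest JSON.
#'
#' @param cohort A `bold_cohort`.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bold_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  design <- cohort$design
  design$path <- NA_character_
  for (row in seq_len(nrow(design))) {
    nm <- sprintf("%s_ses%d", design$subject_id[row], design$session[row])
    rel <- paste0(nm, ".nii.gz")
    write_bold_run(cohort$runs[[nm]], file.path(dir, rel))
    design$path[row] <- rel
  }
  write_subject_table(design, file.path(dir, "design.tsv"))
  write_phantom_geometry(cohort$geometry, file.path(dir, "phantom"))
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(shape = dim(gt$class_map),
         classes = lapply(stats::setNames(nm = names(gt_classes)), function(cl)
           which(gt$class_map == gt_classes[[cl]])),
         effect = unclass(gt$effect), rng_seed = gt$rng_seed,
         n_timepoints = gt$n_timepoints, tr = gt$tr, band = gt$band),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Cohort directory.
#' @return A `bold_cohort`.
#' @export
read_cohort <- function(dir) {
  design <- read_subject_table(file.path(dir, "design.tsv"))
  geometry <- read_phantom_geometry(file.path(dir, "phantom"))
  runs <- list()
  for (row in seq_len(nrow(design))) {
    nm <- sprintf("%s_ses%d", design$subject_id[row], design$session[row])
    runs[[nm]] <- read_bold_run(file.path(dir, design$path[row]),
                                subject_id = design$subject_id[row],
                                session = design$session[row],
                                drug = design$drug[row])
  }
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  class_map <- array(0L, as.integer(gt$shape))
  for (cl in names(gt_classes)) {
    class_map[as.integer(gt$classes[[cl]])] <- gt_classes[[cl]]
  }
  eff <- effect_spec(r_cells = unlist(gt$effect$r_cells),
                     frac_dopaminergic = gt$effect$frac_dopaminergic,
                     frac_constant = gt$effect$frac_constant,
                     r_constant = gt$effect$r_constant,
                     noise_sd = gt$effect$noise_sd,
                     confound_weight = gt$effect$confound_weight)
  structure(
    list(runs = runs, design = design[, setdiff(names(design), "path")],
         geometry = geometry,
         ground_truth = structure(
           list(class_map = class_map, effect = eff, rng_seed = gt$rng_seed,
                n_timepoints = gt$n_timepoints, tr = gt$tr, band = gt$band),
           class = "ground_truth")),
    class = "bold_cohort")
}

#' Write a connectivity map (z volume plus validity mask)
#'
#' @param map A `connectivity_map`.
#' @param prefix Path prefix; writes `<prefix>_z.nii.gz` and
#'   `<prefix>_valid.nii.gz`.
#' @param affine Voxel-to-world matrix for the header.
#' @export
write_connectivity_map <- function(map, prefix, affine = diag(4)) {
  z <- map$z; z[!map$valid] <- 0
  write_nifti_vol(z, affine, paste0(prefix, "_z.nii.gz"), "float")
  write_nifti_vol(map$valid + 0L, affine, paste0(prefix, "_valid.nii.gz"), "uint8")
  invisible(prefix)
}

#' Write a voxel set as binary mask, index TSV and provenance JSON
#'
#' @param vs A `voxel_set`.
#' @param prefix Path prefix.
#' @param affine Voxel-to-world matrix for the mask header.
#' @export
write_voxel_set <- function(vs, prefix, affine = diag(4)) {
  stopifnot(inherits(vs, "voxel_set"))
  write_nifti_vol(as_mask(vs) + 0L, affine, paste0(prefix, "_mask.nii.gz"), "uint8")
  readr::write_tsv(tidy(vs), paste0(prefix, "_voxels.tsv"))
  jsonlite::write_json(c(list(n_voxels = nrow(vs$ijk), shape = vs$shape),
                         vs$provenance),
                       paste0(prefix, "_provenance.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(prefix)
}
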