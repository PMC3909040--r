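#' Construct a voxel set
#'
#' A set of unique 1-based voxel indices on a fixed grid, carrying
#' provenance describing how it was obtained (contrast, threshold,
#' correction, mask).
#'
#' @param ijk Matrix or tibble with columns `i`, `j`, `k` (1-based), or an
#'   empty value for the empty set.
#' @param shape Integer grid dimensions.
#' @param provenance Named list of free-form provenance fields.
#' @return A `voxel_set` object.
#' @export
voxel_set <- function(ijk, shape, provenance = list()) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L)
  if (is.null(ijk) || (is.data.frame(ijk) && nrow(ijk) == 0L) ||
      (is.matrix(ijk) && nrow(ijk) == 0L) || length(ijk) == 0L) {
    ijk <- matrix(integer(0), 0L, 3L, dimnames = list(NULL, c("i", "j", "k")))
  }
  if (is.matrix(ijk) && is.null(colnames(ijk)) && ncol(ijk) == 3L) {
    colnames(ijk) <- c("i", "j", "k")
  }
  ijk <- as.matrix(as.data.frame(ijk)[, c("i", "j", "k"), drop = FALSE])
  storage.mode(ijk) <- "integer"
  if (nrow(ijk)) {
    if (any(ijk < 1L) || any(ijk > matrix(shape, nrow(ijk), 3L, byrow = TRUE))) {
      abort("voxel indices fall outside the grid")
    }
    lin <- ijk_to_linear(ijk, shape)
    if (anyDuplicated(lin)) abort("voxel indices must be unique")
    ijk <- ijk[order(lin), , drop = FALSE]
  }
  structure(list(ijk = ijk, shape = shape, provenance = provenance),
            class = "voxel_set")
}

#' Voxel set from a logical mask
#' @param mask 3D logical array.
#' @param provenance Provenance list.
#' @return A `voxel_set`.
#' @export
voxel_set_from_mask <- function(mask, provenance = list()) {
  voxel_set(which_ijk(mask), dim(mask), provenance)
}

#' Number of voxels in a set
#' @param x A `voxel_set`.
#' @export
length.voxel_set <- function(x) nrow(x$ijk)

#' @export
print.voxel_set <- function(x, ...) {
  cat(sprintf("<voxel_set> %d voxels on a %s grid\n", nrow(x$ijk),
              paste(x$shape, collapse = " x ")))
  if (length(x$provenance)) {
    cat("  provenance:", paste(names(x$provenance),
                               vapply(x$provenance, function(v)
                                 paste(format(v), collapse = " "), ""),
                               sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# linear indices of a voxel set
vs_linear <- function(vs) ijk_to_linear(vs$ijk, vs$shape)

#' Logical mask of a voxel set
#' @param vs A `voxel_set`.
#' @return 3D logical array.
#' @export
as_mask <- function(vs) {
  stopifnot(inherits(vs, "voxel_set"))
  m <- array(FALSE, vs$shape)
  if (nrow(vs$ijk)) m[vs_linear(vs)] <- TRUE
  m
}

#' Restrict a voxel set to a mask
#' @param vs A `voxel_set`.
#' @param mask 3D logical array on the same grid.
#' @return The restricted `voxel_set`.
#' @export
restrict_voxel_set <- function(vs, mask) {
  stopifnot(inherits(vs, "voxel_set"), identical(dim(mask), as.integer(vs$shape)))
  keep <- mask[vs_linear(vs)]
  voxel_set(vs$ijk[keep, , drop = FALSE], vs$shape, vs$provenance)
}

# neighbourhood offsets for 6/18/26 connectivity
neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  switch(as.character(connectivity),
         "6"  = g[rowSums(abs(g)) == 1, , drop = FALSE],
         "18" = g[rowSums(abs(g)) <= 2, , drop = FALSE],
         "26" = g,
         abort("`connectivity` must be one of 6, 18, 26"))
}

#' Label connected components of a voxel set
#'
#' @param vs A `voxel_set`.
#' @param connectivity Neighbourhood: 6 (faces), 18 (faces+edges) or
#'   26 (faces+edges+corners).
#' @return Integer vector of component labels, one per voxel in `vs`.
#' @export
label_components <- function(vs, connectivity = 6) {
  offs <- neighbor_offsets(connectivity)
  n <- nrow(vs$ijk)
  labels <- integer(n)
  if (!n) return(labels)
  shape <- vs$shape
  lin <- vs_linear(vs)
  pos <- integer(prod(shape)); pos[lin] <- seq_len(n)
  current <- 0L
  for (v in seq_len(n)) {
    if (labels[v]) next
    current <- current + 1L
    queue <- v; labels[v] <- current
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- sweep(offs, 2, as.numeric(vs$ijk[u, ]), `+`)
      okb <- nb[, 1] >= 1 & nb[, 1] <= shape[1] & nb[, 2] >= 1 &
        nb[, 2] <= shape[2] & nb[, 3] >= 1 & nb[, 3] <= shape[3]
      cand <- pos[ijk_to_linear(nb[okb, , drop = FALSE], shape)]
      cand <- cand[cand > 0L]
      cand <- cand[labels[cand] == 0L]
      labels[cand] <- current
      queue <- c(queue, cand)
    }
  }
  labels
}

#' Remove small connected components from a voxel set
#'
#' Implements the cluster-extent threshold: connected components (under the
#' chosen neighbourhood) with fewer than `min_cluster` voxels are dropped.
#'
#' @param vs A `voxel_set`.
#' @param min_cluster Minimum surviving component size (voxels).
#' @param connectivity 6, 18 or 26.
#' @return The filtered `voxel_set` (provenance annotated).
#' @export
cluster_filter <- function(vs, min_cluster = 20L, connectivity = 6) {
  stopifnot(inherits(vs, "voxel_set"))
  if (min_cluster < 1L) abort("`min_cluster` must be at least 1")
  labels <- label_components(vs, connectivity)
  sizes <- table(labels)
  keep <- labels %in% as.integer(names(sizes)[sizes >= min_cluster])
  prov <- c(vs$provenance,
            list(min_cluster = as.integer(min_cluster),
                 cluster_connectivity = as.integer(connectivity)))
  voxel_set(vs$ijk[keep, , drop = FALSE], vs$shape, prov)
}

#' @describeIn voxel_set Tidy a voxel set into a tibble of indices.
#' @param x A `voxel_set`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.voxel_set <- function(x, ...) {
  as_tibble(as.data.frame(x$ijk))
}
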