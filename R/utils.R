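# internal helpers shared across modules

# Deterministic 31-bit child seed from a master seed plus string labels.
# Polynomial rolling hash mod the Mersenne prime 2^31 - 1; stays exact in
# doubles (intermediates < 2^53).
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (lab in as.character(c(...))) {
    for (code in utf8ToInt(lab)) h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
}

# linear index <-> (i, j, k) for 1-based voxel coordinates
ijk_to_linear <- function(ijk, shape) {
  ijk <- as.matrix(ijk)
  (ijk[, 1] - 1L) + shape[1] * ((ijk[, 2] - 1L) + shape[2] * (ijk[, 3] - 1L)) + 1L
}

linear_to_ijk <- function(lin, shape) {
  lin0 <- lin - 1L
  i <- lin0 %% shape[1]
  j <- (lin0 %/% shape[1]) %% shape[2]
  k <- lin0 %/% (shape[1] * shape[2])
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

# world coordinates (mm) of 1-based voxel indices under a 4x4 affine
voxel_to_world <- function(ijk, affine) {
  ijk <- as.matrix(ijk)
  hm <- cbind(ijk, 1) %*% t(affine)
  hm[, 1:3, drop = FALSE]
}
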