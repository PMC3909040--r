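# compact phantom used throughout the unit tests: same layout as the
# default geometry, scaled down so simulated cohorts build in well under a
# second each
tiny_region_spec <- function() {
  list(
    midbrain_seed    = list(i = c(4L, 5L), j = c(2L, 3L),   k = c(3L, 4L)),
    caudate_tail     = list(i = c(2L, 5L), j = c(6L, 8L),   k = c(3L, 5L)),
    caudate_headbody = list(i = c(2L, 5L), j = c(9L, 12L),  k = c(3L, 5L)),
    putamen          = list(i = c(7L, 9L), j = c(7L, 10L),  k = c(3L, 4L)),
    ventral_striatum = list(i = c(7L, 8L), j = c(11L, 12L), k = c(2L, 2L)),
    white_matter     = list(i = c(2L, 9L), j = c(2L, 14L),  k = c(6L, 6L)),
    csf              = list(i = c(2L, 9L), j = c(2L, 14L),  k = c(1L, 1L)),
    other_brain      = "fill"
  )
}

tiny_geometry <- function() {
  make_phantom_geometry(shape = c(10L, 16L, 6L),
                        region_spec = tiny_region_spec())
}

tiny_cohort <- function(seed = 1L, n_low = 2L, n_high = 2L,
                        effect = effect_spec(), n_timepoints = 60L) {
  geom <- tiny_geometry()
  des <- cohort_design(n_low, n_high, rng_seed = seed)
  simulate_cohort(geom, des, effect, n_timepoints = n_timepoints, tr = 2,
                  rng_seed = seed)
}

# a bold_run wrapping given voxel series; series is a t x v matrix whose
# columns are laid out in array order over `shape`
run_from_series <- function(series, shape, tr = 2, affine = NULL) {
  if (is.null(affine)) affine <- diag(4)
  bold_run(array(t(series), c(shape, nrow(series))), tr = tr, affine = affine,
           subject_id = "test", session = 1L, drug = "placebo")
}

# fraction of periodogram power inside a band (DC excluded)
power_fraction <- function(x, tr, band) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) / (n * tr)
  ffold <- pmin(f, 1 / tr - f)
  inside <- ffold >= band[1] & ffold <= band[2]
  sum(P[inside & f > 0]) / sum(P[-1])
}

# amplitude of the dominant FFT component over the central half of a series
fft_amplitude <- function(x, freq, tr) {
  n <- length(x)
  central <- x[floor(n / 4):ceiling(3 * n / 4)]
  m <- length(central)
  sp <- stats::fft(central)
  f <- (seq_len(m) - 1) / (m * tr)
  bin <- which.min(abs(f - freq))
  2 * Mod(sp[bin]) / m
}

# connectivity maps with prescribed per-subject z values: one map per
# design row, constant over the grid except where `pattern` sets voxels
maps_from_z <- function(design, z_fun, shape = c(4L, 4L, 2L)) {
  lapply(seq_len(nrow(design)), function(r) {
    z <- array(z_fun(design[r, ]), shape)
    connectivity_map(z, array(TRUE, shape),
                     subject_id = design$subject_id[r],
                     session = design$session[r], drug = design$drug[r])
  })
}
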