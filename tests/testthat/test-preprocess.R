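test_that("band-pass filter removes DC and keeps in-band components", {
  n <- 300; tr <- 2
  tt <- (seq_len(n) - 1) * tr
  const <- run_from_series(matrix(5, n, 4), c(2, 2, 1), tr = tr)
  out <- bandpass_filter(const)
  expect_lt(max(abs(out$data)), 1e-10)

  in_band <- run_from_series(matrix(sin(2 * pi * 0.04 * tt), n, 4), c(2, 2, 1),
                             tr = tr)
  f_in <- bandpass_filter(in_band)
  ratio <- fft_amplitude(f_in$data[1, 1, 1, ], 0.04, tr) /
    fft_amplitude(in_band$data[1, 1, 1, ], 0.04, tr)
  expect_gt(ratio, 0.95)
  expect_lt(ratio, 1.05)

  out_band <- run_from_series(matrix(sin(2 * pi * 0.2 * tt), n, 4), c(2, 2, 1),
                              tr = tr)
  f_out <- bandpass_filter(out_band)
  att <- fft_amplitude(f_out$data[1, 1, 1, ], 0.2, tr) /
    fft_amplitude(out_band$data[1, 1, 1, ], 0.2, tr)
  expect_lt(att, 0.1)

  expect_error(bandpass_filter(in_band, band = c(0.009, 0.4)), "Nyquist")
})

test_that("band-pass filter is linear", {
  set.seed(11)
  n <- 150
  x <- rnorm(n); y <- rnorm(n)
  a <- 2.5; b <- -1.3
  fx <- bandpass_filter(run_from_series(cbind(x), c(1, 1, 1)))$data[1, 1, 1, ]
  fy <- bandpass_filter(run_from_series(cbind(y), c(1, 1, 1)))$data[1, 1, 1, ]
  fxy <- bandpass_filter(run_from_series(cbind(a * x + b * y),
                                         c(1, 1, 1)))$data[1, 1, 1, ]
  expect_equal(fxy, a * fx + b * fy, tolerance = 1e-8)
})

test_that("nuisance regression produces residuals orthogonal to confounds", {
  set.seed(21)
  n <- 120
  conf <- cbind(rnorm(n), rnorm(n))
  # a voxel equal to a confound vanishes
  series <- cbind(conf[, 1], rnorm(n), rnorm(n) + 0.5 * conf[, 2])
  run <- run_from_series(series, c(3, 1, 1))
  res <- regress_nuisance(run, conf)
  expect_lt(max(abs(res$data[1, 1, 1, ])), 1e-10)
  # residuals orthogonal to every confound
  R <- t(matrix(res$data, 3, n))
  expect_lt(max(abs(crossprod(R, conf))) / max(abs(R)) / max(abs(conf)), 1e-8)
  # zero-mean series orthogonal to the confounds is returned unchanged
  ortho <- rnorm(n)
  D <- cbind(1, conf)
  ortho <- ortho - D %*% solve(crossprod(D), crossprod(D, ortho))
  run_o <- run_from_series(cbind(as.numeric(ortho)), c(1, 1, 1))
  res_o <- regress_nuisance(run_o, conf)
  expect_equal(res_o$data[1, 1, 1, ], as.numeric(ortho), tolerance = 1e-10)
})

test_that("nuisance regression matches a normal-equations oracle", {
  set.seed(22)
  n <- 80
  conf <- cbind(rnorm(n), rnorm(n))
  X <- matrix(rnorm(n * 6), n, 6)
  run <- run_from_series(X, c(3, 2, 1))
  res <- regress_nuisance(run, conf)
  D <- cbind(1, conf)
  oracle <- X - D %*% (solve(crossprod(D)) %*% crossprod(D, X))
  got <- t(matrix(res$data, 6, n))
  expect_equal(got, oracle, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("collinear confounds are rejected with the column named", {
  n <- 60
  c1 <- rnorm(n)
  run <- run_from_series(cbind(rnorm(n)), c(1, 1, 1))
  expect_error(regress_nuisance(run, cbind(a = c1, b = 2 * c1)),
               "rank deficient")
})

test_that("spatial smoothing has the advertised kernel behaviour", {
  shape <- c(13L, 13L, 13L)
  # fwhm 0 is the exact identity
  set.seed(31)
  arr <- array(rnorm(prod(shape) * 10), c(shape, 10))
  run <- bold_run(arr, tr = 2, affine = diag(c(2, 2, 2, 1)))
  expect_identical(smooth_spatial(run, 0)$data, arr)
  # constant volume is unchanged (reflective boundaries)
  const <- bold_run(array(3.7, c(shape, 10)), tr = 2,
                    affine = diag(c(2, 2, 2, 1)))
  sm <- smooth_spatial(const, 4)
  expect_equal(sm$data, const$data, tolerance = 1e-6)
  # impulse response matches the explicit normalised Gaussian kernel
  imp <- array(0, c(shape, 10)); imp[7, 7, 7, ] <- 1
  runi <- bold_run(imp, tr = 2, affine = diag(c(2, 2, 2, 1)))
  smi <- smooth_spatial(runi, 4)
  sigma <- 4 / (2 * 2 * sqrt(2 * log(2)))   # voxels, isotropic 2 mm
  offs <- -4:4
  w <- exp(-offs^2 / (2 * sigma^2)); w <- w / sum(w)
  kern3 <- outer(outer(w, w), w)
  center <- which(offs == 0)
  expect_equal(smi$data[7, 7, 7, 1], kern3[center, center, center],
               tolerance = 1e-10)
  expect_equal(smi$data[7, 8, 6, 1],
               w[center] * w[center + 1] * w[center - 1], tolerance = 1e-10)
  # volume sum preserved for interior-supported input
  expect_equal(sum(smi$data[, , , 1]), 1, tolerance = 1e-6)
  # anisotropic voxels get per-axis sigmas: x axis (1.8 mm) spreads more
  # than z (3.45 mm)
  runa <- bold_run(imp, tr = 2, affine = diag(c(1.8, 1.8, 3.45, 1)))
  sma <- smooth_spatial(runa, 4)
  expect_gt(sma$data[8, 7, 7, 1], sma$data[7, 7, 8, 1])
  expect_error(smooth_spatial(run, -1), "nonnegative")
})

test_that("mean time-series extraction equals the per-timepoint loop", {
  set.seed(41)
  n <- 40
  X <- matrix(rnorm(n * 8), n, 8)
  run <- run_from_series(X, c(2, 2, 2))
  # single voxel: exactly that series
  m1 <- array(FALSE, c(2, 2, 2)); m1[1, 1, 1] <- TRUE
  expect_identical(extract_mean_timeseries(run, m1), X[, 1])
  # s and -s cancel
  X2 <- cbind(X[, 1], -X[, 1])
  run2 <- run_from_series(X2, c(2, 1, 1))
  expect_equal(extract_mean_timeseries(run2, array(TRUE, c(2, 1, 1))),
               rep(0, n))
  # 5-voxel mask against a brute-force loop
  mask <- array(FALSE, c(2, 2, 2)); mask[c(1, 3, 4, 6, 8)] <- TRUE
  got <- extract_mean_timeseries(run, mask)
  oracle <- vapply(seq_len(n), function(t) mean(X[t, c(1, 3, 4, 6, 8)]),
                   numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(extract_mean_timeseries(run, array(FALSE, c(2, 2, 2))), "empty")
  expect_error(extract_mean_timeseries(run, array(TRUE, c(3, 2, 2))), "grid")
})

test_that("batched preprocessing equals the per-run path", {
  coh <- tiny_cohort(seed = 5L, n_low = 1L, n_high = 1L)
  geom <- coh$geometry
  wm <- region_mask(geom, "white_matter")
  csf <- region_mask(geom, "csf")
  batched <- mesoconn:::preprocess_runs(coh$runs, wm, csf, fwhm_mm = 3,
                                        chunk_size = 3L)
  for (nm in names(coh$runs)) {
    single <- preprocess_run(coh$runs[[nm]], wm, csf, fwhm_mm = 3)
    expect_equal(batched[[nm]]$data, single$data, tolerance = 1e-12)
  }
})
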