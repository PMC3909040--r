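test_that("phantom geometry satisfies its region invariants", {
  geom <- tiny_geometry()
  spec <- tiny_region_spec()
  # every named region nonempty and sized exactly by its box
  for (nm in setdiff(names(spec), "other_brain")) {
    b <- spec[[nm]]
    expected <- prod(b$i[2] - b$i[1] + 1, b$j[2] - b$j[1] + 1,
                     b$k[2] - b$k[1] + 1)
    expect_equal(sum(geom$labels == phantom_regions[[nm]]), expected,
                 info = nm)
  }
  expect_gt(sum(geom$labels == phantom_regions[["other_brain"]]), 0)
  # labels partition: each voxel has exactly one label
  expect_true(all(geom$labels %in% c(0L, phantom_regions)))
  # caudate boxes sit on opposite sides of the world-y boundary
  hb <- region_mask(geom, "caudate_headbody")
  tl <- region_mask(geom, "caudate_tail")
  yh <- mesoconn:::voxel_to_world(mesoconn:::which_ijk(hb), geom$affine)[, 2]
  yt <- mesoconn:::voxel_to_world(mesoconn:::which_ijk(tl), geom$affine)[, 2]
  expect_true(min(yh) > geom$y_boundary)
  expect_true(max(yt) <= geom$y_boundary)
})

test_that("geometry construction rejects bad region layouts", {
  spec <- tiny_region_spec()
  spec$putamen <- spec$caudate_headbody  # collide
  expect_error(make_phantom_geometry(shape = c(10L, 16L, 6L), region_spec = spec),
               "putamen.*overlap|overlap.*putamen")
  spec <- tiny_region_spec()
  spec$csf$k <- c(1L, 99L)
  expect_error(make_phantom_geometry(shape = c(10L, 16L, 6L), region_spec = spec),
               "csf")
  # a one-voxel midbrain seed is allowed
  spec <- tiny_region_spec()
  spec$midbrain_seed <- list(i = c(4L, 4L), j = c(2L, 2L), k = c(3L, 3L))
  geom <- make_phantom_geometry(shape = c(10L, 16L, 6L), region_spec = spec)
  expect_equal(sum(geom$labels == phantom_regions[["midbrain_seed"]]), 1L)
})

test_that("band-limited signals are unit variance, zero mean, in band", {
  x <- simulate_band_limited_signal(150, 2, rng_seed = 1)
  expect_lt(abs(mean(x)), 1e-10)
  expect_equal(sd(x), 1, tolerance = 1e-12)
  expect_gte(power_fraction(x, 2, c(0.009, 0.08)), 0.9)
  # determinism
  expect_identical(x, simulate_band_limited_signal(150, 2, rng_seed = 1))
  expect_false(identical(x, simulate_band_limited_signal(150, 2, rng_seed = 2)))
  # Nyquist guard
  expect_error(simulate_band_limited_signal(150, 2, band = c(0.01, 0.3),
                                            rng_seed = 1), "Nyquist")
})

test_that("planted_correlation follows the closed form of the mixture model", {
  expect_equal(planted_correlation(0, 0.7, sigma_e = 1), 0)
  expect_equal(planted_correlation(1, 0, sigma_s = 1, sigma_e = 1),
               1 / sqrt(2), tolerance = 1e-12)
  # limit of vanishing noise: r -> 1
  expect_equal(planted_correlation(2, 0, sigma_e = 1e-12), 1, tolerance = 1e-6)
  # general closed form against direct arithmetic
  a <- 0.8; b <- 0.3; se <- 1.2
  expect_equal(planted_correlation(a, b, sigma_e = se),
               a / sqrt(a^2 + b^2 + se^2), tolerance = 1e-14)
  expect_error(planted_correlation(0, 0, sigma_s = 1, sigma_c = 1, sigma_e = 0),
               "undefined")
})

test_that("cohort simulation is reproducible and records valid ground truth", {
  coh1 <- tiny_cohort(seed = 7L)
  coh2 <- tiny_cohort(seed = 7L)
  expect_identical(coh1$runs[[1]]$data, coh2$runs[[1]]$data)
  expect_identical(coh1$ground_truth$class_map, coh2$ground_truth$class_map)
  coh3 <- tiny_cohort(seed = 8L)
  expect_false(identical(coh1$runs[[1]]$data, coh3$runs[[1]]$data))

  # ground-truth classes partition the caudate
  geom <- coh1$geometry
  caud <- region_mask(geom, c("caudate_headbody", "caudate_tail"))
  cm <- coh1$ground_truth$class_map
  expect_true(all(cm[caud] %in% gt_classes))
  expect_true(all(cm[!caud] == 0L))
  gt <- ground_truth_table(coh1)
  expect_equal(nrow(gt), sum(caud))
  frac <- mean(gt$class == "dopaminergic_invertedU")
  expect_equal(frac, effect_spec()$frac_dopaminergic, tolerance = 0.05)
  # the planted dopaminergic block is spatially connected
  dopa <- voxel_set_from_mask(cm == gt_classes[["dopaminergic_invertedU"]])
  expect_equal(max(label_components(dopa, 6)), 1L)
})

test_that("unreachable planted correlations are rejected with the cell named", {
  eff <- effect_spec(noise_sd = 0, confound_weight = 0)
  geom <- tiny_geometry()
  des <- cohort_design(2, 2, rng_seed = 1)
  expect_error(simulate_cohort(geom, des, eff, n_timepoints = 60L, tr = 2,
                               rng_seed = 1),
               "low_placebo")
})

test_that("empirical voxel-seed correlations converge on the planted value", {
  # connected-but-unmodulated caudate: every voxel planted at r = 0.6
  eff <- effect_spec(r_cells = rep(0.3, 4), frac_dopaminergic = 0,
                     frac_constant = 1, r_constant = 0.6)
  geom <- tiny_geometry()
  des <- cohort_design(1, 1, rng_seed = 1)
  seed_mask <- region_mask(geom, "midbrain_seed")
  caud <- region_mask(geom, c("caudate_headbody", "caudate_tail"))
  zbar <- vapply(1:60, function(s) {
    coh <- simulate_cohort(geom, des, eff, n_timepoints = 150L, tr = 2,
                           rng_seed = 1000 + s)
    run <- coh$runs[[1]]
    m <- seed_connectivity_map(run, seed_mask, caud)
    mean(m$z[m$valid])
  }, numeric(1))
  expect_equal(mean(zbar), atanh(0.6), tolerance = 0.05)
})

test_that("cohort design honours group sizes, sessions and the span cutoff", {
  des <- cohort_design(8, 8, rng_seed = 3)
  expect_equal(nrow(des), 32L)
  subj <- dplyr::distinct(des, subject_id, span_group, span_score)
  expect_equal(sum(subj$span_group == "high"), 8L)
  expect_equal(sum(subj$span_group == "low"), 8L)
  expect_true(all(subj$span_score[subj$span_group == "high"] >= 3.5))
  expect_true(all(subj$span_score[subj$span_group == "low"] < 3.5))
  # both drug orders occur (counterbalancing)
  first <- des[des$session == 1L, ]
  expect_true(all(c("placebo", "bromocriptine") %in% first$drug))
  # validation catches a broken design
  broken <- des[-1, ]
  expect_error(validate_cohort_design(broken), "sub01")
  relabel <- des
  relabel$drug[1] <- "caffeine"
  expect_error(validate_cohort_design(relabel), "caffeine")
})
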