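make_design <- function(n_low = 4L, n_high = 4L, seed = 2L) {
  cohort_design(n_low, n_high, rng_seed = seed)
}

test_that("one-sample t map matches t.test voxel by voxel", {
  set.seed(61)
  shape <- c(4L, 3L, 2L)
  des <- make_design(3, 3)
  zs <- array(rnorm(prod(shape) * nrow(des)), c(shape, nrow(des)))
  maps <- lapply(seq_len(nrow(des)), function(r) {
    connectivity_map(zs[, , , r], array(TRUE, shape),
                     subject_id = des$subject_id[r], session = des$session[r],
                     drug = des$drug[r])
  })
  tm <- one_sample_t_map(maps)
  expect_equal(tm$df, nrow(des) - 1L)
  for (v in seq_len(prod(shape))) {
    vals <- vapply(seq_len(nrow(des)), function(r) zs[, , , r][v], numeric(1))
    tt <- t.test(vals)
    expect_equal(tm$stat[v], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(tm$p[v], tt$p.value, tolerance = 1e-10)
  }
  # degenerate: identical maps -> invalid, not infinite t
  same <- lapply(maps, function(m) { m$z <- array(0.4, shape); m })
  expect_warning(tm0 <- one_sample_t_map(same), "zero between-map variance")
  expect_false(any(tm0$valid))
  expect_error(one_sample_t_map(maps[1:2]), "at least 3")
})

test_that("interaction contrast equals the paired-difference two-sample t", {
  set.seed(62)
  shape <- c(4L, 4L, 2L)
  des <- make_design(4, 4)
  z_lookup <- array(rnorm(prod(shape) * nrow(des)), c(prod(shape), nrow(des)))
  maps <- lapply(seq_len(nrow(des)), function(r) {
    connectivity_map(array(z_lookup[, r], shape), array(TRUE, shape),
                     subject_id = des$subject_id[r], session = des$session[r],
                     drug = des$drug[r])
  })
  im <- interaction_contrast_map(maps, des)
  subj <- dplyr::distinct(des, subject_id, span_group)
  expect_equal(im$df, nrow(subj) - 2L)
  # brute-force loop oracle
  for (v in seq_len(prod(shape))) {
    d <- vapply(subj$subject_id, function(s) {
      zd <- z_lookup[v, which(des$subject_id == s & des$drug == "bromocriptine")]
      zp <- z_lookup[v, which(des$subject_id == s & des$drug == "placebo")]
      zd - zp
    }, numeric(1))
    tt <- t.test(d[subj$span_group == "low"], d[subj$span_group == "high"],
                 var.equal = TRUE)
    expect_equal(im$stat[v], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(im$p[v], tt$p.value, tolerance = 1e-10)
  }
})

test_that("interaction contrast estimate applies the quadratic weights", {
  shape <- c(2L, 2L, 1L)
  des <- make_design(4, 4)
  cellv <- c(low_placebo = 0.2, low_drug = 0.5, high_placebo = 0.5,
             high_drug = 0.2)
  # drug-session jitter that cancels within each cell keeps cell means
  # exact while giving the paired differences nonzero variance
  jit <- rep(c(0.01, -0.01), 4)[seq_len(8)]
  names(jit) <- unique(des$subject_id)
  maps <- maps_from_z(des, function(row) {
    cell <- paste(row$span_group,
                  ifelse(row$drug == "placebo", "placebo", "drug"), sep = "_")
    cellv[[cell]] +
      if (row$drug == "bromocriptine") jit[[row$subject_id]] else 0
  }, shape)
  im <- interaction_contrast_map(maps, des)
  expect_equal(im$estimate[1, 1, 1], 0.3, tolerance = 1e-12)
  expect_gt(im$stat[1, 1, 1], 0)  # positive = inverted-U
  # all cells equal -> estimate and t are zero
  maps0 <- maps_from_z(des, function(row) {
    0.4 + if (row$drug == "bromocriptine") jit[[row$subject_id]] else 0
  }, shape)
  im0 <- interaction_contrast_map(maps0, des)
  expect_equal(im0$estimate[1, 1, 1], 0, tolerance = 1e-12)
  expect_equal(im0$stat[1, 1, 1], 0, tolerance = 1e-12)
})

test_that("interaction contrast validates its design", {
  shape <- c(2L, 2L, 1L)
  des <- make_design(4, 4)
  maps <- maps_from_z(des, function(row) rnorm(1), shape)
  expect_error(interaction_contrast_map(maps[-1], des), "sub01")
  des_small <- make_design(1, 4, seed = 3L)
  maps_small <- maps_from_z(des_small, function(row) rnorm(1), shape)
  expect_error(interaction_contrast_map(maps_small, des_small), "at least 2")
  expect_error(interaction_contrast_map(maps, des, contrast = c(1, 1, 0, 0)),
               "summing to 0")
})

test_that("bh_fdr reproduces the step-up rule", {
  res <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_equal(res$rejected, 1:4)
  expect_equal(res$threshold, 0.04)
  res1 <- bh_fdr(rep(1, 10), q = 0.05)
  expect_equal(res1$rejected, integer(0))
  expect_true(is.na(res1$threshold))
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("bh_fdr agrees with exhaustive enumeration and p.adjust", {
  set.seed(63)
  for (rep in 1:40) {
    m <- sample(1:10, 1)
    p <- round(runif(m), 3)
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    res <- bh_fdr(p, q)
    # exhaustive step-up: largest i among sorted p with p(i) <= i q / m
    ps <- sort(p)
    k <- 0
    for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
    oracle <- if (k == 0) integer(0) else which(p <= ps[k])
    expect_equal(res$rejected, sort(oracle))
    # equivalent to the adjusted-p formulation
    expect_equal(sort(res$rejected),
                 which(stats::p.adjust(p, "BH") <= q))
    # invariance under permutation
    perm <- sample(m)
    res_p <- bh_fdr(p[perm], q)
    expect_equal(sort(perm[res_p$rejected]), res$rejected)
  }
})

test_that("bh_fdr controls the false discovery proportion under the null mix", {
  set.seed(64)
  m <- 200; m0 <- 150
  fdp <- replicate(200, {
    p <- c(runif(m0), rbeta(m - m0, 0.1, 1))
    rej <- bh_fdr(p, 0.05)$rejected
    sum(rej <= m0) / max(1, length(rej))
  })
  expect_lt(mean(fdp), 0.05 + 3 * sd(fdp) / sqrt(200))
})

test_that("cluster_filter respects size and connectivity", {
  shape <- c(8L, 8L, 8L)
  # isolated voxel removed
  vs1 <- voxel_set(cbind(i = 1L, j = 1L, k = 1L), shape)
  expect_equal(length(cluster_filter(vs1, 20)), 0L)
  # solid 3x3x3 block of 27 kept at min_cluster 20
  block <- as.matrix(expand.grid(i = 2:4, j = 2:4, k = 2:4))
  vs2 <- voxel_set(block, shape)
  expect_equal(length(cluster_filter(vs2, 20, 6)), 27L)
  # two corner-sharing voxels: separate under 6, joined under 26
  corners <- voxel_set(rbind(c(1L, 1L, 1L), c(2L, 2L, 2L)), shape)
  expect_equal(max(label_components(corners, 6)), 2L)
  expect_equal(max(label_components(corners, 26)), 1L)
  # edge-sharing voxels: separate under 6, joined under 18
  edges <- voxel_set(rbind(c(1L, 1L, 1L), c(2L, 2L, 1L)), shape)
  expect_equal(max(label_components(edges, 6)), 2L)
  expect_equal(max(label_components(edges, 18)), 1L)
  expect_error(cluster_filter(vs2, 20, 7), "connectivity")
})

test_that("small-volume restriction makes BH rejection monotone", {
  shape <- c(6L, 6L, 2L)
  nvox <- prod(shape)
  set.seed(65)
  p <- array(runif(nvox, 0.5, 1), shape)
  caud <- array(FALSE, shape); caud[2:4, 2:4, 1] <- TRUE
  p[caud] <- runif(sum(caud), 0, 0.04)
  stat <- array(1, shape)
  sm <- stat_map(stat, p, df = 10, valid = array(TRUE, shape))
  whole <- small_volume_threshold(sm, threshold_spec(q = 0.05, min_cluster = 1))
  svc <- small_volume_threshold(
    sm, threshold_spec(q = 0.05, small_volume_mask = caud, min_cluster = 1))
  inside_whole <- restrict_voxel_set(whole, caud)
  # caudate-restricted correction rejects a superset on caudate voxels
  expect_true(all(mesoconn:::vs_linear(inside_whole) %in%
                    mesoconn:::vs_linear(svc)))
  # empty result when nothing is below threshold
  p1 <- array(runif(nvox, 0.9, 1), shape)
  sm1 <- stat_map(stat, p1, df = 10, valid = array(TRUE, shape))
  expect_equal(length(small_volume_threshold(sm1, threshold_spec())), 0L)
  # disjoint mask errors
  off <- array(FALSE, shape)
  sm2 <- stat_map(stat, p, df = 10, valid = array(TRUE, shape))
  expect_error(small_volume_threshold(
    sm2, threshold_spec(small_volume_mask = off)), "disjoint")
})

test_that("span correlation matches cor.test and handles boundaries", {
  set.seed(66)
  scores <- runif(16, 1.5, 5.5)
  vals <- 0.3 * scores + rnorm(16, 0, 0.4)
  got <- correlate_with_span(vals, scores)
  ct <- stats::cor.test(vals, scores)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$t, unname(ct$statistic), tolerance = 1e-10)
  expect_equal(got$p, ct$p.value, tolerance = 1e-10)
  expect_equal(got$df, 14L)
  # perfect correlation: p reported at the machine floor, not NaN
  perfect <- correlate_with_span(scores, scores)
  expect_equal(perfect$r, 1)
  expect_true(perfect$p > 0 && perfect$p < 1e-300)
  expect_error(correlate_with_span(vals, rep(2, 16)), "constant")
  expect_error(correlate_with_span(vals[1:3], scores[1:3]), "at least 4")
})

test_that("null span correlations give uniform p-values", {
  set.seed(67)
  n <- 16; reps <- 10000
  scores <- runif(n, 1.5, 5.5)
  V <- matrix(rnorm(n * reps), n, reps)
  r <- as.numeric(stats::cor(scores, V))
  tv <- r * sqrt(n - 2) / sqrt(1 - r^2)
  pv <- 2 * stats::pt(-abs(tv), n - 2)
  ks <- stats::ks.test(pv, "punif")
  expect_lt(unname(ks$statistic), 0.03)
})

test_that("compare_correlations implements the two-sample Fisher z test", {
  eq <- compare_correlations(0.4, 20, 0.4, 30)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  # oracle: direct formula recomputed longhand
  z_oracle <- (atanh(0.5) - atanh(0)) / sqrt(1 / 16 + 1 / 16)
  got <- compare_correlations(0.5, 19, 0, 19)
  expect_equal(got$z, z_oracle, tolerance = 1e-12)
  expect_equal(got$z, 1.554, tolerance = 1e-3)
  expect_error(compare_correlations(0.5, 3, 0.2, 10), "exceed 3")
  expect_error(compare_correlations(1, 10, 0.2, 10), "strictly inside")
})

test_that("span groups split at an inclusive 3.5 cutoff", {
  expect_equal(assign_span_groups(c(3.5, 3.49, 5, 1.5)),
               c("high", "low", "high", "low"))
  scores <- c(runif(8, 1.5, 3.4), runif(8, 3.5, 5.5))
  g <- assign_span_groups(scores)
  expect_equal(sum(g == "high"), 8L)
  expect_equal(sum(g == "low"), 8L)
})
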