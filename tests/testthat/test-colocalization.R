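test_that("ROI grids follow floor arithmetic and exclusion rules", {
  g <- make_neuropil_rois(c(184.58, 184.58), depth_um = 2.1)
  expect_equal(nrow(g$rois), 324)              # floor(184.58/10)^2
  expect_equal(sum(g$rois$kept), 324)
  expect_equal(g$analyzed_volume_um3, 324 * 100 * 2.1)

  # everything excluded -> nothing kept, zero analyzed volume
  mask_all <- matrix(TRUE, 200, 200)
  g0 <- make_neuropil_rois(c(100, 100), depth_um = 2, exclusion_mask = mask_all,
                           pixel_size_um = 0.5)
  expect_equal(sum(g0$rois$kept), 0)
  expect_equal(g0$analyzed_volume_um3, 0)

  # one ROI-sized blob aligned to the grid drops exactly one ROI
  mask1 <- matrix(FALSE, 200, 200)
  mask1[21:40, 41:60] <- TRUE                  # 10x10 um at (10..20, 20..30)
  g1 <- make_neuropil_rois(c(100, 100), depth_um = 2, exclusion_mask = mask1,
                           pixel_size_um = 0.5)
  expect_equal(sum(!g1$rois$kept), 1)
  dropped <- g1$rois[!g1$rois$kept, ]
  expect_equal(c(dropped$x0, dropped$y0), c(10, 20))

  expect_error(make_neuropil_rois(c(100, 100), 2,
                                  exclusion_mask = matrix(FALSE, 10, 10),
                                  pixel_size_um = 0.5),
               "shape")
  expect_error(make_neuropil_rois(c(5, 5), 2), "exceeds")
})

test_that("pairing respects the distance cutoff and one-to-one rule", {
  pre <- as_objects(rbind(c(0, 0, 0)))
  post_near <- as_objects(rbind(c(0, 0, 0.4)))
  post_far <- as_objects(rbind(c(0, 0, 0.6)))
  p1 <- pair_puncta(pre, post_near, 0.5)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$distance_um, 0.4)
  expect_equal(nrow(pair_puncta(pre, post_far, 0.5)), 0)
  expect_error(pair_puncta(pre, post_near, 0), "max_dist")

  # one post between two pre: one-to-one takes the closer pre only,
  # any-within takes both
  pre2 <- as_objects(rbind(c(0, 0, 0), c(0.3, 0, 0)))
  post2 <- as_objects(rbind(c(0.1, 0, 0)))
  expect_equal(nrow(pair_puncta(pre2, post2, 0.5)), 1)
  expect_equal(pair_puncta(pre2, post2, 0.5)$pre_id, 1)
  expect_equal(nrow(pair_puncta(pre2, post2, 0.5, mode = "any_within")), 2)
})

test_that("greedy pairing agrees with the brute-force oracle", {
  set.seed(17)
  for (i in 1:40) {
    na <- sample.int(30, 1)
    nb <- sample.int(30, 1)
    a <- matrix(runif(3 * na, 0, 5), ncol = 3)
    b <- matrix(runif(3 * nb, 0, 5), ncol = 3)
    got <- pair_puncta(as_objects(a), as_objects(b), 0.5)
    want <- oracle_greedy_pairs(a, b, 0.5)
    got <- got[order(got$pre_id), ]
    want <- want[order(want$pre), ]
    expect_equal(got$pre_id, want$pre)
    expect_equal(got$post_id, want$post)
    expect_equal(got$distance_um, want$d, tolerance = 1e-12)
  }
})

test_that("pairing is symmetric and monotone under object removal", {
  set.seed(23)
  a <- matrix(runif(90, 0, 4), ncol = 3)
  b <- matrix(runif(75, 0, 4), ncol = 3)
  ab <- pair_puncta(as_objects(a), as_objects(b), 0.6)
  ba <- pair_puncta(as_objects(b), as_objects(a), 0.6)
  expect_lte(nrow(ab), min(nrow(a), nrow(b)))
  expect_equal(ab[order(ab$pre_id), ]$distance_um,
               ba[order(ba$post_id), ]$distance_um)
  expect_equal(
    as.data.frame(ab[order(ab$pre_id), c("pre_id", "post_id")]),
    setNames(as.data.frame(ba[order(ba$post_id), c("post_id", "pre_id")]),
             c("pre_id", "post_id")),
    ignore_attr = TRUE)
  # removing any pre object never increases the pair count
  for (drop in sample.int(nrow(a), 5)) {
    fewer <- pair_puncta(as_objects(a[-drop, , drop = FALSE]),
                         as_objects(b), 0.6)
    expect_lte(nrow(fewer), nrow(ab))
  }
})

test_that("densities convert counts per analyzed volume to per mm3", {
  # 4 ROIs x 100 um2 x 1.08 um depth = 432 um3; 40 pairs -> 9.259e7 / mm3,
  # the order of magnitude of inhibitory synapse densities in motor cortex
  grid <- make_neuropil_rois(c(20, 20), depth_um = 1.08)
  set.seed(5)
  xy <- cbind(runif(40, 0, 14), runif(40, 0, 14), runif(40, 0, 1))
  pre <- as_objects(xy)
  post <- as_objects(xy + 0.05)
  pairing <- pair_puncta(pre, post, 0.5)
  expect_equal(nrow(pairing), 40)
  dens <- compute_densities(pairing, list(pre = pre, post = post), grid)
  expect_equal(dens$summary$synapse_density_per_mm3, 40 / 432 * 1e9)
  expect_equal(dens$summary$synapse_density_per_mm3, 9.259259e7,
               tolerance = 1e-6)
  # invariant: paired density cannot exceed either single-channel density
  expect_lte(dens$summary$synapse_density_per_mm3,
             min(dens$summary$pre_per_mm3, dens$summary$post_per_mm3))
  # linearity: doubling the scene doubles every density
  xy2 <- rbind(xy, sweep(xy, 2, c(5.23, 5.61, 0.04), `+`))
  pre2 <- as_objects(xy2)
  post2 <- as_objects(xy2 + 0.05)
  d2 <- compute_densities(pair_puncta(pre2, post2, 0.5),
                          list(pre = pre2, post = post2), grid)
  expect_equal(d2$summary$synapse_density_per_mm3,
               2 * dens$summary$synapse_density_per_mm3)
  # empty pairing -> zero density
  d0 <- compute_densities(pair_puncta(as_objects(xy), as_objects(xy + 10),
                                      0.5),
                          list(pre = pre, post = post), grid)
  expect_equal(d0$summary$synapse_density_per_mm3, 0)
  # zero analyzed volume is an error
  gfull <- make_neuropil_rois(c(60, 60), 120,
                              exclusion_mask = matrix(TRUE, 120, 120),
                              pixel_size_um = 0.5)
  expect_error(compute_densities(pairing, list(pre = pre, post = post),
                                 gfull), "volume")
  expect_s3_class(glance(dens), "tbl_df")
  expect_equal(nrow(tidy(dens)), 4)
})
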