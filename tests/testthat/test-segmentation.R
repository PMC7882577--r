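test_that("local thresholding matches a per-pixel oracle", {
  set.seed(7)
  img <- matrix(rnorm(40 * 35, 50, 5), 40, 35)
  img[10:14, 8:12] <- img[10:14, 8:12] + 60
  for (r in c(3, 8)) {
    got <- local_threshold_section(img, seg_params(window_radius_px = r,
                                                   k = 2))
    expect_identical(got, oracle_local_threshold(img, r, "niblack", k = 2))
    gm <- local_threshold_section(img, seg_params("mean",
                                                  window_radius_px = r,
                                                  offset = 10))
    expect_identical(gm, oracle_local_threshold(img, r, "mean", offset = 10))
  }
})

test_that("uniform images yield empty masks and bright disks are recovered", {
  flat <- matrix(37.5, 30, 30)
  expect_false(any(local_threshold_section(flat, seg_params())))
  expect_false(any(local_threshold_section(
    flat, seg_params("mean", offset = 1))))
  expect_false(any(local_threshold_section(
    flat, seg_params("median", offset = 1))))

  # bright disk (100) on background (10): mask covers the disk interior and
  # no deep-background pixel, as a global threshold at (100+10)/2 would
  img <- matrix(10, 60, 60)
  xs <- (seq_len(60) - 0.5)
  d2 <- outer((xs - 30)^2, (xs - 30)^2, `+`)
  img[d2 <= 36] <- 100
  for (m in c("niblack", "mean", "median")) {
    mask <- local_threshold_section(
      img, seg_params(m, window_radius_px = 12, k = 1, offset = 20))
    expect_true(all(mask[d2 <= 16]))        # disk interior
    expect_false(any(mask[d2 >= 144]))      # far background
  }
})

test_that("window larger than the image is rejected", {
  expect_error(local_threshold_section(matrix(0, 10, 10),
                                       seg_params(window_radius_px = 8)),
               "window")
})

test_that("extract_objects links identical footprints across sections", {
  arr <- array(0, c(40, 40, 6, 1))
  arr[10:12, 20:22, 2:4, 1] <- 100     # 3x3 square on sections 2-4
  st <- synq_stack(arr, pixel_size_um = 0.1, spacing_um = 0.07,
                   channels = "a", mode = "array_tomography")
  ob <- extract_objects(st, "a", seg_params("mean", offset = 5,
                                            min_footprint_px = 1))
  expect_equal(nrow(ob), 1)
  expect_equal(ob$sections[[1]], 2:4)
  expect_equal(ob$centroid_x_um, 11 * 0.1 - 0.05)   # center of cols 10:12
  expect_equal(ob$centroid_y_um, 21 * 0.1 - 0.05)
  expect_equal(ob$centroid_z_um, 3 * 0.07 - 0.035)  # mean of sections 2:4
  expect_equal(ob$volume_um3, 27 * 0.1^2 * 0.07)

  # two disjoint squares on one section stay two objects
  arr2 <- array(0, c(40, 40, 3, 1))
  arr2[5:7, 5:7, 2, 1] <- 100
  arr2[30:32, 30:32, 2, 1] <- 100
  st2 <- synq_stack(arr2, 0.1, 0.07, "a", mode = "array_tomography")
  ob2 <- extract_objects(st2, "a", seg_params("mean", offset = 5,
                                              min_footprint_px = 1))
  expect_equal(nrow(ob2), 2)

  # diagonal contact merges in-plane (8-connectivity)
  arr3 <- array(0, c(20, 20, 2, 1))
  arr3[5:6, 5:6, 1, 1] <- 100
  arr3[7:8, 7:8, 1, 1] <- 100
  st3 <- synq_stack(arr3, 0.1, 0.07, "a", mode = "array_tomography")
  ob3 <- extract_objects(st3, "a", seg_params("mean", offset = 5,
                                              min_footprint_px = 1))
  expect_equal(nrow(ob3), 1)
})

test_that("object extraction is translation-equivariant and conserves volume", {
  ch <- tibble::tibble(name = "a", puncta_density_per_mm3 = 1.5e8,
                       punctum_radius_um = 0.2, peak_intensity = 150,
                       psf_sigma_xy_um = 0.06, psf_sigma_z_um = 0.15)
  cfg <- sim_image_config(field_size_um = c(8, 8), n_sections = 20,
                          channels = ch, colocalization_fraction = 0,
                          flicker_density_per_mm3 = 0,
                          background_level = 20, gaussian_noise_sd = 0,
                          poisson_noise = FALSE, seed = 13)
  sim <- simulate_section_series(cfg)
  p <- seg_params()
  ob <- extract_objects(sim$stack, "a", p)

  arr <- unclass(sim$stack)
  d <- dim(arr)
  shifted <- array(attr(sim$stack, "pixel_size_um") * 0 + 20, d)
  shifted[3:d[1], 5:d[2], , ] <- arr[1:(d[1] - 2), 1:(d[2] - 4), , ]
  st2 <- synq_stack(shifted, attr(sim$stack, "pixel_size_um"),
                    attr(sim$stack, "spacing_um"), "a",
                    mode = "array_tomography")
  ob2 <- extract_objects(st2, "a", p)
  px <- attr(sim$stack, "pixel_size_um")
  # compare interior objects (away from the borders both before and after)
  sel <- ob$centroid_x_um > 1 & ob$centroid_x_um < 7 - 2 * px &
    ob$centroid_y_um > 1 & ob$centroid_y_um < 7 - 4 * px
  a <- ob[sel, ]
  a <- a[order(a$centroid_x_um, a$centroid_y_um), ]
  b <- ob2[ob2$centroid_x_um > 1 + 2 * px & ob2$centroid_y_um > 1 + 4 * px &
             ob2$centroid_x_um < 7 & ob2$centroid_y_um < 7, ]
  b <- b[order(b$centroid_x_um, b$centroid_y_um), ]
  expect_equal(nrow(a), nrow(b))
  expect_equal(b$centroid_x_um, a$centroid_x_um + 2 * px, tolerance = 1e-10)
  expect_equal(b$centroid_y_um, a$centroid_y_um + 4 * px, tolerance = 1e-10)

  # volumes sum to the filtered foreground voxel count times voxel volume
  sp <- attr(sim$stack, "spacing_um")
  fg <- 0
  for (k in seq_len(d[3])) {
    lab <- synaptiq:::label8(local_threshold_section(arr[, , k, 1], p))
    if (max(lab) > 0) {
      sz <- tabulate(lab[lab > 0])
      fg <- fg + sum(sz[sz >= p$min_footprint_px])
    }
  }
  expect_equal(sum(ob$volume_um3), fg * px^2 * sp)
})

test_that("noise-free ribbons are recovered exactly after persistence filtering", {
  ch <- tibble::tibble(name = "VGAT", puncta_density_per_mm3 = 2e8,
                       punctum_radius_um = 0.2, peak_intensity = 150,
                       psf_sigma_xy_um = 0.06, psf_sigma_z_um = 0.15)
  cfg <- sim_image_config(field_size_um = c(10, 10), n_sections = 30,
                          channels = ch, colocalization_fraction = 0,
                          background_level = 20, gaussian_noise_sd = 0,
                          poisson_noise = FALSE, seed = 11)
  sim <- simulate_section_series(cfg)
  ob <- extract_objects(sim$stack, "VGAT", seg_params())
  filt <- persistence_filter(ob)
  n_true <- nrow(sim$truth$centers$VGAT)
  n_flick <- nrow(sim$truth$flickers)
  expect_equal(nrow(ob), n_true + n_flick)   # flickers present pre-filter
  expect_equal(nrow(filt), n_true)
  # every interior truth center is matched within one voxel diagonal
  # (blobs touching the field border — laterally or at the first/last
  # section — lose footprint voxels, which pulls their centroid inward)
  vox_diag <- sqrt(2 * 0.0587^2 + 0.07^2)
  tr <- sim$truth$centers$VGAT
  interior <- tr$x_um > 0.5 & tr$x_um < 9.5 & tr$y_um > 0.5 &
    tr$y_um < 9.5 & tr$z_um > 0.3 & tr$z_um < 30 * 0.07 - 0.3
  d <- vapply(which(interior), function(i) {
    min(sqrt((filt$centroid_x_um - tr$x_um[i])^2 +
               (filt$centroid_y_um - tr$y_um[i])^2 +
               (filt$centroid_z_um - tr$z_um[i])^2))
  }, numeric(1))
  expect_lt(max(d), vox_diag)
})

test_that("persistence filter keeps exactly the consecutive-section objects", {
  mk <- function(spans) tibble::tibble(id = seq_along(spans),
                                       sections = spans)
  expect_equal(nrow(persistence_filter(mk(list(4L)))), 0)
  expect_equal(nrow(persistence_filter(mk(list(c(4L, 5L))))), 1)
  expect_equal(nrow(persistence_filter(mk(list(c(2L, 4L, 6L))))), 0)
  expect_equal(nrow(persistence_filter(mk(list())[0, ])), 0)

  set.seed(31)
  spans <- lapply(1:300, function(i) {
    sort(sample.int(12, sample.int(5, 1)))
  })
  objects <- mk(spans)
  out <- persistence_filter(objects)
  expect_true(all(out$id %in% objects$id))                    # subset
  expect_identical(persistence_filter(out), out)              # idempotent
  keep_oracle <- vapply(spans, oracle_has_run, logical(1), k = 2)
  expect_equal(out$id, objects$id[keep_oracle])               # order kept
  # and with a stricter requirement
  out3 <- persistence_filter(objects, min_consecutive = 3)
  expect_equal(out3$id,
               objects$id[vapply(spans, oracle_has_run, logical(1), k = 3)])
  expect_error(persistence_filter(objects, 0), "min_consecutive")
})
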