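test_that("segmentation recovers uniform discs", {
  img <- image_stack(matrix(0, 40, 40), 1)
  img[raster_ball(c(40, 40), c(20, 20), 10)] <- 50
  seg <- segment_cells(img)
  expect_equal(nrow(seg$cells), 1)
  expect_equal(sum(seg$labels == 1), sum(img > 0))
  two <- image_stack(matrix(0, 60, 60), 1)
  two[raster_ball(c(60, 60), c(15, 15), 8)] <- 40
  two[raster_ball(c(60, 60), c(45, 45), 8)] <- 60
  seg2 <- segment_cells(two)
  expect_equal(nrow(seg2$cells), 2)
  expect_error(segment_cells(image_stack(matrix(1, 10, 10), 1)), "no cell")
})

test_that("segmented nucleus area is within 5% of the generator truth", {
  sim <- generate_cell_images(imaging_ground_truth(seed = 31), c(30, 200))
  for (i in 1:2) {
    seg <- segment_cells(sim$images[[i]])
    area_um2 <- seg$cells$area_px * pixel_size(sim$images[[i]])^2
    expect_equal(area_um2, sim$truth$nucleus_area_um2[i], tolerance = 0.05)
  }
})

test_that("a uniform cell yields an empty condensate set", {
  cell <- toy_cell()
  flat <- cell$img
  flat[cell$mask] <- 25
  det <- detect_condensates(flat, cell$mask)
  expect_s3_class(det, "condensate_set")
  expect_equal(nrow(det$objects), 0)
  expect_equal(spark_signal(det, cell$mask, flat), 0)
  ## threshold above the maximum intensity: empty set, not an error
  det2 <- detect_condensates(cell$img, cell$mask, threshold = 1e6)
  expect_equal(nrow(det2$objects), 0)
})

test_that("hand-built toy cell gives SPARK = 0.25 by pixel arithmetic", {
  cell <- toy_cell()
  det <- detect_condensates(cell$img, cell$mask)
  expect_equal(nrow(det$objects), 1)
  expect_equal(det$objects$total_intensity, 500)    # 4 px x 125
  expect_equal(spark_signal(det, cell$mask, cell$img), 0.25)
})

test_that("detection and SPARK agree with exhaustive enumeration on small fields", {
  set.seed(32)
  for (rep in 1:5) {
    img <- matrix(rpois(32 * 32, 30), 32, 32)
    mask <- raster_ball(c(32, 32), c(16, 16), 12)
    img[mask] <- img[mask] + rpois(sum(mask), 40)
    img <- image_stack(img, 1)
    thr <- quantile(img[mask], 0.9)
    det <- detect_condensates(img, mask, threshold = thr, min_size_px = 1)
    ## oracle: direct pixel enumeration at the same threshold
    bg <- median(img[!mask])
    hot <- img > thr & mask
    expect_equal(sum(det$objects$size_px), sum(hot))
    expect_equal(sum(det$objects$total_intensity), sum(img[hot] - bg))
    expect_equal(spark_signal(det, mask, img),
                 max(0, sum(img[hot] - bg)) / sum(img[mask] - bg))
  }
})

test_that("a synthetic condensate is recovered with radius within 1 pixel", {
  gt <- quiet_gt(partition_ratio = 8, condensate_radius_um = 0.8,
                 condensate_radius_cv = 0, seed = 33)
  sim <- generate_cell_images(gt, 55)       # just above csat
  img <- sim$images[[1]]
  seg <- segment_cells(img)
  ## half-max threshold (the standard size criterion for a blurred step)
  thr <- (sim$truth$dilute_pre[1] + sim$truth$cond_pre[1]) / 2
  det <- detect_condensates(img, seg$labels == 1, threshold = thr)
  expect_equal(nrow(det$objects), sim$truth$n_condensates[1])
  r_px <- det$objects$equiv_radius_um / pixel_size(img)
  truth_r_px <- sqrt(sim$truth$cond_fraction[1] * sim$truth$nucleus_area_um2[1] /
                       pixel_size(img)^2 / nrow(det$objects) / pi)
  expect_lt(max(abs(r_px - truth_r_px)), 1)
})

test_that("3D sphere volume is recovered within voxelization error", {
  d <- c(24, 24, 24)
  img <- array(0, d)
  img[raster_ball(d, c(12, 12, 12), 1 / 0.25)] <- 100   # r = 1 um
  img <- image_stack(img, 0.25)
  mask <- array(TRUE, d)
  det <- detect_condensates(img, mask, threshold = 50)
  expect_equal(nrow(det$objects), 1)
  expect_equal(det$objects$area_volume_um, 4 / 3 * pi, tolerance = 0.05)
})

test_that("SPARK signal is invariant under intensity rescaling", {
  gt <- imaging_ground_truth(seed = 34, offset = 0)
  sim <- generate_cell_images(gt, 150)
  img <- sim$images[[1]]
  seg <- segment_cells(img)
  cmask <- seg$labels == 1
  s1 <- spark_signal(detect_condensates(img, cmask), cmask, img)
  img5 <- img * 5
  s5 <- spark_signal(detect_condensates(img5, cmask), cmask, img5)
  expect_equal(s1, s5, tolerance = 1e-10)
  expect_gte(s1, 0)
  expect_lte(s1, 1)
})

test_that("raising the high threshold never increases the SPARK signal", {
  sim <- generate_cell_images(imaging_ground_truth(seed = 35), 200)
  img <- sim$images[[1]]
  seg <- segment_cells(img)
  cmask <- seg$labels == 1
  sparks <- vapply(c(1.5, 2, 3, 4, 6, 10), function(k)
    spark_signal(detect_condensates(img, cmask, k = k), cmask, img),
    numeric(1))
  expect_true(all(diff(sparks) <= 1e-12))
})

test_that("density ratio recovers the generator partition ratio", {
  gt <- imaging_ground_truth(partition_ratio = 8, seed = 36)
  sim <- generate_cell_images(gt, c(150, 250, 350))
  ratios <- vapply(seq_len(3), function(i) {
    img <- sim$images[[i]]
    seg <- segment_cells(img)
    det <- detect_condensates(img, seg$labels == 1)
    density_ratio(det, seg$labels == 1, img)
  }, numeric(1))
  expect_equal(mean(ratios), 8, tolerance = 0.2)   # PSF-bleed tolerance
  ## no condensates: undefined ratio is an error
  flat <- toy_cell()
  flat$img[flat$mask] <- 25
  det0 <- detect_condensates(flat$img, flat$mask)
  expect_error(density_ratio(det0, flat$mask, flat$img), "undefined")
})
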