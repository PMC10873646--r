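test_that("generators are bit-identical under a fixed seed", {
  gt <- imaging_ground_truth(seed = 5)
  a <- generate_cell_images(gt, c(20, 120))
  b <- generate_cell_images(gt, c(20, 120))
  expect_identical(a$images, b$images)
  expect_identical(a$truth, b$truth)
  f1 <- generate_fusion_movie(fusion_ground_truth(n_events = 2, seed = 6))
  f2 <- generate_fusion_movie(fusion_ground_truth(n_events = 2, seed = 6))
  expect_identical(f1$movies, f2$movies)
  c1 <- generate_counts(counts_ground_truth(n_genes = 200, seed = 7))
  c2 <- generate_counts(counts_ground_truth(n_genes = 200, seed = 7))
  expect_identical(c1$counts, c2$counts)
})

test_that("cells below the saturation concentration have no condensates", {
  gt <- imaging_ground_truth(csat_nM = 40, seed = 8)
  sim <- generate_cell_images(gt, c(5, 10, 20, 39))
  expect_true(all(sim$truth$n_condensates == 0))
  expect_true(all(sim$truth$spark_true == 0))
  sup <- generate_cell_images(imaging_ground_truth(csat_nM = 40, seed = 9),
                              c(41, 100, 400))
  expect_true(all(sup$truth$n_condensates >= 1))
})

test_that("invalid generator inputs are rejected", {
  gt <- imaging_ground_truth(seed = 1)
  expect_error(generate_cell_images(gt, numeric(0)), "non-empty")
  expect_error(generate_cell_images(gt, c(10, -5)), "> 0")
  expect_error(imaging_ground_truth(csat_nM = -1))
  expect_error(imaging_ground_truth(partition_ratio = 0.5))
  expect_error(fusion_ground_truth(inv_cap_velocity_s_per_um = -2))
  ## droplets far below the pixel size cannot be rendered
  tiny <- fusion_ground_truth(radii_um = cbind(0.05, 0.05),
                              pixel_size_um = 0.1, seed = 2)
  expect_error(generate_fusion_movie(tiny), "too small")
})

test_that("pre-noise condensate/dilute contrast equals the partition ratio", {
  gt <- quiet_gt(csat_nM = 40, partition_ratio = 8, psf_sigma_um = 0,
                 seed = 10)
  sim <- generate_cell_images(gt, 200, keep_prenoise = TRUE)
  pre <- sim$prenoise[[1]]
  dilute <- median(pre[pre > 0])            # most nuclear pixels are dilute
  expect_equal(max(pre) / dilute, 8, tolerance = 0.01)  # rasterized edges
  expect_equal(sim$truth$partition_ratio, 8, tolerance = 1e-9)
})

test_that("total pre-noise intensity is proportional to concentration", {
  gt <- quiet_gt(seed = 11, psf_sigma_um = 0)
  conc <- c(20, 80, 160, 320)
  sim <- generate_cell_images(gt, conc, keep_prenoise = TRUE)
  mean_per_px <- vapply(seq_along(conc), function(i) {
    pre <- sim$prenoise[[i]]
    sum(pre) / sum(pre > 0)
  }, numeric(1))
  expect_equal(mean_per_px, gt$calib_slope * conc, tolerance = 1e-6)
})

test_that("dilution series recovers the generator slope within 2%", {
  gt <- imaging_ground_truth(seed = 12)
  cal <- fit_standard_curve(generate_dilution_table(gt))
  expect_equal(cal$slope, gt$calib_slope, tolerance = 0.02)
  expect_gt(cal$r_squared, 0.999)
})

test_that("fusion movies follow the closed-form aspect-ratio law", {
  gt <- fusion_ground_truth(inv_cap_velocity_s_per_um = 2.5,
                            radii_um = cbind(0.8, 0.8),
                            frame_interval_s = 0.25, gain = 1e-4,
                            read_noise_sd = 0, offset = 0, seed = 13)
  sim <- generate_fusion_movie(gt)
  tr <- sim$truth
  expect_equal(tr$ell_um, sqrt(2 * 0.8^2), tolerance = 1e-9)
  expect_equal(tr$tau_s, 2.5 * tr$ell_um, tolerance = 1e-9)
  ev <- track_fusion_events(sim$movies[[1]])
  expect_length(ev, 1)
  ar <- ev[[1]]
  ## measured AR at t = tau equals 1 + (AR0 - 1)/e within rasterization
  j <- which.min(abs(ar$t_s - tr$tau_s))
  expect_equal(ar$aspect_ratio[j],
               1 + (tr$ar0 - 1) * exp(-ar$t_s[j] / tr$tau_s),
               tolerance = 0.05)
  ## late frames relax to a sphere
  expect_lt(ar$aspect_ratio[nrow(ar)], 1.05)
})

test_that("dissolution series conserve pre-noise intensity and decay on cue", {
  gt <- imaging_ground_truth(seed = 14)
  ds <- generate_dissolution_series(gt, decay_tau_s = 40, t_total_s = 160,
                                    frame_interval_s = 10,
                                    keep_prenoise = TRUE)
  tot <- vapply(ds$prenoise, sum, numeric(1))
  expect_lt(max(abs(tot / tot[1] - 1)), 0.001)
  ## true condensate-resident fraction crosses 5% at tau*ln(20)
  norm <- ds$truth$spark_true / ds$truth$spark_true[1]
  t_cross <- ds$truth$t_s[which(norm < 0.05)[1]]
  expect_lte(abs(t_cross - 40 * log(20)), 10)
  ## infinite timescale: constant fraction
  flat <- generate_dissolution_series(gt, decay_tau_s = Inf,
                                      t_total_s = 60,
                                      frame_interval_s = 20)
  expect_equal(diff(range(flat$truth$spark_true)), 0, tolerance = 1e-12)
  expect_error(generate_dissolution_series(gt, t_total_s = 5,
                                           frame_interval_s = 10),
               "2 frames")
})

test_that("Ct tables encode the requested fold changes exactly at zero noise", {
  ct <- generate_ct_table(c(geneA = 0.5, geneB = 1), ct_noise_sd = 0,
                          seed = 15)
  res <- ddct(ct)
  expect_equal(res$rel_expression[res$gene == "geneA"], 0.5)
  expect_equal(res$rel_expression[res$gene == "geneB"], 1)
  expect_equal(res$ddct[res$gene == "geneA"], 1)    # -log2(0.5)
  expect_error(generate_ct_table(c(g = -1)), "fold_changes|> 0")
})

test_that("counts generator spikes the truth set as specified", {
  gt <- counts_ground_truth(n_genes = 500, n_de = 10, de_lfc = 3,
                            de_min_mean = 200, dispersion = 0.01,
                            lib_size_range = c(1, 1), seed = 16)
  sim <- generate_counts(gt)
  expect_equal(sum(sim$truth$is_de), 10)
  expect_equal(sum(sim$truth$lfc > 0), 5)
  expect_equal(sum(sim$truth$lfc < 0), 5)
  de <- sim$truth[sim$truth$is_de & sim$truth$lfc > 0, ]
  m1 <- rowMeans(sim$counts[de$gene, sim$condition == "control"])
  m2 <- rowMeans(sim$counts[de$gene, sim$condition == "treated"])
  expect_equal(mean(log2(m2 / m1)), 3, tolerance = 0.2)
  null_genes <- sim$truth$gene[!sim$truth$is_de]
  mm1 <- rowMeans(sim$counts[null_genes, sim$condition == "control"])
  mm2 <- rowMeans(sim$counts[null_genes, sim$condition == "treated"])
  expect_equal(median(log2((mm2 + 1) / (mm1 + 1))), 0, tolerance = 0.05)
})
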