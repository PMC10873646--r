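## Hand-built time_course objects for the summary/changepoint logic.
mk_tc <- function(spark, total = NULL, chrom = NULL, dt = 1,
                  unit = "min") {
  n <- length(spark)
  tc <- data.frame(frame = seq_len(n), t = (seq_len(n) - 1) * dt,
                   spark_signal = spark,
                   total_fluorescence = total %||% rep(1000, n),
                   n_condensates = ifelse(spark > 0, 5L, 0L))
  if (!is.null(chrom)) tc$chrom_volume_um3 <- chrom
  attr(tc, "time_unit") <- unit
  class(tc) <- c("time_course", "data.frame")
  tc
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("changepoint detection equals brute-force residual minimization", {
  set.seed(81)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    y <- c(rnorm(n, 5), rnorm(sample(3:20, 1), 0)) + rnorm(1)
    expect_equal(sparkq:::changepoint_index(y), naive_changepoint(y))
  }
})

test_that("dissolution summary applies the closed-form completion time", {
  tau <- 3
  t <- seq(0, 30, by = 0.5)
  tc <- mk_tc(0.4 * exp(-t / tau), dt = 0.5)
  ds <- dissolution_summary(tc, epsilon = 0.05)
  expect_true(ds$completed)
  expect_lte(abs(ds$completion_t - tau * log(20)), 0.5)
  expect_equal(ds$spark_norm[1], 1)
  ## constant trace: undefined completion, flagged
  flat <- dissolution_summary(mk_tc(rep(0.3, 10)))
  expect_false(flat$completed)
  expect_true(is.na(flat$completion_t))
  expect_error(dissolution_summary(mk_tc(c(0, 0, 0.1, 0.2))),
               "no condensates at time 0")
})

test_that("event offsets are recovered with sign symmetry", {
  spark <- c(rep(0.5, 8), rep(0.01, 12))       # drop after frame 8 (t = 7)
  chrom <- c(rep(900, 10), rep(450, 10))       # drop after frame 10 (t = 9)
  tc <- mk_tc(spark, chrom = chrom)
  et <- event_timing_offset(tc)
  expect_equal(et$offset_t, -2)
  ## simultaneous events
  tc0 <- mk_tc(spark, chrom = c(rep(900, 8), rep(450, 12)))
  expect_equal(event_timing_offset(tc0)$offset_t, 0)
  ## reversed traces (mitotic exit): the offset flips sign
  tcr <- mk_tc(rev(spark), chrom = rev(chrom))
  expect_equal(event_timing_offset(tcr)$offset_t, 2)
})

test_that("static movies give flat measured traces", {
  gt <- imaging_ground_truth(seed = 82)
  ds <- generate_dissolution_series(gt, decay_tau_s = Inf, t_total_s = 60,
                                    frame_interval_s = 20)
  tc <- measure_timecourse(ds$movie)
  expect_lt(diff(range(tc$spark_signal)) / tc$spark_signal[1], 0.15)
  expect_lt(max(abs(tc$total_fluorescence /
                      tc$total_fluorescence[1] - 1)), 0.01)
})

test_that("measured dissolution conserves total fluorescence within 1%", {
  gt <- imaging_ground_truth(seed = 83)
  ds <- generate_dissolution_series(gt, decay_tau_s = 40, t_total_s = 160,
                                    frame_interval_s = 20)
  tc <- measure_timecourse(ds$movie)
  ds_sum <- dissolution_summary(tc)
  expect_lt(ds_sum$drift, 0.01)
  expect_true(ds_sum$completed)
})

test_that("chromosome volume and event coupling are measured from 3D movies", {
  ms <- generate_mitosis_series(dissolve_time_min = 4, condense_time_min = 6,
                                volumes_um3 = c(900, 450),
                                t_total_min = 10, seed = 84)
  tc <- measure_timecourse(ms$condensate, h2b = ms$h2b, time_unit = "min")
  ## pre/post volumes match the generator truth within voxelization
  expect_equal(tc$chrom_volume_um3[1], 900, tolerance = 0.05)
  expect_equal(tc$chrom_volume_um3[nrow(tc)], 450, tolerance = 0.05)
  et <- event_timing_offset(tc)
  expect_lte(abs(et$offset_t - (4 - 6)), 1)    # within one frame
})

test_that("above-threshold voxel counting recovers a sphere volume", {
  d <- c(28, 28, 28)
  img <- array(0, d)
  img[raster_ball(d, c(14, 14, 14), 10)] <- 100   # r = 5 um at 0.5 um voxels
  img <- image_stack(img, 0.5)
  thr <- otsu_threshold(img)
  vol <- sum(img > thr) * 0.5^3
  expect_equal(vol, 4 / 3 * pi * 125, tolerance = 0.03)
})
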