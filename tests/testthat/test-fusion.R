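## Closed-form relaxation trace (no rendering): the oracle for fit accuracy.
analytic_event <- function(tau, ar0 = 1.8, dt = 0.25, n = 24, ell = 1) {
  ev <- data.frame(t_s = (0:(n - 1)) * dt)
  ev$aspect_ratio <- 1 + (ar0 - 1) * exp(-ev$t_s / tau)
  attr(ev, "ell_um") <- ell
  ev
}

test_that("noiseless relaxation fits recover tau to 1e-6 relative", {
  for (tau in c(0.7, 2, 5)) {
    fit <- fit_relaxation(analytic_event(tau))
    expect_lt(abs(fit$tau_s - tau) / tau, 1e-6)
    expect_equal(fit$ar0, 1.8, tolerance = 1e-6)
    expect_equal(fit$inv_cap_velocity, tau, tolerance = 1e-6)  # ell = 1
  }
})

test_that("velocity scales as 1/ell for the same relaxation time", {
  f1 <- fit_relaxation(analytic_event(2, ell = 0.5))
  f2 <- fit_relaxation(analytic_event(2, ell = 2))
  expect_equal(f1$inv_cap_velocity / f2$inv_cap_velocity, 4,
               tolerance = 1e-9)
})

test_that("fitted tau is invariant under a uniform time offset", {
  ev <- analytic_event(1.5)
  shifted <- ev
  shifted$t_s <- shifted$t_s + 7         # clock starts later
  attr(shifted, "ell_um") <- 1
  f0 <- fit_relaxation(ev)
  f1 <- fit_relaxation(shifted)
  expect_equal(f1$tau_s, f0$tau_s, tolerance = 1e-6)
})

test_that("degenerate traces are rejected", {
  flat <- data.frame(t_s = 0:9, aspect_ratio = rep(1, 10))
  attr(flat, "ell_um") <- 1
  expect_error(fit_relaxation(flat), "degenerate")
  expect_error(fit_relaxation(analytic_event(2)[1:3, ]), "4 post-onset")
})

test_that("a static movie yields no fusion events", {
  img <- matrix(0, 30, 30)
  img[raster_ball(c(30, 30), c(15, 15), 6)] <- 200
  mov <- image_stack(array(rep(img, 5), c(30, 30, 5)), 0.1,
                     frame_interval_s = 0.5, time_axis = 3L)
  expect_equal(length(track_fusion_events(mov)), 0)
})

test_that("a rendered merge is tracked at the true onset and fitted", {
  gt <- fusion_ground_truth(radii_um = cbind(0.6, 0.5),
                            inv_cap_velocity_s_per_um = 1.8, seed = 61)
  sim <- generate_fusion_movie(gt)
  ev <- track_fusion_events(sim$movies[[1]])
  expect_length(ev, 1)
  expect_lte(abs(attr(ev[[1]], "onset_frame") - sim$truth$onset_frame), 1)
  fit <- fit_relaxation(ev[[1]])
  expect_equal(fit$tau_s, sim$truth$tau_s, tolerance = 0.25)
  expect_equal(fit$ell_um, sim$truth$ell_um, tolerance = 0.1)
})

test_that("velocity pooling matches hand arithmetic and filters bad fits", {
  mk <- function(v, rms) structure(list(inv_cap_velocity = v,
                                        rms_residual = rms,
                                        converged = TRUE),
                                   class = "fusion_fit")
  fits <- list(mk(1.5, 0.01), mk(2.1, 0.02), mk(1.8, 0.03), mk(9, 0.5))
  s <- summarize_inverse_capillary_velocity(fits)
  expect_equal(s$n, 3)
  expect_equal(s$n_excluded, 1)
  expect_equal(s$mean_s_per_um, mean(c(1.5, 2.1, 1.8)))
  expect_equal(s$sd_s_per_um, sd(c(1.5, 2.1, 1.8)))
  same <- summarize_inverse_capillary_velocity(list(mk(2, 0.01),
                                                    mk(2, 0.01)))
  expect_equal(same$sd_s_per_um, 0)
  expect_error(summarize_inverse_capillary_velocity(list(mk(2, 0.5),
                                                         mk(2, 0.6))),
               "at least 2")
})
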