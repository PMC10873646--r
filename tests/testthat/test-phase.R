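## Direct curve simulator used where images are unnecessary: SPARK values
## follow the saturating-hinge model with Gaussian noise, truncated to
## [0, 1].
sim_curve <- function(n, csat, a = 0.5, noise = 0.03, cmin = 5, cmax = 500) {
  conc <- exp(runif(n, log(cmin), log(cmax)))
  spark <- pmin(pmax(a * pmax(1 - csat / conc, 0) +
                       rnorm(n, 0, noise), 0), 1)
  build_phase_curve(data.frame(concentration_nM = conc,
                               spark_signal = spark))
}

test_that("phase-curve assembly validates and sorts", {
  expect_error(build_phase_curve(data.frame()), "no cell")
  expect_error(build_phase_curve(
    data.frame(concentration_nM = c(-1, 10), spark_signal = c(0, 0.5))),
    "> 0")
  expect_error(build_phase_curve(
    data.frame(concentration_nM = c(5, 10), spark_signal = c(0, 1.5))),
    "\\[0, 1\\]")
  pc <- build_phase_curve(data.frame(concentration_nM = c(50, 5, 500),
                                     spark_signal = c(0.2, 0, 0.6)))
  expect_equal(pc$concentration_nM, c(5, 50, 500))
  flat <- build_phase_curve(data.frame(concentration_nM = rep(10, 5),
                                       spark_signal = rep(0.3, 5)))
  expect_true(isTRUE(attr(flat, "degenerate")))
})

test_that("a noiseless hinge is recovered exactly at grid resolution", {
  conc <- c(5, 10, 20, 40, 80, 160, 320)
  spark <- 0.6 * pmax(1 - 40 / conc, 0)
  pc <- build_phase_curve(data.frame(concentration_nM = conc,
                                     spark_signal = spark))
  fit <- estimate_csat(pc, n_bootstrap = 0)
  expect_equal(fit$csat_nM, 40)
  expect_equal(fit$slope, 0.6, tolerance = 1e-9)
  expect_equal(fit$rss, 0, tolerance = 1e-12)
})

test_that("unidentifiable curves raise errors", {
  all_zero <- build_phase_curve(data.frame(
    concentration_nM = c(5, 10, 20, 40), spark_signal = rep(0, 4)))
  expect_error(estimate_csat(all_zero), "unidentifiable")
  all_on <- build_phase_curve(data.frame(
    concentration_nM = c(50, 100, 200), spark_signal = c(0.4, 0.5, 0.6)))
  expect_error(estimate_csat(all_on), "unidentifiable")
})

test_that("the c_sat estimate is invariant under cell order", {
  set.seed(51)
  pc <- sim_curve(80, 40)
  f1 <- estimate_csat(pc, n_bootstrap = 0)
  shuffled <- as.data.frame(pc)[sample(nrow(pc)), ]
  f2 <- estimate_csat(build_phase_curve(shuffled), n_bootstrap = 0)
  expect_equal(f1$csat_nM, f2$csat_nM)
})

test_that("bootstrap CI covers the true c_sat at roughly nominal rate", {
  set.seed(52)
  hits <- vapply(seq_len(200), function(i) {
    pc <- sim_curve(60, 40)
    fit <- estimate_csat(pc, n_bootstrap = 199)
    fit$ci_nM[1] <= 40 && 40 <= fit$ci_nM[2]
  }, logical(1))
  expect_gte(mean(hits), 0.90)           # scaled-down coverage check
})

test_that("condition shifts in c_sat are recovered with a positive CI", {
  set.seed(53)
  pc_a <- sim_curve(80, 40)
  pc_b <- sim_curve(80, 150)
  shift <- compare_csat(pc_a, pc_b, n_bootstrap = 300, seed = 1)
  expect_equal(shift$shift_nM, 110, tolerance = 0.25)
  expect_gt(shift$ci_nM[1], 0)
  ## identical curves: shift 0 inside the CI
  same <- compare_csat(pc_a, pc_a, n_bootstrap = 200, seed = 2)
  expect_equal(same$shift_nM, 0)
  expect_true(same$ci_nM[1] <= 0 && 0 <= same$ci_nM[2])
})

test_that("csat_fit methods expose estimate, CI and coefficients", {
  set.seed(54)
  fit <- estimate_csat(sim_curve(60, 40), n_bootstrap = 50, seed = 3)
  expect_s3_class(fit, "csat_fit")
  expect_named(coef(fit), c("csat_nM", "slope"))
  expect_length(confint(fit), 2)
  expect_output(print(fit), "Saturation concentration")
  expect_output(summary(fit), "bootstrap")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
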