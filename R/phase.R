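#' Assemble a SPARK-signal vs concentration phase-separation curve
#'
#' @param measurements data.frame with at least `concentration_nM` and
#'   `spark_signal` columns (e.g. [measure_cells()] output joined with
#'   concentrations), one row per cell.
#' @param condition optional condition label attached to the curve (e.g.
#'   "+rapamycin").
#' @return data.frame of class `phase_curve`, sorted by concentration, with
#'   columns `cell_id`, `concentration_nM`, `spark_signal`, `condition`.
#' @export
build_phase_curve <- function(measurements, condition = "untreated") {
  if (is.null(measurements) || nrow(measurements) == 0)
    stop("no cell measurements supplied")
  stopifnot(all(c("concentration_nM", "spark_signal") %in%
                  names(measurements)))
  if (any(measurements$concentration_nM <= 0))
    stop("concentrations must be > 0")
  if (any(measurements$spark_signal < 0 | measurements$spark_signal > 1))
    stop("spark_signal must lie in [0, 1]")
  out <- data.frame(
    cell_id = if ("cell_id" %in% names(measurements))
      measurements$cell_id else seq_len(nrow(measurements)),
    concentration_nM = measurements$concentration_nM,
    spark_signal = measurements$spark_signal,
    condition = condition)
  out <- out[order(out$concentration_nM), ]
  rownames(out) <- NULL
  if (stats::var(out$concentration_nM) == 0 ||
      stats::var(out$spark_signal) == 0)
    attr(out, "degenerate") <- TRUE
  class(out) <- c("phase_curve", "data.frame")
  out
}

## Least-squares hinge fit over a fixed candidate grid. Model below the
## breakpoint b: spark = 0; above: a * (1 - b/c) ("saturating") or
## a * (c - b) ("linear"). Returns breakpoint, slope and RSS.
hinge_fit <- function(conc, spark, grid, rise = "saturating") {
  x <- if (rise == "saturating")
    pmax(1 - outer(1 / conc, grid), 0)        # n x K basis
  else pmax(outer(conc, grid, `-`), 0)
  sxy <- colSums(x * spark)
  sxx <- colSums(x * x)
  slope <- ifelse(sxx > 0, pmax(0, sxy / sxx), 0)
  rss <- sum(spark^2) - 2 * slope * sxy + slope^2 * sxx
  k <- which.min(rss)
  list(csat = grid[k], slope = slope[k], rss = rss[k])
}

csat_grid <- function(conc) {
  u <- sort(unique(conc))
  if (length(u) < 3) return(u)
  mid <- sqrt(u[-1] * u[-length(u)])          # geometric midpoints
  grid <- sort(unique(c(u, mid)))
  grid[grid < max(u)]                          # need >= 1 point above b
}

#' Estimate the saturation concentration from a phase curve
#'
#' Fits a hinge changepoint model to per-cell (concentration, SPARK) pairs:
#' SPARK is zero below the saturation concentration `c_sat` and rises above
#' it — by default along the saturating form `a (1 - c_sat / c)` implied by
#' a dilute phase pinned at `c_sat` (a linear rise is available). The
#' breakpoint is found by least squares over a grid of observed
#' concentrations and their geometric midpoints; the confidence interval is
#' a percentile bootstrap over cells.
#'
#' @param curve a [build_phase_curve()] result (>= 10 cells recommended,
#'   spanning both sides of the breakpoint).
#' @param n_bootstrap bootstrap replicates for the CI.
#' @param rise `"saturating"` (default) or `"linear"` rise above the
#'   breakpoint.
#' @param conf_level CI coverage.
#' @param spark_zero_tol cells at or below this SPARK value count as
#'   sub-threshold when checking identifiability.
#' @param seed integer seed for the bootstrap or `NULL`.
#' @return object of class `csat_fit` with components `csat_nM`, `ci_nM`,
#'   `slope`, `rss`, `boot` (bootstrap estimates), `curve`, `rise`.
#' @export
estimate_csat <- function(curve, n_bootstrap = 1000, rise = c("saturating",
                                                              "linear"),
                          conf_level = 0.95, spark_zero_tol = 0.02,
                          seed = NULL) {
  rise <- match.arg(rise)
  stopifnot(inherits(curve, "phase_curve"), n_bootstrap >= 0)
  conc <- curve$concentration_nM
  spark <- curve$spark_signal
  n_sub <- sum(spark <= spark_zero_tol)
  n_super <- sum(spark > spark_zero_tol)
  if (n_sub == 0)
    stop("c_sat unidentifiable: no sub-threshold (SPARK ~ 0) cells")
  if (n_super == 0)
    stop("c_sat unidentifiable: no super-threshold (SPARK > 0) cells")
  grid <- csat_grid(conc)
  fit <- hinge_fit(conc, spark, grid, rise)
  boot <- numeric(0)
  ci <- c(NA_real_, NA_real_)
  if (n_bootstrap > 0) {
    boot <- with_seed(seed, {
      vapply(seq_len(n_bootstrap), function(b) {
        i <- sample.int(length(conc), replace = TRUE)
        hinge_fit(conc[i], spark[i], csat_grid(conc[i]), rise)$csat
      }, numeric(1))
    })
    alpha <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  }
  structure(list(csat_nM = fit$csat, ci_nM = ci, slope = fit$slope,
                 rss = fit$rss, boot = boot, n_cells = length(conc),
                 conf_level = conf_level, rise = rise, curve = curve),
            class = "csat_fit")
}

#' @export
print.csat_fit <- function(x, ...) {
  cat(sprintf("Saturation concentration: %.3g nM", x$csat_nM))
  if (!anyNA(x$ci_nM))
    cat(sprintf(" (%.0f%% bootstrap CI %.3g to %.3g nM)",
                100 * x$conf_level, x$ci_nM[1], x$ci_nM[2]))
  cat(sprintf("\n  hinge fit (%s rise) over %d cells, RSS %.4g\n",
              x$rise, x$n_cells, x$rss))
  invisible(x)
}

#' @export
summary.csat_fit <- function(object, ...) {
  cat("Phase-separation curve changepoint fit\n")
  print(object)
  s <- object$curve$spark_signal
  cat(sprintf("  cells: %d sub-threshold (SPARK <= 0.02), %d super-threshold\n",
              sum(s <= 0.02), sum(s > 0.02)))
  if (length(object$boot))
    cat(sprintf("  bootstrap: %d replicates, sd %.3g nM\n",
                length(object$boot), stats::sd(object$boot)))
  invisible(object)
}

#' @export
coef.csat_fit <- function(object, ...) {
  c(csat_nM = object$csat_nM, slope = object$slope)
}

#' @export
confint.csat_fit <- function(object, parm, level, ...) {
  object$ci_nM
}

#' Plot a phase curve and its fitted changepoint
#'
#' @param x a `csat_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.csat_fit <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$concentration_nM, cv$spark_signal, log = "x",
                 xlab = "concentration (nM)", ylab = "SPARK signal",
                 pch = 16, col = "grey30", ...)
  cc <- exp(seq(log(min(cv$concentration_nM)),
                log(max(cv$concentration_nM)), length.out = 200))
  yy <- if (x$rise == "saturating")
    x$slope * pmax(0, 1 - x$csat_nM / cc)
  else x$slope * pmax(0, cc - x$csat_nM)
  graphics::lines(cc, yy, col = "firebrick", lwd = 2)
  graphics::abline(v = x$csat_nM, lty = 2, col = "firebrick")
  invisible(x)
}

#' Compare saturation concentrations between two conditions
#'
#' Difference of the two hinge-fit `c_sat` estimates with a paired bootstrap
#' CI (cells resampled independently within each curve per replicate).
#'
#' @param curve_a,curve_b [build_phase_curve()] results (e.g. -/+
#'   rapamycin).
#' @param n_bootstrap bootstrap replicates.
#' @param rise,conf_level,seed as in [estimate_csat()].
#' @return object of class `csat_shift`: `shift_nM` (b minus a), `ci_nM`,
#'   and the two `csat_fit`s.
#' @export
compare_csat <- function(curve_a, curve_b, n_bootstrap = 1000,
                         rise = "saturating", conf_level = 0.95,
                         seed = NULL) {
  fit_a <- estimate_csat(curve_a, n_bootstrap = 0, rise = rise)
  fit_b <- estimate_csat(curve_b, n_bootstrap = 0, rise = rise)
  boot <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      ia <- sample.int(nrow(curve_a), replace = TRUE)
      ib <- sample.int(nrow(curve_b), replace = TRUE)
      ca <- hinge_fit(curve_a$concentration_nM[ia],
                      curve_a$spark_signal[ia],
                      csat_grid(curve_a$concentration_nM[ia]), rise)$csat
      cb <- hinge_fit(curve_b$concentration_nM[ib],
                      curve_b$spark_signal[ib],
                      csat_grid(curve_b$concentration_nM[ib]), rise)$csat
      cb - ca
    }, numeric(1))
  })
  alpha <- (1 - conf_level) / 2
  structure(list(shift_nM = fit_b$csat_nM - fit_a$csat_nM,
                 ci_nM = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
                 fit_a = fit_a, fit_b = fit_b, boot = boot,
                 conf_level = conf_level),
            class = "csat_shift")
}

#' @export
print.csat_shift <- function(x, ...) {
  cat(sprintf(
    "c_sat shift: %.3g nM (%.3g -> %.3g nM; %.0f%% bootstrap CI %.3g to %.3g)\n",
    x$shift_nM, x$fit_a$csat_nM, x$fit_b$csat_nM, 100 * x$conf_level,
    x$ci_nM[1], x$ci_nM[2]))
  invisible(x)
}
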