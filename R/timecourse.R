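#' Measure condensate and chromatin traces from a time-lapse movie
#'
#' For each frame: segments the cell on the condensate channel, runs
#' condensate detection, and records the SPARK signal and total
#' background-subtracted cell fluorescence. If a histone (H2B) channel is
#' supplied, the chromosome volume is measured as the number of
#' above-threshold voxels (per-frame Otsu within the H2B channel) times the
#' voxel volume.
#'
#' @param movie condensate-channel movie (2D+t or 3D+t [image_stack()]).
#' @param h2b optional histone-channel movie of the same geometry.
#' @param k,min_size_px passed to [detect_condensates()].
#' @param time_unit `"s"` or `"min"` for the `t` column.
#' @return data.frame of class `time_course`: `frame`, `t`, `spark_signal`,
#'   `total_fluorescence`, `n_condensates` and (with `h2b`)
#'   `chrom_volume_um3`.
#' @export
measure_timecourse <- function(movie, h2b = NULL, k = 3, min_size_px = 4,
                               time_unit = c("s", "min")) {
  time_unit <- match.arg(time_unit)
  nf <- n_frames(movie)
  px <- pixel_size(movie)
  dt <- attr(movie, "frame_interval_s")
  if (time_unit == "min") dt <- dt / 60
  rows <- vector("list", nf)
  for (j in seq_len(nf)) {
    fr <- get_frame(movie, j)
    seg <- segment_cells(fr, min_size_px = 50)
    cmask <- seg$labels == which.max(seg$cells$area_px)
    det <- detect_condensates(fr, cmask, k = k, min_size_px = min_size_px)
    row <- data.frame(
      frame = j, t = (j - 1) * dt,
      spark_signal = spark_signal(det, cmask, fr),
      total_fluorescence = sum(fr[cmask] - det$background),
      n_condensates = nrow(det$objects))
    if (!is.null(h2b)) {
      fh <- get_frame(h2b, j)
      thr <- otsu_threshold(fh)
      row$chrom_volume_um3 <- sum(fh > thr) * px^length(dim(fh))
    }
    rows[[j]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "time_unit") <- time_unit
  class(out) <- c("time_course", "data.frame")
  out
}

#' Summarize condensate dissolution from a time course
#'
#' Normalizes the SPARK trace to 1 at time zero and reports the completion
#' time (first time the normalized signal drops below `epsilon`) and the
#' total-fluorescence drift, `max |total(t)/total(0) - 1|`, which should be
#' small when the dissolving protein is conserved in the cell.
#'
#' @param tc a [measure_timecourse()] result (>= 3 frames).
#' @param epsilon completion criterion on the normalized SPARK signal.
#' @return list of class `dissolution_summary`: `completion_t` (`NA` with
#'   `completed = FALSE` if the signal never falls below `epsilon`),
#'   `drift`, `spark_norm`, `time_unit`.
#' @export
dissolution_summary <- function(tc, epsilon = 0.05) {
  stopifnot(inherits(tc, "time_course"), nrow(tc) >= 3,
            epsilon > 0, epsilon < 1)
  if (tc$spark_signal[1] <= 0)
    stop("no condensates at time 0: nothing to dissolve")
  norm <- tc$spark_signal / tc$spark_signal[1]
  idx <- which(norm < epsilon)
  completed <- length(idx) > 0
  drift <- max(abs(tc$total_fluorescence / tc$total_fluorescence[1] - 1))
  structure(list(
    completion_t = if (completed) tc$t[idx[1]] else NA_real_,
    completed = completed, epsilon = epsilon, drift = drift,
    spark_norm = norm, t = tc$t,
    time_unit = attr(tc, "time_unit") %||% "s"),
    class = "dissolution_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dissolution_summary <- function(x, ...) {
  if (x$completed)
    cat(sprintf("Dissolution completed at t = %.3g %s (normalized SPARK < %g)\n",
                x$completion_t, x$time_unit, x$epsilon))
  else cat(sprintf("Dissolution not completed (normalized SPARK never < %g)\n",
                   x$epsilon))
  cat(sprintf("Total-fluorescence drift: %.2f%%\n", 100 * x$drift))
  invisible(x)
}

## Two-segment piecewise-constant changepoint: index k (1 <= k < n) after
## which the second segment starts, minimizing within-segment sum of
## squares. Vectorized with cumulative sums.
changepoint_index <- function(y) {
  n <- length(y)
  stopifnot(n >= 2)
  cs <- cumsum(y)
  cs2 <- cumsum(y^2)
  k <- seq_len(n - 1)
  rss1 <- cs2[k] - cs[k]^2 / k
  rss2 <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  which.min(rss1 + rss2)
}

#' Signed timing offset between two trace events
#'
#' Detects one changepoint per trace (the split minimizing the two-segment
#' piecewise-constant residual) and returns the time difference
#' `t(event_a) - t(event_b)`, where each event time is the first frame of
#' the second segment. Negative values mean event A precedes event B.
#'
#' @param tc a [measure_timecourse()] result.
#' @param trace_a,trace_b column names in `tc` (e.g. `"spark_signal"` for
#'   condensate dissolution, `"chrom_volume_um3"` for chromosome
#'   condensation).
#' @return list of class `event_timing`: `offset_t`, `t_a`, `t_b`, the two
#'   changepoint indices and the time unit.
#' @export
event_timing_offset <- function(tc, trace_a = "spark_signal",
                                trace_b = "chrom_volume_um3") {
  stopifnot(inherits(tc, "time_course"),
            all(c(trace_a, trace_b) %in% names(tc)))
  ka <- changepoint_index(tc[[trace_a]])
  kb <- changepoint_index(tc[[trace_b]])
  t_a <- tc$t[ka + 1]
  t_b <- tc$t[kb + 1]
  structure(list(offset_t = t_a - t_b, t_a = t_a, t_b = t_b,
                 k_a = ka, k_b = kb,
                 time_unit = attr(tc, "time_unit") %||% "s"),
            class = "event_timing")
}

#' @export
print.event_timing <- function(x, ...) {
  cat(sprintf("Event timing: A at t = %.3g, B at t = %.3g; offset %+.3g %s\n",
              x$t_a, x$t_b, x$offset_t, x$time_unit))
  invisible(x)
}
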