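## Intensity-weighted second-moment shape of one labeled object in a 2D
## frame: aspect ratio = sqrt of the ratio of covariance eigenvalues.
object_shape <- function(img, idx, bg) {
  d <- dim(img)
  co <- arrayInd(idx, d)
  w <- pmax(img[idx] - bg, 0)
  if (sum(w) <= 0) w <- rep(1, length(idx))
  w <- w / sum(w)
  mu <- colSums(co * w)
  cc <- sweep(co, 2, mu)
  cov <- crossprod(cc * sqrt(w))               # 2x2 weighted covariance
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 1e-9)
  list(centroid = mu, aspect_ratio = sqrt(ev[1] / ev[2]),
       area_px = length(idx))
}

#' Track droplet-fusion events in a time-lapse movie
#'
#' Objects are segmented per frame (Otsu threshold, 8-connected components,
#' minimum-size filtered) and linked by nearest centroid. A fusion event
#' opens at the first frame where two tracked objects have merged into one
#' connected component; from that frame on, the merged object's aspect ratio
#' is measured from its intensity-weighted second-moment ellipse
#' (sqrt of major/minor covariance eigenvalue ratio). The event's length
#' scale `ell` is the equivalent radius of the final fused droplet.
#'
#' @param movie a 2D+t [image_stack()].
#' @param min_size_px minimum object size per frame.
#' @param threshold optional fixed threshold; `NULL` uses Otsu per frame.
#' @return list of `fusion_event` objects (possibly empty). Each is a
#'   data.frame with columns `frame`, `t_s`, `aspect_ratio`, `area_px` and
#'   attributes `ell_um` and `onset_frame`.
#' @export
track_fusion_events <- function(movie, min_size_px = 8, threshold = NULL) {
  nf <- n_frames(movie)
  if (nf < 3) stop("need at least 3 frames")
  px <- pixel_size(movie)
  dt <- attr(movie, "frame_interval_s")
  frames <- vector("list", nf)
  for (j in seq_len(nf)) {
    fr <- get_frame(movie, j)
    thr <- if (is.null(threshold)) otsu_threshold(fr) else threshold
    mask <- fr > thr
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_size_px)
    bg <- stats::median(fr[!mask])
    objs <- lapply(keep, function(k) object_shape(fr, which(lab == k), bg))
    frames[[j]] <- objs
  }
  counts <- lengths(frames)
  events <- list()
  j <- 2
  while (j <= nf) {
    if (counts[j - 1] >= 2 && counts[j] == counts[j - 1] - 1) {
      ## a merge happened between j-1 and j: follow the merged object,
      ## chosen as the frame-j object closest to the midpoint of the two
      ## nearest frame-(j-1) objects
      prev <- frames[[j - 1]]
      curr <- frames[[j]]
      pc <- do.call(rbind, lapply(prev, `[[`, "centroid"))
      dmat <- as.matrix(stats::dist(pc))
      diag(dmat) <- Inf
      pair <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
      mid <- colMeans(pc[pair, , drop = FALSE])
      cc <- do.call(rbind, lapply(curr, `[[`, "centroid"))
      tgt <- which.min(colSums((t(cc) - mid)^2))
      rows <- list()
      tgt_c <- cc[tgt, ]
      for (jj in j:nf) {
        objs <- frames[[jj]]
        if (length(objs) == 0) break
        oc <- do.call(rbind, lapply(objs, `[[`, "centroid"))
        k <- which.min(colSums((t(oc) - tgt_c)^2))
        tgt_c <- oc[k, ]
        rows[[length(rows) + 1]] <- data.frame(
          frame = jj, t_s = (jj - j) * dt,
          aspect_ratio = objs[[k]]$aspect_ratio,
          area_px = objs[[k]]$area_px)
      }
      ev <- do.call(rbind, rows)
      last <- ev[nrow(ev), ]
      attr(ev, "ell_um") <- sqrt(last$area_px / pi) * px
      attr(ev, "onset_frame") <- j
      class(ev) <- c("fusion_event", "data.frame")
      events[[length(events) + 1]] <- ev
      j <- nf + 1                      # one event per movie track
    } else j <- j + 1
  }
  events
}

#' Fit single-exponential aspect-ratio relaxation to a fusion event
#'
#' Nonlinear least squares of `AR(t) = 1 + (AR0 - 1) exp(-t / tau)`; the
#' inverse capillary velocity (viscosity over surface tension) is
#' `tau / ell` with `ell` the event's length scale.
#'
#' @param event a `fusion_event` from [track_fusion_events()], or any
#'   data.frame with `t_s` and `aspect_ratio` columns and an `ell_um`
#'   attribute (pass `ell_um` explicitly otherwise).
#' @param ell_um length scale override (um).
#' @return object of class `fusion_fit`: `tau_s`, `ar0`, `ell_um`,
#'   `inv_cap_velocity` (s/um), `rms_residual`, `converged`.
#' @export
fit_relaxation <- function(event, ell_um = NULL) {
  stopifnot(all(c("t_s", "aspect_ratio") %in% names(event)))
  if (nrow(event) < 4) stop("need at least 4 post-onset frames")
  if (is.null(ell_um)) ell_um <- attr(event, "ell_um")
  if (is.null(ell_um)) stop("no length scale: supply ell_um")
  t <- event$t_s
  ar <- event$aspect_ratio
  if (max(ar) < 1.05)
    stop("degenerate fit: aspect ratio never exceeds 1.05")
  ## fit the active relaxation: once AR has settled near 1 the measurement
  ## noise floor (AR >= 1 by construction) would bias tau upward, so keep
  ## only two frames past the first near-spherical one
  settle <- which(ar - 1 < 0.05 * (max(ar) - 1))
  if (length(settle) && settle[1] + 2 < length(ar) &&
      settle[1] + 2 >= 4) {
    keep <- seq_len(settle[1] + 2)
    t <- t[keep]
    ar <- ar[keep]
  }
  ## starting values from a log-linear fit on the decaying part
  pos <- which(ar > 1.02)
  start_tau <- if (length(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(ar[pos] - 1) ~ t[pos]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(t)) / 3
  } else diff(range(t)) / 3
  fit <- minpack.lm::nlsLM(
    ar ~ 1 + (ar0 - 1) * exp(-t / tau),
    start = list(ar0 = max(ar), tau = max(start_tau, 1e-6)),
    lower = c(ar0 = 1 + 1e-9, tau = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  rms <- sqrt(mean(stats::residuals(fit)^2))
  structure(list(tau_s = unname(cf["tau"]), ar0 = unname(cf["ar0"]),
                 ell_um = ell_um,
                 inv_cap_velocity = unname(cf["tau"]) / ell_um,
                 rms_residual = rms,
                 converged = fit$convInfo$isConv, fit = fit, event = event),
            class = "fusion_fit")
}

#' @export
print.fusion_fit <- function(x, ...) {
  cat(sprintf(
    "Fusion relaxation fit: tau = %.3g s, AR0 = %.3g, ell = %.3g um\n  inverse capillary velocity tau/ell = %.3g s/um (RMS residual %.3g)\n",
    x$tau_s, x$ar0, x$ell_um, x$inv_cap_velocity, x$rms_residual))
  invisible(x)
}

#' @export
coef.fusion_fit <- function(object, ...) {
  c(tau_s = object$tau_s, ar0 = object$ar0,
    inv_cap_velocity = object$inv_cap_velocity)
}

#' Pool inverse capillary velocities over fusion events
#'
#' Arithmetic mean and sample sd of `tau / ell` over successfully fitted
#' events; fits whose RMS residual exceeds `residual_tol` (in aspect-ratio
#' units) are excluded, mirroring the manual curation of noisy events.
#'
#' @param fits list of [fit_relaxation()] results (>= 2 retained fits).
#' @param residual_tol RMS residual threshold for inclusion.
#' @return list of class `fusion_summary`: `mean_s_per_um`, `sd_s_per_um`,
#'   `n`, `n_excluded`, `velocities`.
#' @export
summarize_inverse_capillary_velocity <- function(fits, residual_tol = 0.1) {
  stopifnot(length(fits) >= 1)
  ok <- vapply(fits, function(f) f$rms_residual <= residual_tol &&
                 isTRUE(f$converged), logical(1))
  if (sum(ok) < 2)
    stop("need at least 2 fusion fits within the residual tolerance")
  v <- vapply(fits[ok], `[[`, numeric(1), "inv_cap_velocity")
  structure(list(mean_s_per_um = mean(v), sd_s_per_um = stats::sd(v),
                 n = length(v), n_excluded = sum(!ok), velocities = v),
            class = "fusion_summary")
}

#' @export
print.fusion_summary <- function(x, ...) {
  cat(sprintf(
    "Inverse capillary velocity: %.2f +/- %.2f s/um (n = %d%s)\n",
    x$mean_s_per_um, x$sd_s_per_um, x$n,
    if (x$n_excluded) paste0(", ", x$n_excluded, " excluded") else ""))
  invisible(x)
}
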