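#' Ground-truth parameters for synthetic condensate imaging
#'
#' Collects every knob of the single-cell image generator. The defaults
#' describe a nuclear transcription-factor condensate system: condensates
#' appear only above a saturation concentration `csat_nM` and are
#' `partition_ratio` times denser than the surrounding dilute phase
#' (per-cell ratio drawn uniformly when a range of length 2 is given).
#'
#' Intensity scale: the pre-noise signal inside the nucleus averages
#' `calib_slope * concentration` counts/pixel, so a standard curve fitted on
#' dilution-series images recovers `calib_slope`. The camera adds `offset`
#' counts and Poisson shot noise (photo-electron gain `gain`) plus Gaussian
#' read noise.
#'
#' @param csat_nM saturation concentration (nM) above which condensates form.
#' @param partition_ratio condensed/dilute density ratio; scalar or range.
#' @param cond_excess_fraction fraction of the above-`csat_nM` concentration
#'   excess that resides in condensates, so the true condensate-resident
#'   fluorescence fraction is `cond_excess_fraction * (1 - csat_nM / C)`.
#' @param condensate_radius_um mean condensate radius (um).
#' @param condensate_radius_cv lognormal spread of condensate radii.
#' @param psf_sigma_um Gaussian point-spread-function sigma (um).
#' @param pixel_size_um pixel edge (um).
#' @param nucleus_radius_um mean nucleus radius (um).
#' @param gain photo-electrons per count for Poisson shot noise.
#' @param read_noise_sd Gaussian read noise sd (counts).
#' @param offset camera offset (counts); this is also the intercept of the
#'   matching calibration curve.
#' @param calib_slope counts/pixel per nM linking intensity to concentration.
#' @param max_cond_fraction cap on the condensate area fraction; above it the
#'   condensed-phase density rises instead (late-stage ripening).
#' @param bit_depth camera bit depth; saturated pixels are clipped with a
#'   warning.
#' @param seed integer seed making all draws reproducible; `NULL` uses the
#'   caller's RNG stream.
#' @return an object of class `imaging_ground_truth` (a validated list).
#' @export
imaging_ground_truth <- function(csat_nM = 40, partition_ratio = c(5, 10),
                                 cond_excess_fraction = 0.5,
                                 condensate_radius_um = 0.6,
                                 condensate_radius_cv = 0.25,
                                 psf_sigma_um = 0.15, pixel_size_um = 0.2,
                                 nucleus_radius_um = 8, gain = 2,
                                 read_noise_sd = 3, offset = 100,
                                 calib_slope = 2, max_cond_fraction = 0.4,
                                 bit_depth = 16, seed = NULL) {
  stopifnot(csat_nM > 0, all(partition_ratio > 1),
            length(partition_ratio) %in% c(1, 2),
            cond_excess_fraction > 0, cond_excess_fraction <= 1,
            condensate_radius_um > 0, condensate_radius_cv >= 0,
            psf_sigma_um >= 0, pixel_size_um > 0, nucleus_radius_um > 0,
            gain > 0, read_noise_sd >= 0, offset >= 0, calib_slope > 0,
            max_cond_fraction > 0, max_cond_fraction <= 0.9)
  out <- list(csat_nM = csat_nM, partition_ratio = sort(partition_ratio),
              cond_excess_fraction = cond_excess_fraction,
              condensate_radius_um = condensate_radius_um,
              condensate_radius_cv = condensate_radius_cv,
              psf_sigma_um = psf_sigma_um, pixel_size_um = pixel_size_um,
              nucleus_radius_um = nucleus_radius_um, gain = gain,
              read_noise_sd = read_noise_sd, offset = offset,
              calib_slope = calib_slope,
              max_cond_fraction = max_cond_fraction, bit_depth = bit_depth,
              seed = seed)
  class(out) <- "imaging_ground_truth"
  out
}

## Partial-partitioning split of a cellular concentration C: below csat all
## protein is dilute; above, a fraction `kappa` of the excess condenses into
## a phase `ratio` times denser than the (still rising) dilute phase. This
## reproduces measured phase curves, where the condensate-resident fraction
## of fluorescence rises as kappa * (1 - csat / C). The area fraction
## f = kappa (C - csat) / (ratio * dilute) stays well below 1.
phase_split <- function(C, csat, ratio, kappa, fmax = 0.4) {
  if (C <= csat) return(list(f = 0, cond_conc = NA_real_, dilute_conc = C))
  dilute <- C - kappa * (C - csat)
  cond <- ratio * dilute
  f <- min(kappa * (C - csat) / cond, fmax)
  list(f = f, cond_conc = cond, dilute_conc = dilute)
}

## Place n discs of radii r_px inside a disc of radius R_px centred at
## `center`, keeping at least `margin` pixels of clearance between disc
## rims (condensates that close would have fused, and the PSF would merge
## their images). Falls back to accepting overlaps after max_try draws.
place_discs <- function(n, r_px, R_px, center, max_try = 200, margin = 1) {
  pos <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    for (try in seq_len(max_try)) {
      rho <- sqrt(stats::runif(1)) * max(R_px - r_px[i] - 1, 0.5)
      th <- stats::runif(1, 0, 2 * pi)
      p <- center + rho * c(cos(th), sin(th))
      ok <- TRUE
      if (i > 1) {
        dd <- sqrt(rowSums((pos[seq_len(i - 1), , drop = FALSE] -
                              matrix(p, i - 1, 2, byrow = TRUE))^2))
        ok <- all(dd > r_px[i] + r_px[seq_len(i - 1)] + margin)
      }
      if (ok || try == max_try) { pos[i, ] <- p; break }
    }
  }
  pos
}

## Camera model: Poisson shot noise on the photon-scaled signal, camera
## offset, Gaussian read noise, clipping to the sensor range.
apply_camera <- function(prenoise, gt) {
  n <- length(prenoise)
  shot <- gt$gain * stats::rpois(n, pmax(prenoise, 0) / gt$gain)
  img <- shot + gt$offset + stats::rnorm(n, 0, gt$read_noise_sd)
  top <- 2^gt$bit_depth - 1
  if (any(img > top)) {
    warning("saturated pixels clipped at ", top)
    img <- pmin(img, top)
  }
  out <- array(round(pmax(img, 0)), dim(prenoise))
  attributes(out) <- attributes(prenoise)
  out
}

render_cell <- function(gt, C) {
  px <- gt$pixel_size_um
  psf_px <- gt$psf_sigma_um / px
  R_px <- gt$nucleus_radius_um / px * stats::runif(1, 0.95, 1.05)
  margin <- ceiling(max(6, 3 * psf_px))
  n_px <- 2L * ceiling(gt$nucleus_radius_um * 1.05 / px) + 2L * margin + 1L
  center <- rep((n_px + 1) / 2, 2)
  nuc <- raster_ball(c(n_px, n_px), center, R_px)
  A <- sum(nuc)

  ratio <- if (length(gt$partition_ratio) == 2)
    stats::runif(1, gt$partition_ratio[1], gt$partition_ratio[2])
  else gt$partition_ratio
  ps <- phase_split(C, gt$csat_nM, ratio, gt$cond_excess_fraction,
                    gt$max_cond_fraction)

  cov <- array(0, c(n_px, n_px))
  n_c <- 0L
  if (ps$f > 0) {
    r0 <- gt$condensate_radius_um / px
    n_c <- max(1L, as.integer(round(ps$f * A / (pi * r0^2))))
    radii <- stats::rlnorm(n_c, log(r0), gt$condensate_radius_cv)
    radii <- radii * sqrt(ps$f * A / sum(pi * radii^2))
    pos <- place_discs(n_c, radii, R_px, center)
    for (i in seq_len(n_c))
      cov <- cov + raster_disc_cov(c(n_px, n_px), pos[i, ], radii[i])
    cov <- pmin(cov, 1)
    cov[!nuc] <- 0
  }
  S <- sum(cov)

  ## intensity levels: ratio held exactly at the drawn partition ratio,
  ## dilute level solved so the pre-noise total equals slope * C * area
  s <- gt$calib_slope
  total <- s * C * A
  if (S > 0) {
    rr <- ps$cond_conc / ps$dilute_conc
    dilute_level <- total / (A + (rr - 1) * S)
    cond_level <- rr * dilute_level
  } else {
    cond_level <- NA_real_
    dilute_level <- total / A
  }

  pre <- array(0, c(n_px, n_px))
  pre[nuc] <- dilute_level
  if (S > 0) pre <- pre + (cond_level - dilute_level) * cov
  pre <- image_stack(pre, px)
  pre_blur <- gaussian_blur(pre, psf_px)
  img <- apply_camera(pre_blur, gt)

  truth <- data.frame(
    concentration_nM = C, csat_nM = gt$csat_nM,
    partition_ratio = if (S > 0) cond_level / dilute_level else NA_real_,
    n_condensates = n_c, cond_fraction = S / A,
    dilute_pre = dilute_level, cond_pre = cond_level,
    total_pre = total,
    spark_true = if (S > 0) cond_level * S / total else 0,
    nucleus_area_um2 = A * px^2)
  list(image = img, prenoise = pre, truth = truth)
}

#' Simulate single-cell condensate images across a concentration series
#'
#' Renders one nucleus per requested concentration. Below `csat_nM` the
#' nucleus is uniformly dilute; above it, condensates appear whose pre-noise
#' mean intensity is `partition_ratio` times the dilute level, with the
#' condensed area fraction following the lever rule so that total pre-noise
#' intensity stays proportional to concentration via `calib_slope`.
#'
#' @param gt an [imaging_ground_truth()] object.
#' @param concentrations vector of per-cell concentrations (nM), all > 0.
#' @param keep_prenoise also return the noise-free, pre-camera images.
#' @return a list with `images` (list of 2D [image_stack()]s), `truth`
#'   (one row per cell: true concentration, partition ratio, condensate
#'   count, condensed fraction, pre-noise intensity levels and the true SPARK
#'   signal) and, optionally, `prenoise`.
#' @export
generate_cell_images <- function(gt, concentrations, keep_prenoise = FALSE) {
  stopifnot(inherits(gt, "imaging_ground_truth"))
  if (length(concentrations) == 0) stop("concentrations must be non-empty")
  if (any(concentrations <= 0)) stop("concentrations must all be > 0")
  with_seed(gt$seed, {
    cells <- lapply(concentrations, function(C) render_cell(gt, C))
    truth <- do.call(rbind, lapply(cells, `[[`, "truth"))
    truth <- cbind(cell_id = seq_len(nrow(truth)), truth)
    out <- list(images = lapply(cells, `[[`, "image"), truth = truth, gt = gt)
    if (keep_prenoise) out$prenoise <- lapply(cells, `[[`, "prenoise")
    out
  })
}

#' Simulate a fluorophore dilution-series table
#'
#' Emulates imaging a purified fluorophore at known concentrations under the
#' same camera model as the cell generator: mean counts/pixel equal
#' `calib_slope * concentration + offset` plus a small measurement error
#' (standard error of a mean over `n_pixels` pixels).
#'
#' @param gt an [imaging_ground_truth()] object (supplies slope, offset and
#'   noise parameters).
#' @param concentrations dilution concentrations in nM.
#' @param n_pixels number of pixels averaged per dilution step.
#' @return data.frame with columns `concentration_nM`, `mean_intensity`.
#' @export
generate_dilution_table <- function(gt, concentrations = c(5, 10, 25, 50, 100,
                                                           250, 500),
                                    n_pixels = 10000) {
  stopifnot(inherits(gt, "imaging_ground_truth"), all(concentrations > 0))
  with_seed(gt$seed, {
    signal <- gt$calib_slope * concentrations
    se <- sqrt(signal * gt$gain + gt$read_noise_sd^2) / sqrt(n_pixels)
    data.frame(concentration_nM = concentrations,
               mean_intensity = signal + gt$offset + stats::rnorm(
                 length(concentrations), 0, se))
  })
}

#' Ground-truth parameters for droplet-fusion movies
#'
#' @param inv_cap_velocity_s_per_um inverse capillary velocity (viscosity /
#'   surface tension, s/um); only this ratio is identifiable from relaxation.
#' @param radii_um two-column matrix of initial droplet radii per event, or
#'   `NULL` to draw uniformly from `radius_range_um`.
#' @param radius_range_um range for drawn radii (um).
#' @param n_events number of fusion events.
#' @param frame_interval_s time between frames (s).
#' @param pixel_size_um pixel edge (um).
#' @param psf_sigma_um PSF sigma (um).
#' @param intensity droplet pre-noise intensity (counts/pixel).
#' @param gain,read_noise_sd,offset camera model, as in
#'   [imaging_ground_truth()].
#' @param n_pre_frames frames before contact showing two separate droplets.
#' @param seed integer seed or `NULL`.
#' @return an object of class `fusion_ground_truth`.
#' @export
fusion_ground_truth <- function(inv_cap_velocity_s_per_um = 1.8,
                                radii_um = NULL,
                                radius_range_um = c(0.3, 1.0),
                                n_events = 14, frame_interval_s = 0.5,
                                pixel_size_um = 0.1, psf_sigma_um = 0.1,
                                intensity = 300, gain = 2, read_noise_sd = 3,
                                offset = 100, n_pre_frames = 3, seed = NULL) {
  stopifnot(inv_cap_velocity_s_per_um > 0, n_events >= 1,
            frame_interval_s > 0, pixel_size_um > 0, intensity > 0)
  if (!is.null(radii_um)) {
    radii_um <- as.matrix(radii_um)
    stopifnot(ncol(radii_um) == 2, all(radii_um > 0))
    n_events <- nrow(radii_um)
  }
  out <- list(inv_cap_velocity_s_per_um = inv_cap_velocity_s_per_um,
              radii_um = radii_um, radius_range_um = radius_range_um,
              n_events = n_events, frame_interval_s = frame_interval_s,
              pixel_size_um = pixel_size_um, psf_sigma_um = psf_sigma_um,
              intensity = intensity, gain = gain,
              read_noise_sd = read_noise_sd, offset = offset,
              n_pre_frames = n_pre_frames, seed = seed)
  class(out) <- "fusion_ground_truth"
  out
}

render_fusion_event <- function(gt, r1, r2) {
  px <- gt$pixel_size_um
  rf <- sqrt(r1^2 + r2^2)              # area-conserving fused radius (um)
  if (rf / px < 2) stop("radii too small to render at this pixel size")
  tau <- gt$inv_cap_velocity_s_per_um * rf
  ar0 <- (r1 + r2) / rf
  dt <- gt$frame_interval_s
  n_post <- max(8L, min(40L, ceiling(5 * tau / dt) + 1L))

  half_w <- (r1 + r2 + 1.5) / px
  half_h <- (max(r1, r2) + 1.5) / px
  d <- c(2L * ceiling(half_h) + 1L, 2L * ceiling(half_w) + 1L)
  cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
  frames <- vector("list", gt$n_pre_frames + n_post)

  ## approach phase: two droplets closing a small gap (still disjoint)
  for (j in seq_len(gt$n_pre_frames)) {
    gap_px <- (gt$n_pre_frames - j + 1) * max(3, 2 * gt$psf_sigma_um / px + 2)
    m <- raster_ball(d, c(cy, cx - (r2 / px + gap_px / 2)), r1 / px) |
      raster_ball(d, c(cy, cx + (r1 / px + gap_px / 2)), r2 / px)
    frames[[j]] <- m
  }
  ## relaxation phase: area-conserved ellipse with AR(t) = 1+(AR0-1)e^(-t/tau)
  for (j in seq_len(n_post)) {
    t <- (j - 1) * dt
    ar <- 1 + (ar0 - 1) * exp(-t / tau)
    a <- rf / px * sqrt(ar)
    b <- rf / px / sqrt(ar)
    frames[[gt$n_pre_frames + j]] <- raster_ellipse(d, c(cy, cx), a, b)
  }

  psf_px <- gt$psf_sigma_um / px
  mov <- array(0, c(d, length(frames)))
  for (j in seq_along(frames)) {
    pre <- gaussian_blur(array(gt$intensity * frames[[j]], d), psf_px)
    mov[, , j] <- apply_camera(pre, gt)
  }
  mov <- image_stack(mov, px, gt$frame_interval_s, time_axis = 3L)
  list(movie = mov,
       truth = data.frame(r1_um = r1, r2_um = r2, ell_um = rf, tau_s = tau,
                          ar0 = ar0, onset_frame = gt$n_pre_frames + 1L,
                          inv_cap_velocity = gt$inv_cap_velocity_s_per_um))
}

#' Simulate droplet-fusion time-lapse movies
#'
#' Each event shows two droplets that touch and relax to a sphere: after
#' contact the object is rendered as an area-conserved ellipse whose aspect
#' ratio follows `AR(t) = 1 + (AR0 - 1) exp(-t / tau)` with
#' `tau = inv_cap_velocity * ell`, where `ell` is the equivalent radius of
#' the final fused droplet (the dumbbell intermediate is approximated because
#' only the aspect ratio is fitted downstream).
#'
#' @param gt a [fusion_ground_truth()] object.
#' @return list with `movies` (one 2D+t [image_stack()] per event) and
#'   `truth` (per event: radii, `ell_um`, `tau_s`, initial aspect ratio,
#'   onset frame and the ground-truth inverse capillary velocity).
#' @export
generate_fusion_movie <- function(gt) {
  stopifnot(inherits(gt, "fusion_ground_truth"))
  with_seed(gt$seed, {
    radii <- gt$radii_um
    if (is.null(radii))
      radii <- matrix(stats::runif(2 * gt$n_events, gt$radius_range_um[1],
                                   gt$radius_range_um[2]), ncol = 2)
    ev <- lapply(seq_len(nrow(radii)), function(i)
      render_fusion_event(gt, max(radii[i, ]), min(radii[i, ])))
    truth <- do.call(rbind, lapply(ev, `[[`, "truth"))
    truth <- cbind(event_id = seq_len(nrow(truth)), truth)
    list(movies = lapply(ev, `[[`, "movie"), truth = truth, gt = gt)
  })
}

#' Simulate a condensate-dissolution time series
#'
#' One nucleus imaged over time while its condensed fraction decays as
#' `f(t) = f0 exp(-t / decay_tau_s)` (use `decay_tau_s = Inf` for a stable
#' control). The per-frame pre-noise total intensity is held exactly constant
#' (protein is conserved; dissolving condensates raise the dilute level), as
#' in chemically induced condensate-dissolution experiments.
#'
#' @param gt an [imaging_ground_truth()] object.
#' @param concentration_nM cell concentration (must exceed `gt$csat_nM` for a
#'   non-trivial series).
#' @param decay_tau_s exponential decay timescale of the condensed fraction.
#' @param t_total_s total duration (s).
#' @param frame_interval_s frame interval (s).
#' @param keep_prenoise also return noise-free frames.
#' @return list with `movie` (2D+t [image_stack()]), `truth` (per frame:
#'   time, condensed fraction, true SPARK signal, pre-noise total intensity)
#'   and optionally `prenoise`.
#' @export
generate_dissolution_series <- function(gt, concentration_nM = 200,
                                        decay_tau_s = 60, t_total_s = 300,
                                        frame_interval_s = 15,
                                        keep_prenoise = FALSE) {
  stopifnot(inherits(gt, "imaging_ground_truth"), concentration_nM > 0,
            decay_tau_s > 0, t_total_s > 0, frame_interval_s > 0)
  times <- seq(0, t_total_s, by = frame_interval_s)
  if (length(times) < 2) stop("series must cover at least 2 frames")
  with_seed(gt$seed, {
    px <- gt$pixel_size_um
    psf_px <- gt$psf_sigma_um / px
    R_px <- gt$nucleus_radius_um / px
    margin <- ceiling(max(6, 3 * psf_px))
    n_px <- 2L * ceiling(R_px) + 2L * margin + 1L
    center <- rep((n_px + 1) / 2, 2)
    nuc <- raster_ball(c(n_px, n_px), center, R_px)
    A <- sum(nuc)

    ratio <- mean(gt$partition_ratio)
    ps <- phase_split(concentration_nM, gt$csat_nM, ratio,
                      gt$cond_excess_fraction, gt$max_cond_fraction)
    f0 <- ps$f
    r0 <- gt$condensate_radius_um / px
    n_c <- max(1L, as.integer(round(f0 * A / (pi * r0^2))))
    radii0 <- stats::rlnorm(n_c, log(r0), gt$condensate_radius_cv)
    radii0 <- radii0 * sqrt(max(f0, 1e-12) * A / sum(pi * radii0^2))
    pos <- place_discs(n_c, radii0, R_px, center)

    s <- gt$calib_slope
    total <- s * concentration_nM * A
    mov <- array(0, c(n_px, n_px, length(times)))
    pre_list <- if (keep_prenoise) vector("list", length(times)) else NULL
    truth <- data.frame(frame = seq_along(times), t_s = times,
                        cond_fraction = NA_real_, spark_true = NA_real_,
                        total_pre = NA_real_)
    rr <- ps$cond_conc / ps$dilute_conc
    ## the condensate-resident protein fraction q decays exponentially;
    ## solve the condensate area S back from q each frame
    cov0 <- array(0, c(n_px, n_px))
    for (i in seq_len(n_c))
      cov0 <- cov0 + raster_disc_cov(c(n_px, n_px), pos[i, ], radii0[i])
    cov0 <- pmin(cov0, 1)
    cov0[!nuc] <- 0
    S0 <- sum(cov0)
    q0 <- rr * S0 / (A + (rr - 1) * S0)
    for (j in seq_along(times)) {
      q_t <- q0 * exp(-times[j] / decay_tau_s)
      S_target <- q_t * A / (rr - (rr - 1) * q_t)
      scale <- sqrt(S_target / max(S0, 1e-12))
      cov <- array(0, c(n_px, n_px))
      if (q_t > 0) for (i in seq_len(n_c))
        cov <- cov + raster_disc_cov(c(n_px, n_px), pos[i, ],
                                     radii0[i] * scale)
      cov <- pmin(cov, 1)
      cov[!nuc] <- 0
      S <- sum(cov)
      if (S > 0) {
        dilute_level <- total / (A + (rr - 1) * S)
        cond_level <- rr * dilute_level
      } else {
        cond_level <- NA_real_
        dilute_level <- total / A
      }
      pre <- array(0, c(n_px, n_px))
      pre[nuc] <- dilute_level
      if (S > 0) pre <- pre + (cond_level - dilute_level) * cov
      pre <- gaussian_blur(pre, psf_px)
      if (keep_prenoise) pre_list[[j]] <- image_stack(pre, px)
      mov[, , j] <- apply_camera(pre, gt)
      truth$cond_fraction[j] <- S / A
      truth$spark_true[j] <- if (S > 0) cond_level * S / total else 0
      truth$total_pre[j] <- sum(pre)
    }
    mov <- image_stack(mov, px, frame_interval_s, time_axis = 3L)
    out <- list(movie = mov, truth = truth, gt = gt)
    if (keep_prenoise) out$prenoise <- pre_list
    out
  })
}

#' Simulate paired-channel puncta with a set colocalization probability
#'
#' For each cell, `puncta_per_cell` reference-channel puncta are placed in a
#' nucleus; each acquires a matched second-channel punctum with probability
#' `coloc_probability`, centred within `jitter_um` of the reference centroid.
#' Unmatched second-channel puncta (`n_distractors` on average) are added at
#' random positions, so a reference punctum can still overlap a distractor by
#' chance.
#'
#' @param n_cells number of cells.
#' @param puncta_per_cell mean reference puncta per cell (Poisson, min 1).
#' @param coloc_probability probability in `[0, 1]` that a reference punctum
#'   has a matched partner.
#' @param jitter_um sd of the centroid offset of matched partners (um).
#' @param n_distractors mean number of unmatched second-channel puncta.
#' @param gt an [imaging_ground_truth()] object for rendering parameters
#'   (pixel size, nucleus size, camera model).
#' @param punctum_radius_um punctum radius in both channels (um).
#' @param seed integer seed or `NULL` (a seed in `gt` is also honoured).
#' @return list with `cells` (per cell: `ref` and `other` 2D images) and
#'   `truth` (per cell: reference count, matched count).
#' @export
generate_coloc_channels <- function(n_cells = 13, puncta_per_cell = 10,
                                    coloc_probability = 0.94,
                                    jitter_um = 0.2, n_distractors = 3,
                                    gt = imaging_ground_truth(),
                                    punctum_radius_um = 0.5, seed = NULL) {
  stopifnot(n_cells >= 1, puncta_per_cell > 0,
            coloc_probability >= 0, coloc_probability <= 1, jitter_um >= 0)
  if (is.null(seed)) seed <- gt$seed
  with_seed(seed, {
    px <- gt$pixel_size_um
    psf_px <- gt$psf_sigma_um / px
    R_px <- gt$nucleus_radius_um / px
    margin <- ceiling(max(6, 3 * psf_px))
    n_px <- 2L * ceiling(R_px) + 2L * margin + 1L
    center <- rep((n_px + 1) / 2, 2)
    r_pt <- punctum_radius_um / px
    dilute <- 40; bright <- 400        # counts/pixel, pre-noise

    render_channel <- function(nuc, pts) {
      pre <- array(0, c(n_px, n_px))
      pre[nuc] <- dilute
      if (nrow(pts) > 0) for (i in seq_len(nrow(pts)))
        pre[raster_ball(c(n_px, n_px), pts[i, ], r_pt) & nuc] <- bright
      apply_camera(gaussian_blur(image_stack(pre, px), psf_px), gt)
    }

    cells <- vector("list", n_cells)
    truth <- data.frame(cell_id = seq_len(n_cells), n_ref = 0L,
                        n_matched = 0L)
    for (ci in seq_len(n_cells)) {
      nuc <- raster_ball(c(n_px, n_px), center, R_px)
      n_ref <- max(1L, stats::rpois(1, puncta_per_cell))
      ref_pts <- place_discs(n_ref, rep(r_pt, n_ref), R_px, center,
                             margin = 2 + 3 * psf_px)
      matched <- stats::runif(n_ref) < coloc_probability
      oth_pts <- ref_pts[matched, , drop = FALSE]
      if (nrow(oth_pts) > 0)
        oth_pts <- oth_pts + matrix(stats::rnorm(2 * nrow(oth_pts), 0,
                                                 jitter_um / px),
                                    ncol = 2)
      n_dis <- stats::rpois(1, n_distractors)
      if (n_dis > 0) {
        dis <- place_discs(n_dis, rep(r_pt, n_dis), R_px, center,
                           margin = 2 + 3 * psf_px)
        oth_pts <- rbind(oth_pts, dis)
      }
      cells[[ci]] <- list(ref = render_channel(nuc, ref_pts),
                          other = render_channel(nuc, oth_pts))
      truth$n_ref[ci] <- n_ref
      truth$n_matched[ci] <- sum(matched)
    }
    list(cells = cells, truth = truth)
  })
}

#' Simulate a mitotic-entry two-channel 3D time series
#'
#' Couples condensate dissolution to chromosome condensation: the condensate
#' channel shows a nucleus whose condensates dissolve around
#' `dissolve_time_min` (total channel intensity conserved), while the
#' chromatin channel shows a histone-labelled volume that contracts from
#' `volumes_um3[1]` to `volumes_um3[2]` around `condense_time_min` (total
#' histone signal conserved, so the condensed chromatin is brighter).
#'
#' @param dissolve_time_min time of condensate dissolution (min).
#' @param condense_time_min time of chromosome condensation (min).
#' @param volumes_um3 chromatin volume before and after condensation (um^3).
#' @param t_total_min series duration (min).
#' @param frame_interval_min frame interval (min).
#' @param transition_width_min logistic width of both transitions (min).
#' @param pixel_size_um isotropic voxel edge (um).
#' @param concentration_nM condensate-channel concentration (nM).
#' @param gt an [imaging_ground_truth()] object for the condensate channel;
#'   its `condensate_radius_um` should be resolvable at the voxel size.
#' @param seed integer seed or `NULL`.
#' @return list with `condensate` and `h2b` 3D+t [image_stack()]s and
#'   `truth` (event times, per-frame true condensed fraction and chromatin
#'   volume).
#' @export
generate_mitosis_series <- function(dissolve_time_min = 10,
                                    condense_time_min = 10,
                                    volumes_um3 = c(900, 450),
                                    t_total_min = 20,
                                    frame_interval_min = 1,
                                    transition_width_min = 0.3,
                                    pixel_size_um = 0.5,
                                    concentration_nM = 200,
                                    gt = imaging_ground_truth(
                                      condensate_radius_um = 1.2,
                                      psf_sigma_um = 0.3,
                                      pixel_size_um = 0.5,
                                      nucleus_radius_um = 6),
                                    seed = NULL) {
  stopifnot(dissolve_time_min >= 0, condense_time_min >= 0,
            all(volumes_um3 > 0), volumes_um3[2] <= volumes_um3[1],
            t_total_min > 0, frame_interval_min > 0)
  if (dissolve_time_min > t_total_min || condense_time_min > t_total_min)
    stop("event times must lie within the series span")
  if (is.null(seed)) seed <- gt$seed
  times <- seq(0, t_total_min, by = frame_interval_min)
  with_seed(seed, {
    px <- pixel_size_um
    psf_px <- gt$psf_sigma_um / px
    R_px <- gt$nucleus_radius_um / px
    margin <- ceiling(max(4, 3 * psf_px))
    nxy <- 2L * ceiling(R_px) + 2L * margin + 1L
    r_pre <- (3 * volumes_um3[1] / (4 * pi))^(1 / 3) / px
    nz <- 2L * ceiling(max(R_px, r_pre)) + 2L * margin + 1L
    d3 <- c(nxy, nxy, nz)
    center <- (d3 + 1) / 2
    nuc <- raster_ball(d3, center, R_px)
    V_nuc <- sum(nuc)

    ratio <- mean(gt$partition_ratio)
    ps <- phase_split(concentration_nM, gt$csat_nM, ratio,
                      gt$cond_excess_fraction, gt$max_cond_fraction)
    f0 <- ps$f
    r0 <- gt$condensate_radius_um / px
    n_c <- max(1L, as.integer(round(f0 * V_nuc / (4 / 3 * pi * r0^3))))
    radii0 <- rep(r0, n_c) * (f0 * V_nuc / (n_c * 4 / 3 * pi * r0^3))^(1 / 3)
    pos2 <- place_discs(n_c, radii0, R_px - 1, center[1:2])
    posz <- center[3] + stats::runif(n_c, -0.5, 0.5) *
      (R_px - radii0 - 1) * 1.2
    s <- gt$calib_slope
    total_cond <- s * concentration_nM * V_nuc
    h2b_total <- 200 * volumes_um3[1] / px^3   # counts conserved over time

    logistic <- function(t, t0, w) 1 / (1 + exp((t - t0) / w))
    cond_ch <- array(0, c(d3, length(times)))
    h2b_ch <- array(0, c(d3, length(times)))
    truth_fr <- data.frame(frame = seq_along(times), t_min = times,
                           cond_fraction = NA_real_,
                           chrom_volume_um3 = NA_real_)
    for (j in seq_along(times)) {
      keep <- logistic(times[j], dissolve_time_min, transition_width_min)
      scale <- keep^(1 / 3)
      cmask <- array(FALSE, d3)
      if (keep > 1e-3) for (i in seq_len(n_c)) {
        r_i <- radii0[i] * scale
        if (r_i >= 1) cmask <- cmask |
            raster_ball(d3, c(pos2[i, ], posz[i]), r_i)
      }
      cmask <- cmask & nuc
      N_c <- sum(cmask)
      if (N_c > 0 && N_c < V_nuc) {
        cond_level <- s * ps$cond_conc
        dil <- (total_cond - cond_level * N_c) / (V_nuc - N_c)
      } else { cond_level <- NA_real_; dil <- total_cond / V_nuc; N_c <- 0L }
      pre <- array(0, d3)
      pre[nuc] <- dil
      if (N_c > 0) pre[cmask] <- cond_level
      cond_ch[, , , j] <- apply_camera(gaussian_blur(pre, psf_px), gt)

      V_t <- volumes_um3[2] + (volumes_um3[1] - volumes_um3[2]) *
        logistic(times[j], condense_time_min, transition_width_min)
      r_t <- (3 * V_t / (4 * pi))^(1 / 3) / px
      chrom <- raster_ball(d3, center, r_t)
      pre_h <- array(0, d3)
      pre_h[chrom] <- h2b_total / sum(chrom)
      h2b_ch[, , , j] <- apply_camera(gaussian_blur(pre_h, psf_px), gt)

      truth_fr$cond_fraction[j] <- N_c / V_nuc
      truth_fr$chrom_volume_um3[j] <- sum(chrom) * px^3
    }
    cond_ch <- image_stack(cond_ch, px, frame_interval_min * 60,
                           time_axis = 4L)
    h2b_ch <- image_stack(h2b_ch, px, frame_interval_min * 60,
                          time_axis = 4L)
    list(condensate = cond_ch, h2b = h2b_ch,
         truth = list(dissolve_time_min = dissolve_time_min,
                      condense_time_min = condense_time_min,
                      frames = truth_fr))
  })
}
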