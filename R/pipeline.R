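#' Default pipeline configuration
#'
#' Nested list of every stage's parameters with the package's default
#' analysis settings (detection stringency `k = 3`, dissolution completion
#' criterion `epsilon = 0.05`, 1,000 bootstrap replicates, DEG thresholds
#' p < 0.01, |log2FC| >= 0.58, FDR < 0.1) and a global seed from which each
#' stage derives its own RNG stream. Simulation sizes are kept modest so a
#' full run stays interactive; every field can be overridden and the
#' configuration round-trips losslessly through YAML.
#'
#' @param seed global integer seed.
#' @return a named list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    calibration = list(concentrations_nM = c(5, 10, 25, 50, 100, 250, 500)),
    phase = list(n_cells = 60, conc_range_nM = c(5, 500),
                 csat_nM = 40, csat_rapamycin_nM = 150,
                 n_bootstrap = 1000, k = 3),
    fusion = list(n_events = 14, inv_cap_velocity_s_per_um = 1.8,
                  frame_interval_s = 0.5, radius_range_um = c(0.3, 1.0),
                  residual_tol = 0.1),
    coloc = list(n_cells = 13, puncta_per_cell = 10,
                 coloc_probability = 0.94, jitter_um = 0.2),
    dissolution = list(concentration_nM = 200, decay_tau_s = 60,
                       t_total_s = 300, frame_interval_s = 15,
                       epsilon = 0.05),
    qpcr = list(fold_changes = c(CTGF = 0.16, CYR61 = 0.30),
                reference_gene = "ACTB", n_replicates = 3,
                ct_noise_sd = 0.1),
    de = list(n_genes = 2000, n_replicates = 3, dispersion = 0.05,
              n_de = 88, de_lfc = 2, de_min_mean = 500,
              p_threshold = 0.01, lfc_threshold = 0.58,
              fdr_threshold = 0.1)),
    class = "pipeline_config")
}

config_schema <- list(
  seed = "numeric",
  calibration = c("concentrations_nM"),
  phase = c("n_cells", "conc_range_nM", "csat_nM", "csat_rapamycin_nM",
            "n_bootstrap", "k"),
  fusion = c("n_events", "inv_cap_velocity_s_per_um", "frame_interval_s",
             "radius_range_um", "residual_tol"),
  coloc = c("n_cells", "puncta_per_cell", "coloc_probability", "jitter_um"),
  dissolution = c("concentration_nM", "decay_tau_s", "t_total_s",
                  "frame_interval_s", "epsilon"),
  qpcr = c("fold_changes", "reference_gene", "n_replicates", "ct_noise_sd"),
  de = c("n_genes", "n_replicates", "dispersion", "n_de", "de_lfc",
         "de_min_mean", "p_threshold", "lfc_threshold", "fdr_threshold"))

#' Validate a pipeline configuration
#'
#' @param config a list as from [default_config()] or [read_config()].
#' @return the config, invisibly, after checking every stage block and
#'   field; a missing or malformed entry raises an error naming the field.
#' @export
validate_config <- function(config) {
  for (blk in names(config_schema)) {
    if (blk == "seed") {
      if (!is.numeric(config$seed) || length(config$seed) != 1)
        stop("config field 'seed' must be a single number")
      next
    }
    if (is.null(config[[blk]]))
      stop("config block '", blk, "' is missing")
    missing <- setdiff(config_schema[[blk]], names(config[[blk]]))
    if (length(missing))
      stop("config block '", blk, "' is missing field(s): ",
           paste0(blk, "$", missing, collapse = ", "))
  }
  if (config$coloc$coloc_probability < 0 ||
      config$coloc$coloc_probability > 1)
    stop("config field 'coloc$coloc_probability' must lie in [0, 1]")
  if (any(unlist(config$qpcr$fold_changes) <= 0))
    stop("config field 'qpcr$fold_changes' must be positive")
  invisible(config)
}

#' @rdname default_config
#' @param config a pipeline configuration list.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  ## named atomic vectors must become YAML maps or their names are lost
  prep <- rapply(unclass(config), function(x)
    if (!is.null(names(x))) as.list(x) else x,
    classes = c("numeric", "integer", "character"), how = "replace")
  yaml::write_yaml(prep, path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ## yaml turns named numeric vectors into lists; restore the ones we use
  for (blk in names(cfg)) if (is.list(cfg[[blk]]))
    cfg[[blk]] <- lapply(cfg[[blk]], function(x)
      if (is.list(x) && all(vapply(x, is.numeric, logical(1))))
        unlist(x) else x)
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' Write / read a TIFF image or movie with physical metadata
#'
#' Images are written as (multi-page) 16-bit grayscale TIFF; pixel size,
#' frame interval and the intensity scale used for the 16-bit encoding go
#' to a JSON sidecar (`<path>.meta.json`) so that [read_image_tiff()]
#' restores the original counts and metadata.
#'
#' @param img 2D [image_stack()] or 2D+t movie (time as third dimension).
#' @param path output file (`.tif`).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  d <- dim(img)
  scale <- max(img, 1)
  frames <- if (length(d) == 2) list(img / scale)
  else lapply(seq_len(d[3]), function(j) img[, , j] / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  meta <- list(pixel_size_um = pixel_size(img),
               frame_interval_s = attr(img, "frame_interval_s"),
               time_axis = attr(img, "time_axis"),
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
  else list(pixel_size_um = 1, intensity_scale = 1)
  scale <- meta$intensity_scale %||% 1
  arr <- if (length(frames) == 1) round(frames[[1]] * scale)
  else {
    a <- array(0, c(dim(frames[[1]]), length(frames)))
    for (j in seq_along(frames)) a[, , j] <- round(frames[[j]] * scale)
    a
  }
  image_stack(arr, meta$pixel_size_um %||% 1,
              meta$frame_interval_s %||% NA_real_,
              if (length(frames) > 1) 3L else NA_integer_)
}

write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  path
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates every stage end-to-end: calibration, phase curves and
#' saturation-concentration estimation for untreated and
#' condensate-dissolving (rapamycin) conditions, fusion kinetics,
#' colocalization, dissolution kinetics, qPCR and the three-contrast
#' differential-expression comparison. Each stage draws from its own RNG
#' stream derived from the global seed, writes its tables (CSV/TSV) and
#' summaries (JSON) under `out_dir`, and the run closes with a manifest
#' recording package version, parameters and MD5 hashes of every output.
#' Re-running with the same config yields byte-identical tables.
#'
#' @param config a validated pipeline configuration ([default_config()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with every stage's in-memory results and
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile()) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed0 <- as.integer(config$seed)
  stage_seed <- function(i) (seed0 * 113L + i * 7919L) %% 2147483647L
  files <- character(0)
  res <- list()
  msg <- function(...) message("[sparkq] ", ...)

  ## 1. calibration ------------------------------------------------------
  msg("calibration: dilution series and standard curve")
  cal_gt <- imaging_ground_truth(seed = stage_seed(1))
  dil <- generate_dilution_table(cal_gt,
                                 config$calibration$concentrations_nM)
  curve <- fit_standard_curve(dil)
  files <- c(files, write_csv(dil, file.path(out_dir, "dilution_series.csv")))
  files <- c(files, write_json_out(
    list(slope = curve$slope, intercept = curve$intercept,
         r_squared = curve$r_squared, n_points = curve$n_points),
    file.path(out_dir, "calibration_curve.json")))
  res$calibration <- curve

  ## 2. phase curves and c_sat ------------------------------------------
  phase_one <- function(csat, seed, condition) {
    gt <- imaging_ground_truth(csat_nM = csat, seed = seed)
    conc <- exp(seq(log(config$phase$conc_range_nM[1]),
                    log(config$phase$conc_range_nM[2]),
                    length.out = config$phase$n_cells))
    sim <- generate_cell_images(gt, conc)
    meas <- do.call(rbind, lapply(seq_along(sim$images), function(i) {
      m <- measure_cells(sim$images[[i]], curve = curve,
                         k = config$phase$k)
      m$cell_id <- i
      m
    }))
    build_phase_curve(meas, condition = condition)
  }
  msg("phase: ", config$phase$n_cells, " cells per condition")
  pc_a <- phase_one(config$phase$csat_nM, stage_seed(2), "untreated")
  pc_b <- phase_one(config$phase$csat_rapamycin_nM, stage_seed(3),
                    "rapamycin")
  fit_a <- estimate_csat(pc_a, n_bootstrap = config$phase$n_bootstrap,
                         seed = stage_seed(4))
  fit_b <- estimate_csat(pc_b, n_bootstrap = config$phase$n_bootstrap,
                         seed = stage_seed(5))
  shift <- compare_csat(pc_a, pc_b, n_bootstrap = config$phase$n_bootstrap,
                        seed = stage_seed(6))
  files <- c(files,
             write_csv(rbind(pc_a, pc_b),
                       file.path(out_dir, "phase_curves.csv")),
             write_json_out(list(
               untreated = list(csat_nM = fit_a$csat_nM, ci = fit_a$ci_nM),
               rapamycin = list(csat_nM = fit_b$csat_nM, ci = fit_b$ci_nM),
               shift_nM = shift$shift_nM, shift_ci = shift$ci_nM),
               file.path(out_dir, "csat_estimates.json")))
  res$phase <- list(untreated = fit_a, rapamycin = fit_b, shift = shift)

  ## 3. fusion kinetics --------------------------------------------------
  msg("fusion: ", config$fusion$n_events, " events")
  fgt <- fusion_ground_truth(
    inv_cap_velocity_s_per_um = config$fusion$inv_cap_velocity_s_per_um,
    n_events = config$fusion$n_events,
    frame_interval_s = config$fusion$frame_interval_s,
    radius_range_um = config$fusion$radius_range_um,
    seed = stage_seed(7))
  fsim <- generate_fusion_movie(fgt)
  fits <- list()
  ev_rows <- list()
  for (i in seq_along(fsim$movies)) {
    ev <- track_fusion_events(fsim$movies[[i]])
    if (length(ev) != 1) next
    f <- tryCatch(fit_relaxation(ev[[1]]), error = function(e) NULL)
    if (is.null(f)) next
    fits[[length(fits) + 1]] <- f
    ev_rows[[length(ev_rows) + 1]] <- data.frame(
      event_id = i, tau_s = f$tau_s, ar0 = f$ar0, ell_um = f$ell_um,
      inv_cap_velocity = f$inv_cap_velocity,
      rms_residual = f$rms_residual)
  }
  fsum <- summarize_inverse_capillary_velocity(
    fits, residual_tol = config$fusion$residual_tol)
  files <- c(files,
             write_csv(do.call(rbind, ev_rows),
                       file.path(out_dir, "fusion_fits.csv")),
             write_json_out(list(mean_s_per_um = fsum$mean_s_per_um,
                                 sd_s_per_um = fsum$sd_s_per_um,
                                 n = fsum$n),
                            file.path(out_dir, "fusion_summary.json")))
  res$fusion <- fsum

  ## 4. colocalization ---------------------------------------------------
  msg("colocalization: ", config$coloc$n_cells, " two-channel cells")
  csim <- generate_coloc_channels(
    n_cells = config$coloc$n_cells,
    puncta_per_cell = config$coloc$puncta_per_cell,
    coloc_probability = config$coloc$coloc_probability,
    jitter_um = config$coloc$jitter_um, seed = stage_seed(8))
  panel <- coloc_panel(csim$cells)
  files <- c(files,
             write_csv(as.data.frame(panel),
                       file.path(out_dir, "colocalization.csv")))
  res$coloc <- panel

  ## 5. dissolution time course -----------------------------------------
  msg("dissolution time course")
  dgt <- imaging_ground_truth(seed = stage_seed(9))
  dsim <- generate_dissolution_series(
    dgt, concentration_nM = config$dissolution$concentration_nM,
    decay_tau_s = config$dissolution$decay_tau_s,
    t_total_s = config$dissolution$t_total_s,
    frame_interval_s = config$dissolution$frame_interval_s)
  tc <- measure_timecourse(dsim$movie)
  dsum <- dissolution_summary(tc, epsilon = config$dissolution$epsilon)
  files <- c(files,
             write_csv(as.data.frame(tc),
                       file.path(out_dir, "dissolution_trace.csv")),
             write_json_out(list(completion_s = dsum$completion_t,
                                 completed = dsum$completed,
                                 drift = dsum$drift),
                            file.path(out_dir, "dissolution_summary.json")))
  res$dissolution <- dsum

  ## 6. qPCR -------------------------------------------------------------
  msg("qPCR ddCt")
  ct <- generate_ct_table(unlist(config$qpcr$fold_changes),
                          reference_gene = config$qpcr$reference_gene,
                          n_replicates = config$qpcr$n_replicates,
                          ct_noise_sd = config$qpcr$ct_noise_sd,
                          seed = stage_seed(10))
  qp <- ddct(ct, reference_gene = config$qpcr$reference_gene)
  files <- c(files,
             write_csv(ct, file.path(out_dir, "ct_table.csv")),
             write_csv(as.data.frame(qp),
                       file.path(out_dir, "qpcr_results.csv")))
  res$qpcr <- qp

  ## 7. differential expression: three contrasts ------------------------
  msg("differential expression: three contrasts")
  decfg <- config$de
  mk <- function(n_de, lfc, seed) generate_counts(counts_ground_truth(
    n_genes = decfg$n_genes, n_replicates = decfg$n_replicates,
    dispersion = decfg$dispersion, n_de = n_de, de_lfc = lfc,
    de_min_mean = decfg$de_min_mean, seed = seed))
  ## condensed vs control: the full YAP-responsive program; diffuse vs
  ## control: nearly the same program; condensed vs diffuse: the small
  ## PS-regulated subset
  n_big <- max(decfg$n_de * 4, 40)
  sim1 <- mk(n_big, decfg$de_lfc, stage_seed(11))
  sim2 <- mk(n_big, decfg$de_lfc, stage_seed(12))
  sim3 <- mk(decfg$n_de, decfg$de_lfc, stage_seed(13))
  run_de <- function(sim) de_test(
    sim$counts, sim$condition, p_threshold = decfg$p_threshold,
    lfc_threshold = decfg$lfc_threshold,
    fdr_threshold = decfg$fdr_threshold)
  de1 <- run_de(sim1); de2 <- run_de(sim2); de3 <- run_de(sim3)
  cmp <- compare_contrasts(list(condensed_vs_control = de1,
                                diffuse_vs_control = de2,
                                condensed_vs_diffuse = de3))
  counts_out <- data.frame(gene = rownames(sim3$counts), sim3$counts,
                           row.names = NULL, check.names = FALSE)
  tsv <- file.path(out_dir, "counts_condensed_vs_diffuse.tsv")
  utils::write.table(counts_out, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  files <- c(files, tsv,
             write_csv(as.data.frame(de3),
                       file.path(out_dir, "de_condensed_vs_diffuse.csv")),
             write_json_out(list(
               counts = cmp$counts,
               further_enhanced_fraction = cmp$further_enhanced_fraction),
               file.path(out_dir, "deg_comparison.json")))
  res$de <- list(contrasts = list(de1, de2, de3), comparison = cmp)

  ## manifest -------------------------------------------------------------
  manifest <- list(
    package = "sparkq",
    version = tryCatch(as.character(utils::packageVersion("sparkq")),
                       error = function(e) "dev"),
    seed = seed0,
    parameters = unclass(config),
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f))))
  files <- c(files, write_json_out(manifest,
                                   file.path(out_dir, "manifest.json")))
  res$manifest <- manifest
  res$files <- files
  msg("done: ", length(files), " files in ", out_dir)
  invisible(res)
}
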