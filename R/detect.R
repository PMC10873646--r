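#' Segment cells/nuclei in a fluorescence image
#'
#' Foreground/background separation with a per-image low threshold (Otsu by
#' default, or a user threshold), followed by connected-component labeling
#' and a minimum-size filter. Works on 2D and 3D single frames.
#'
#' @param img 2D or 3D [image_stack()] (or bare array).
#' @param threshold optional numeric low threshold; `NULL` uses Otsu.
#' @param min_size_px minimum cell size in pixels/voxels.
#' @return list of class `cell_segmentation`: `labels` (integer array),
#'   `cells` (data.frame: `cell_id`, `area_px`, `mean_intensity`),
#'   `threshold`.
#' @export
segment_cells <- function(img, threshold = NULL, min_size_px = 100) {
  stopifnot(is.array(img) || is.matrix(img))
  if (diff(range(img)) == 0) stop("no cell found: image is constant")
  thr <- if (is.null(threshold)) cell_low_threshold(img) else threshold
  mask <- img > thr
  if (!any(mask)) stop("no cell found: nothing above threshold")
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size_px)
  if (length(keep) == 0) stop("no cell found: all components below min size")
  out <- array(0L, dim(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  cells <- data.frame(
    cell_id = seq_along(keep), area_px = sizes[keep],
    mean_intensity = vapply(seq_along(keep),
                            function(i) mean(img[out == i]), numeric(1)))
  structure(list(labels = out, cells = cells, threshold = thr,
                 pixel_size_um = pixel_size(img)),
            class = "cell_segmentation")
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat(sprintf("Cell segmentation: %d cell(s), low threshold %.4g\n",
              nrow(x$cells), x$threshold))
  print(x$cells)
  invisible(x)
}

## Low threshold separating cells from background. A plain Otsu split can
## land between the dilute phase and bright condensates when condensates
## dominate the histogram's variance; in that case re-running Otsu on the
## sub-threshold pixels recovers the background/cell split.
cell_low_threshold <- function(img) {
  t1 <- otsu_threshold(img)
  f1 <- mean(img > t1)
  t2 <- otsu_threshold(img[img <= t1])
  f2 <- mean(img > t2)
  if (f1 < 0.35 && f2 > 2 * f1 && f2 < 0.85) t2 else t1
}

## Median of pixels outside every cell; the camera/background offset.
background_level <- function(img, cell_mask) {
  outside <- img[!cell_mask]
  if (length(outside) == 0) 0 else stats::median(outside)
}

#' Detect condensates inside a cell mask
#'
#' Applies the per-cell high-threshold rule `dilute + k * sd`, where the
#' dilute-phase level and spread are estimated robustly (median and
#' MAD-based sd of in-mask pixels, insensitive to the bright condensate
#' tail). Connected components above threshold (8-connectivity in 2D,
#' 26 in 3D) of at least `min_size_px` pixels are kept, and their properties
#' are reported in physical units. Intensities are background-subtracted
#' using the extracellular median.
#'
#' @param img 2D or 3D [image_stack()].
#' @param cell_mask logical array of the cell/nucleus (e.g. one label of
#'   [segment_cells()]).
#' @param k threshold stringency: condensates are pixels brighter than
#'   dilute median + `k` * dilute sd.
#' @param min_size_px minimum object size (pixels/voxels).
#' @param threshold optional absolute high threshold overriding the rule.
#' @return object of class `condensate_set`: data.frame `objects` (label,
#'   centroid in um, area/volume, mean/total background-subtracted
#'   intensity, equivalent radius), the label array, thresholds and
#'   background level.
#' @export
detect_condensates <- function(img, cell_mask, k = 3, min_size_px = 4,
                               threshold = NULL) {
  stopifnot(is.array(img) || is.matrix(img), any(cell_mask))
  d <- dim(img)
  nd <- length(d)
  px <- pixel_size(img)
  bg <- background_level(img, cell_mask)
  inside <- img[cell_mask]
  dilute_med <- stats::median(inside)
  dilute_sd <- stats::mad(inside)
  thr <- if (is.null(threshold)) dilute_med + k * dilute_sd else threshold

  mask <- (img > thr) & cell_mask
  empty <- structure(list(
    objects = data.frame(label = integer(), centroid_y_um = numeric(),
                         centroid_x_um = numeric(), size_px = integer(),
                         area_volume_um = numeric(), mean_intensity = numeric(),
                         total_intensity = numeric(),
                         equiv_radius_um = numeric()),
    labels = array(0L, d), high_threshold = thr, background = bg,
    dilute_level = dilute_med - bg, ndim = nd, pixel_size_um = px),
    class = "condensate_set")
  if (!any(mask)) return(empty)

  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size_px)
  if (length(keep) == 0) return(empty)

  out_lab <- array(0L, d)
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    idx <- which(lab == keep[i])
    out_lab[idx] <- i
    coords <- arrayInd(idx, d)
    vals <- img[idx] - bg
    size <- length(idx)
    area <- size * px^nd
    r_eq <- if (nd == 2) sqrt(area / pi) else (3 * area / (4 * pi))^(1 / 3)
    rows[[i]] <- data.frame(
      label = i,
      centroid_y_um = mean(coords[, 1]) * px,
      centroid_x_um = mean(coords[, 2]) * px,
      size_px = size, area_volume_um = area,
      mean_intensity = mean(vals), total_intensity = sum(vals),
      equiv_radius_um = r_eq)
  }
  objects <- do.call(rbind, rows)
  structure(list(objects = objects, labels = out_lab, high_threshold = thr,
                 background = bg, dilute_level = dilute_med - bg, ndim = nd,
                 pixel_size_um = px),
            class = "condensate_set")
}

#' @export
print.condensate_set <- function(x, ...) {
  cat(sprintf(
    "Condensate set: %d object(s); high threshold %.4g, background %.4g\n",
    nrow(x$objects), x$high_threshold, x$background))
  if (nrow(x$objects)) print(x$objects, digits = 4)
  invisible(x)
}

#' SPARK signal of a cell
#'
#' Fraction of the cell's total (background-subtracted) fluorescence that
#' resides in condensate pixels: total condensate intensity divided by total
#' cell intensity. Returns 0 when no condensates were detected; the value is
#' invariant under multiplying the image by a positive constant.
#'
#' @param condensates a [detect_condensates()] result for this cell.
#' @param cell_mask logical array of the same cell.
#' @param img the image both were measured on.
#' @return SPARK signal in `[0, 1]`.
#' @export
spark_signal <- function(condensates, cell_mask, img) {
  stopifnot(inherits(condensates, "condensate_set"))
  total <- sum(img[cell_mask] - condensates$background)
  if (total <= 0) return(0)
  inside <- sum(condensates$objects$total_intensity)
  min(max(inside / total, 0), 1)
}

#' Condensate-to-dilute-phase density ratio
#'
#' Mean background-subtracted intensity of condensate pixels divided by that
#' of dilute-phase pixels (cell mask minus condensates, with a 1-pixel guard
#' ring around each condensate excluded so PSF bleed does not inflate the
#' dilute estimate).
#'
#' @inheritParams spark_signal
#' @param guard_px width of the exclusion ring around condensates (pixels).
#' @param erode_px erosion applied to the condensate mask before averaging,
#'   so the condensate mean is taken over plateau pixels rather than
#'   PSF-dimmed rims (skipped for objects the erosion would remove).
#' @return the density ratio (>= 0). A ratio of ~1 indicates no real
#'   density contrast and is flagged with a warning.
#' @export
density_ratio <- function(condensates, cell_mask, img, guard_px = 2,
                          erode_px = 1) {
  stopifnot(inherits(condensates, "condensate_set"))
  if (nrow(condensates$objects) == 0)
    stop("density ratio undefined: no condensates detected")
  offs <- neighbor_offsets(length(dim(img)))
  dilate <- function(m, times) {
    for (g in seq_len(times)) {
      acc <- m
      for (k in seq_len(nrow(offs)))
        acc <- acc | shift_array(m, offs[k, ], fill = FALSE)
      m <- acc
    }
    m
  }
  erode <- function(m, times) {
    for (g in seq_len(times)) {
      acc <- m
      for (k in seq_len(nrow(offs)))
        acc <- acc & shift_array(m, offs[k, ], fill = TRUE)
      m <- acc
    }
    m
  }
  cmask <- condensates$labels > 0
  core <- if (erode_px > 0) erode(cmask, erode_px) else cmask
  if (!any(core)) core <- cmask
  guard <- if (guard_px > 0) dilate(cmask, guard_px) else cmask
  dilute_mask <- cell_mask & !guard
  if (!any(dilute_mask)) stop("no dilute-phase pixels left in cell mask")
  bg <- condensates$background
  cond_mean <- mean(img[core]) - bg
  dil_mean <- mean(img[dilute_mask]) - bg
  if (dil_mean <= 0) stop("dilute-phase mean is non-positive after background subtraction")
  ratio <- cond_mean / dil_mean
  if (abs(ratio - 1) < 0.05)
    warning("density ratio ~1: no real density contrast (degenerate)")
  ratio
}

#' Per-cell condensate measurements for one image
#'
#' Convenience wrapper running segmentation, condensate detection, SPARK
#' signal, density ratio and (optionally) concentration estimation for every
#' cell in a field.
#'
#' @param img 2D or 3D [image_stack()].
#' @param curve optional [fit_standard_curve()] result; adds a
#'   `concentration_nM` column.
#' @param k,min_size_px passed to [detect_condensates()].
#' @param seg_threshold optional low threshold for [segment_cells()].
#' @return data.frame with one row per cell: `cell_id`, `mean_intensity`,
#'   `concentration_nM` (if curve given), `spark_signal`, `density_ratio`
#'   (NA when no condensates), `n_condensates`.
#' @export
measure_cells <- function(img, curve = NULL, k = 3, min_size_px = 4,
                          seg_threshold = NULL) {
  seg <- segment_cells(img, threshold = seg_threshold)
  rows <- lapply(seg$cells$cell_id, function(ci) {
    cmask <- seg$labels == ci
    det <- detect_condensates(img, cmask, k = k, min_size_px = min_size_px)
    n_c <- nrow(det$objects)
    data.frame(
      cell_id = ci,
      mean_intensity = mean(img[cmask]),
      spark_signal = spark_signal(det, cmask, img),
      density_ratio = if (n_c > 0) density_ratio(det, cmask, img)
      else NA_real_,
      n_condensates = n_c)
  })
  out <- do.call(rbind, rows)
  if (!is.null(curve))
    out$concentration_nM <- estimate_cell_concentration(out$mean_intensity,
                                                        curve)
  out
}
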