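#' Object-based colocalization of two condensate sets
#'
#' A reference object counts as colocalized when its centroid falls inside a
#' second-channel object (`rule = "centroid"`, default — robust to size
#' mismatch between channels) or when at least `min_overlap` of its mask
#' overlaps second-channel objects (`rule = "overlap"`). The fraction is
#' directional: coloc(ref in other) need not equal coloc(other in ref).
#'
#' @param ref [detect_condensates()] result for the reference channel.
#' @param other [detect_condensates()] result for the second channel, from
#'   the same registered field.
#' @param rule matching rule, `"centroid"` or `"overlap"`.
#' @param min_overlap minimum overlapping fraction of the reference mask for
#'   `rule = "overlap"`.
#' @return list of class `coloc_result`: `n_ref`, `n_coloc`, `fraction_pct`
#'   and the per-object logical `colocalized`.
#' @export
match_puncta <- function(ref, other, rule = c("centroid", "overlap"),
                         min_overlap = 0.5) {
  rule <- match.arg(rule)
  stopifnot(inherits(ref, "condensate_set"),
            inherits(other, "condensate_set"))
  n_ref <- nrow(ref$objects)
  if (n_ref == 0) stop("empty reference set: cell excluded")
  if (!identical(dim(ref$labels), dim(other$labels)))
    stop("channels are not from the same field (label shapes differ)")
  px <- ref$pixel_size_um
  d <- dim(ref$labels)
  hit <- logical(n_ref)
  if (rule == "centroid") {
    for (i in seq_len(n_ref)) {
      yy <- max(1, min(d[1], round(ref$objects$centroid_y_um[i] / px)))
      xx <- max(1, min(d[2], round(ref$objects$centroid_x_um[i] / px)))
      hit[i] <- other$labels[yy, xx] > 0
    }
  } else {
    omask <- other$labels > 0
    for (i in seq_len(n_ref)) {
      m <- ref$labels == ref$objects$label[i]
      hit[i] <- sum(omask[m]) / sum(m) >= min_overlap
    }
  }
  structure(list(n_ref = n_ref, n_coloc = sum(hit),
                 fraction_pct = 100 * mean(hit), colocalized = hit,
                 rule = rule),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization (%s rule): %d / %d reference puncta (%.1f%%)\n",
              x$rule, x$n_coloc, x$n_ref, x$fraction_pct))
  invisible(x)
}

#' Colocalization fractions across cells and partner channels
#'
#' Runs detection and [match_puncta()] for every cell and every partner
#' channel, then pools: per-cell fractions, their mean and sd across cells,
#' and the pooled object-level fraction. Cells with an empty reference set
#' are excluded (with a message naming them).
#'
#' @param cells list of cells; each cell is a named list of 2D images with a
#'   `ref` channel and one or more partner channels (as produced by
#'   [generate_coloc_channels()], whose partner channel is named `other`).
#' @param k,min_size_px passed to [detect_condensates()].
#' @param rule,min_overlap passed to [match_puncta()].
#' @return data.frame of class `coloc_panel`, one row per partner channel:
#'   `pair`, `n_cells`, `mean_pct`, `sd_pct`, `pooled_pct`, `n_ref_total`,
#'   `n_coloc_total`; per-cell fractions are kept in the
#'   `per_cell` attribute.
#' @export
coloc_panel <- function(cells, k = 3, min_size_px = 4,
                        rule = "centroid", min_overlap = 0.5) {
  stopifnot(length(cells) >= 1)
  partners <- setdiff(names(cells[[1]]), "ref")
  if (length(partners) == 0) stop("cells carry no partner channel")
  per_cell <- list()
  rows <- list()
  for (p in partners) {
    frac <- nref <- ncol_ <- numeric(0)
    skipped <- integer(0)
    for (ci in seq_along(cells)) {
      img_r <- cells[[ci]]$ref
      img_o <- cells[[ci]][[p]]
      seg <- segment_cells(img_r)
      cmask <- seg$labels == which.max(seg$cells$area_px)
      det_r <- detect_condensates(img_r, cmask, k = k,
                                  min_size_px = min_size_px)
      det_o <- detect_condensates(img_o, cmask, k = k,
                                  min_size_px = min_size_px)
      if (nrow(det_r$objects) == 0) { skipped <- c(skipped, ci); next }
      m <- match_puncta(det_r, det_o, rule = rule,
                        min_overlap = min_overlap)
      frac <- c(frac, m$fraction_pct)
      nref <- c(nref, m$n_ref)
      ncol_ <- c(ncol_, m$n_coloc)
    }
    if (length(skipped))
      message("pair ", p, ": excluded cell(s) with empty reference set: ",
              paste(skipped, collapse = ", "))
    if (length(frac) == 0) stop("no cell had reference puncta for pair ", p)
    rows[[p]] <- data.frame(
      pair = p, n_cells = length(frac), mean_pct = mean(frac),
      sd_pct = stats::sd(frac), pooled_pct = 100 * sum(ncol_) / sum(nref),
      n_ref_total = sum(nref), n_coloc_total = sum(ncol_))
    per_cell[[p]] <- frac
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_cell") <- per_cell
  class(out) <- c("coloc_panel", "data.frame")
  out
}
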