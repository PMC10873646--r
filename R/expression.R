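#' Relative qPCR quantification by the delta-delta-Ct method
#'
#' Per sample, `dCt = Ct(target) - Ct(reference)`; per target,
#' `ddCt = mean dCt(test) - mean dCt(control)` and relative expression
#' `2^(-ddCt)` (amplification efficiency fixed at 2, single reference
#' gene). A Welch t-test compares replicate dCt values between conditions.
#'
#' @param ct_table long-format data.frame with columns `sample`,
#'   `condition`, `gene`, `ct` (as from [generate_ct_table()]).
#' @param targets target gene names; defaults to every gene except the
#'   reference.
#' @param reference_gene housekeeping gene present in every sample.
#' @param control_condition condition label used as baseline.
#' @return data.frame of class `qpcr_result`, one row per target:
#'   `gene`, `ddct`, `rel_expression`, `percent_change` (positive = up),
#'   `p_value`; per-replicate dCt values are kept in the `dct` attribute.
#' @export
ddct <- function(ct_table, targets = NULL, reference_gene = "ACTB",
                 control_condition = NULL) {
  stopifnot(all(c("sample", "condition", "gene", "ct") %in%
                  names(ct_table)))
  samples <- unique(ct_table$sample)
  ref <- ct_table[ct_table$gene == reference_gene, ]
  if (!all(samples %in% ref$sample))
    stop("reference gene '", reference_gene,
         "' is missing from some samples")
  conds <- unique(ct_table$condition)
  stopifnot(length(conds) == 2)
  if (is.null(control_condition)) control_condition <- conds[1]
  test_condition <- setdiff(conds, control_condition)
  if (is.null(targets))
    targets <- setdiff(unique(ct_table$gene), reference_gene)
  ref_ct <- stats::setNames(ref$ct, ref$sample)

  dct_store <- list()
  rows <- lapply(targets, function(g) {
    tg <- ct_table[ct_table$gene == g, ]
    if (nrow(tg) == 0) stop("target gene '", g, "' not in table")
    dct <- tg$ct - ref_ct[tg$sample]
    ctrl <- dct[tg$condition == control_condition]
    test <- dct[tg$condition == test_condition]
    if (length(ctrl) < 2 || length(test) < 2)
      stop("need >= 2 replicates per condition for gene '", g, "'")
    dd <- mean(test) - mean(ctrl)
    rel <- 2^(-dd)
    dct_store[[g]] <<- data.frame(condition = tg$condition, dct = dct)
    pv <- tryCatch(stats::t.test(test, ctrl)$p.value,
                   error = function(e) NA_real_)  # constant replicates
    data.frame(gene = g, ddct = dd, rel_expression = rel,
               percent_change = 100 * (rel - 1), p_value = pv)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dct") <- dct_store
  attr(out, "reference_gene") <- reference_gene
  attr(out, "control_condition") <- control_condition
  class(out) <- c("qpcr_result", "data.frame")
  out
}

#' @export
print.qpcr_result <- function(x, ...) {
  cat("ddCt relative quantification (reference: ",
      attr(x, "reference_gene"), ", control: ",
      attr(x, "control_condition"), ")\n", sep = "")
  df <- as.data.frame(x)
  df$direction <- ifelse(df$rel_expression <= 1,
                         sprintf("%.0f%% decrease",
                                 100 * (1 - df$rel_expression)),
                         sprintf("%.0f%% increase",
                                 100 * (df$rel_expression - 1)))
  print(df, digits = 4)
  invisible(x)
}

## DESeq-style median-of-ratios size factors; falls back to library-size
## ratios when too few genes are expressed in every sample.
size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (sum(use) >= 50) {
    apply(counts[use, , drop = FALSE], 2, function(cj)
      exp(stats::median(log(cj) - log_geo[use])))
  } else {
    ls <- colSums(counts)
    ls / exp(mean(log(ls)))
  }
}

## Dispersion trend a0/mu + a1 fitted to binned mean method-of-moments
## dispersions (edgeR-like decreasing trend with expression). Bin means of
## the *unclamped* moment estimates are used: clamping or medians would bias
## the trend low, since the gene-wise estimates are strongly right-skewed
## at few replicates. Bins are weighted by gene count.
dispersion_trend <- function(mu, disp_raw) {
  ok <- mu > 0 & is.finite(disp_raw)
  lb <- cut(log(mu[ok]), breaks = 20)
  bin_mu <- tapply(mu[ok], lb, stats::median)
  bin_d <- tapply(disp_raw[ok], lb, mean)
  bin_n <- tapply(disp_raw[ok], lb, length)
  keep <- !is.na(bin_mu) & !is.na(bin_d) & bin_n >= 5
  fallback <- max(mean(disp_raw[ok & mu > stats::median(mu[ok])]), 1e-6)
  if (sum(keep) < 3) {
    a <- c(0, fallback)
  } else {
    fit <- stats::lm(d ~ im, data = data.frame(d = bin_d[keep],
                                               im = 1 / bin_mu[keep]),
                     weights = bin_n[keep])
    a <- stats::coef(fit)[c(2, 1)]
    if (!all(is.finite(a)) || a[2] <= 0) a <- c(max(a[1], 0), fallback)
    a[1] <- max(a[1], 0)
  }
  function(m) pmax(a[1] / pmax(m, 1e-8) + a[2], 1e-6)
}

## Exact conditional NB test for one gene: two-sided p-value for the split
## of the total pseudo-count S into group sums (s1, S - s1), conditioning on
## S, at pooled mean mu and dispersion phi. Outcomes no more probable than
## the observed one are summed (the standard two-sided convention for
## discrete tests). The support is windowed to the bulk of the conditional
## mass for speed.
nb_exact_p <- function(s1, s2, n1, n2, phi) {
  S <- s1 + s2
  if (S == 0) return(1)
  mu <- S / (n1 + n2)
  size1 <- n1 / max(phi, 1e-8)
  size2 <- n2 / max(phi, 1e-8)
  lo <- 0; hi <- S
  if (S > 10000) {                      # window: mu1 +/- ~10 sd
    sd1 <- sqrt(n1 * mu * (1 + phi * mu))
    lo <- max(0, floor(n1 * mu - 12 * sd1))
    hi <- min(S, ceiling(n1 * mu + 12 * sd1))
    if (s1 < lo || s1 > hi) return(0)
  }
  s <- lo:hi
  logp <- stats::dnbinom(s, mu = n1 * mu, size = size1, log = TRUE) +
    stats::dnbinom(S - s, mu = n2 * mu, size = size2, log = TRUE)
  m <- max(logp)
  pr <- exp(logp - m)
  obs <- pr[s1 - lo + 1]
  sum(pr[pr <= obs * (1 + 1e-10)]) / sum(pr)
}

#' Negative-binomial differential-expression test
#'
#' A two-condition test on raw counts re-implementing the classic RNA-seq
#' recipe: median-of-ratios library-size normalization, per-gene
#' method-of-moments NB dispersion shrunk toward a fitted `a/mu + b`
#' mean-dispersion trend, and an exact conditional negative-binomial test
#' on the per-condition sums of normalized pseudo-counts (two-sided by
#' summing outcomes no more probable than the observed split). A Wald
#' statistic `log2FC / SE` with the delta-method standard error
#' `SE(log2FC)^2 = [(1/mu1 + phi)/n1 + (1/mu2 + phi)/n2] / ln(2)^2` is
#' reported for ranking. Genes are called `up`/`down` when they pass all
#' three thresholds (raw p, |log2 fold change|, BH FDR), `ns` otherwise.
#' Genes with all-zero counts are dropped before testing.
#'
#' @param counts integer matrix, genes x samples (rownames = gene ids).
#' @param condition factor/character of length `ncol(counts)` with exactly
#'   two levels; the first level is the reference, and log2FC is second
#'   versus first.
#' @param p_threshold,lfc_threshold,fdr_threshold call thresholds (defaults:
#'   p < 0.01, |log2FC| >= 0.58 i.e. 1.5-fold, FDR < 0.1).
#' @param prior_count pseudo-count added to normalized means for the log2FC
#'   (avoids infinities at zero).
#' @param prior_df weight (in residual degrees of freedom) given to the
#'   dispersion trend when shrinking gene-wise estimates.
#' @return data.frame of class `de_result`, one row per tested gene:
#'   `gene`, `base_mean`, `mean_ref`, `mean_alt`, `log2fc`, `stat`,
#'   `p_value`, `fdr`, `call` (factor up/down/ns). Thresholds and the
#'   condition levels are kept as attributes.
#' @export
de_test <- function(counts, condition, p_threshold = 0.01,
                    lfc_threshold = 0.58, fdr_threshold = 0.1,
                    prior_count = 0.5, prior_df = 20) {
  counts <- as.matrix(counts)
  condition <- factor(condition)
  stopifnot(ncol(counts) == length(condition),
            nlevels(condition) == 2)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  n1 <- sum(condition == levels(condition)[1])
  n2 <- sum(condition == levels(condition)[2])
  if (n1 < 2 || n2 < 2) stop("need >= 2 replicates per condition")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene_%05d", seq_len(nrow(counts)))

  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, `/`)
  i1 <- condition == levels(condition)[1]
  i2 <- condition == levels(condition)[2]
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  base_mean <- rowMeans(norm)

  ## gene-wise method-of-moments dispersion from pooled within-condition
  ## variance, then shrinkage toward the trend
  v1 <- apply(norm[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, i2, drop = FALSE], 1, stats::var)
  vw <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mw <- (n1 * m1 + n2 * m2) / (n1 + n2)
  disp_raw <- (vw - mw) / mw^2
  disp_g <- pmax(disp_raw, 0)
  trend <- dispersion_trend(mw, disp_raw)
  df <- n1 + n2 - 2
  w <- df / (df + prior_df)
  phi <- w * disp_g + (1 - w) * trend(mw)

  log2fc <- log2((m2 + prior_count) / (m1 + prior_count))
  se2 <- ((1 / (m1 + prior_count) + phi) / n1 +
            (1 / (m2 + prior_count) + phi) / n2) / log(2)^2
  stat <- log2fc / sqrt(se2)
  s1 <- round(rowSums(norm[, i1, drop = FALSE]))
  s2 <- round(rowSums(norm[, i2, drop = FALSE]))
  p <- vapply(seq_along(s1), function(g)
    nb_exact_p(s1[g], s2[g], n1, n2, phi[g]), numeric(1))
  fdr <- stats::p.adjust(p, method = "BH")
  call <- rep("ns", length(p))
  call[p < p_threshold & log2fc >= lfc_threshold &
         fdr < fdr_threshold] <- "up"
  call[p < p_threshold & log2fc <= -lfc_threshold &
         fdr < fdr_threshold] <- "down"

  out <- data.frame(gene = rownames(counts), base_mean = base_mean,
                    mean_ref = m1, mean_alt = m2, log2fc = log2fc,
                    stat = stat, p_value = p, fdr = fdr,
                    call = factor(call, levels = c("up", "down", "ns")),
                    row.names = NULL)
  attr(out, "thresholds") <- c(p = p_threshold, lfc = lfc_threshold,
                               fdr = fdr_threshold)
  attr(out, "levels") <- levels(condition)
  attr(out, "size_factors") <- sf
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  th <- attr(x, "thresholds")
  lv <- attr(x, "levels")
  cat(sprintf(
    "NB Wald differential expression: %s vs %s (%d genes tested, %d all-zero dropped)\n",
    lv[2], lv[1], nrow(x), attr(x, "n_dropped")))
  cat(sprintf("Calls at p < %g, |log2FC| >= %g, FDR < %g: %d up, %d down\n",
              th["p"], th["lfc"], th["fdr"],
              sum(x$call == "up"), sum(x$call == "down")))
  invisible(x)
}

#' @export
summary.de_result <- function(object, ...) {
  print(object)
  up <- object[object$call == "up", ]
  if (nrow(up)) {
    cat("Top up-regulated genes:\n")
    print(utils::head(up[order(up$p_value), c("gene", "log2fc", "p_value",
                                              "fdr")], 5), digits = 3)
  }
  invisible(object)
}

#' Volcano plot of a differential-expression result
#'
#' @param x a `de_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.de_result <- function(x, ...) {
  col <- c(up = "firebrick", down = "steelblue", ns = "grey60")[
    as.character(x$call)]
  graphics::plot(x$log2fc, -log10(pmax(x$p_value, 1e-300)), col = col,
                 pch = 16, cex = 0.5, xlab = "log2 fold change",
                 ylab = "-log10 p", ...)
  th <- attr(x, "thresholds")
  graphics::abline(v = c(-th["lfc"], th["lfc"]), lty = 2, col = "grey40")
  graphics::abline(h = -log10(th["p"]), lty = 2, col = "grey40")
  invisible(x)
}

#' Three-contrast comparison isolating phase-separation-regulated genes
#'
#' Takes per-contrast [de_test()] results on a common gene universe —
#' typically condensed-vs-control, diffuse-vs-control and
#' condensed-vs-diffuse — and reports the up/down gene sets, their pairwise
#' intersections, and the fraction of genes up-regulated in the first
#' contrast that are *further* up-regulated in the third (the share of
#' target-gene activation attributable to phase separation itself).
#'
#' @param de_list named list of 2 or more `de_result`s; the
#'   further-enhanced fraction uses the first and last elements.
#' @return list of class `deg_comparison`: `sets` (up/down gene vectors per
#'   contrast), `intersections` (pairwise, for up and down),
#'   `further_enhanced_fraction`, `counts`.
#' @export
compare_contrasts <- function(de_list) {
  stopifnot(is.list(de_list), length(de_list) >= 2,
            all(vapply(de_list, inherits, logical(1), "de_result")))
  if (is.null(names(de_list)))
    names(de_list) <- paste0("contrast_", seq_along(de_list))
  universes <- lapply(de_list, `[[`, "gene")
  if (length(unique(lapply(universes, sort))) != 1)
    stop("contrasts do not share the same gene universe")
  sets <- lapply(de_list, function(d)
    list(up = d$gene[d$call == "up"], down = d$gene[d$call == "down"]))
  nm <- names(de_list)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  inter <- lapply(pairs, function(p) list(
    pair = paste(p, collapse = " & "),
    up = intersect(sets[[p[1]]]$up, sets[[p[2]]]$up),
    down = intersect(sets[[p[1]]]$down, sets[[p[2]]]$down)))
  up1 <- sets[[1]]$up
  up_last <- sets[[length(sets)]]$up
  frac <- if (length(up1)) length(intersect(up1, up_last)) / length(up1)
  else NA_real_
  counts <- do.call(rbind, lapply(nm, function(n) data.frame(
    contrast = n, n_up = length(sets[[n]]$up),
    n_down = length(sets[[n]]$down))))
  structure(list(sets = sets, intersections = inter,
                 further_enhanced_fraction = frac, counts = counts),
            class = "deg_comparison")
}

#' @export
print.deg_comparison <- function(x, ...) {
  cat("DEG comparison across contrasts\n")
  print(x$counts, row.names = FALSE)
  if (!is.na(x$further_enhanced_fraction))
    cat(sprintf(
      "Fraction of first-contrast up-genes further up in last contrast: %.1f%%\n",
      100 * x$further_enhanced_fraction))
  invisible(x)
}

#' Hypergeometric over-representation test of gene sets
#'
#' One-sided hypergeometric test of whether each gene set is over-
#' represented in a differential-expression hit list, with BH adjustment
#' across sets. Stands in for annotation-database enrichment when gene sets
#' are supplied by the user.
#'
#' @param deg character vector of hit genes (subset of `universe`).
#' @param gene_sets named list of character vectors (subsets of
#'   `universe`).
#' @param universe character vector of all tested genes.
#' @return data.frame: `set`, `n_set`, `n_hits`, `overlap`, `p_value`,
#'   `fdr`.
#' @export
enrichment_test <- function(deg, gene_sets, universe) {
  stopifnot(is.list(gene_sets), length(gene_sets) >= 1)
  if (is.null(names(gene_sets)))
    names(gene_sets) <- paste0("set_", seq_along(gene_sets))
  universe <- unique(universe)
  if (!all(deg %in% universe)) stop("deg genes must lie in the universe")
  bad <- !vapply(gene_sets, function(s) all(s %in% universe), logical(1))
  if (any(bad)) stop("gene set(s) outside the universe: ",
                     paste(names(gene_sets)[bad], collapse = ", "))
  deg <- unique(deg)
  N <- length(universe)
  n <- length(deg)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- unique(gene_sets[[nm]])
    K <- length(s)
    k <- length(intersect(deg, s))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, n_set = K, n_hits = n, overlap = k, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
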