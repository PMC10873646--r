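#' Simulate a qPCR Ct table under known fold changes
#'
#' Target-gene expression in the treated condition is `fold_change` times the
#' control, so the treated Ct shifts by `-log2(fold_change)` (amplification
#' efficiency 2). Replicate Ct values carry iid Gaussian noise.
#'
#' @param fold_changes named numeric vector of true fold changes, one per
#'   target gene (names become gene labels); all > 0.
#' @param reference_gene housekeeping gene name (fold change 1 by
#'   construction).
#' @param n_replicates biological replicates per condition (>= 2).
#' @param ct_noise_sd Gaussian Ct noise sd (cycles).
#' @param conditions two condition labels, control first.
#' @param base_ct_target,base_ct_ref control-condition mean Ct of targets and
#'   reference.
#' @param seed integer seed or `NULL`.
#' @return long-format data.frame with columns `sample`, `condition`, `gene`,
#'   `ct`.
#' @export
generate_ct_table <- function(fold_changes, reference_gene = "ACTB",
                              n_replicates = 3, ct_noise_sd = 0.1,
                              conditions = c("control", "treated"),
                              base_ct_target = 24, base_ct_ref = 16,
                              seed = NULL) {
  stopifnot(all(fold_changes > 0), n_replicates >= 2, ct_noise_sd >= 0,
            length(conditions) == 2)
  if (is.null(names(fold_changes)))
    names(fold_changes) <- paste0("target_", seq_along(fold_changes))
  with_seed(seed, {
    genes <- c(names(fold_changes), reference_gene)
    rows <- expand.grid(replicate = seq_len(n_replicates),
                        condition = conditions, gene = genes,
                        stringsAsFactors = FALSE)
    base <- ifelse(rows$gene == reference_gene, base_ct_ref, base_ct_target)
    shift <- ifelse(rows$condition == conditions[2] &
                      rows$gene != reference_gene,
                    -log2(fold_changes[rows$gene]), 0)
    rows$ct <- base + shift + stats::rnorm(nrow(rows), 0, ct_noise_sd)
    data.frame(sample = paste0(rows$condition, "_", rows$replicate),
               condition = rows$condition, gene = rows$gene, ct = rows$ct)
  })
}

#' Ground-truth parameters for a synthetic RNA-seq counts matrix
#'
#' @param n_genes number of genes.
#' @param n_replicates replicates per condition (>= 2).
#' @param mu_meanlog,mu_sdlog lognormal parameters of baseline gene means.
#' @param dispersion common negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`).
#' @param n_de number of truly differential genes (ignored when `de_lfc` is
#'   a named vector).
#' @param de_lfc either a single |log2 fold change| applied to `n_de` genes
#'   (signs split evenly, up first) or a named vector of signed log2 fold
#'   changes keyed by gene id.
#' @param de_min_mean optional floor on the baseline mean of differential
#'   genes (guarantees sequencing depth over the truth set).
#' @param lib_size_range per-sample relative library-size factors are drawn
#'   uniformly from this range.
#' @param conditions two condition labels, reference first.
#' @param seed integer seed or `NULL`.
#' @return an object of class `counts_ground_truth`.
#' @export
counts_ground_truth <- function(n_genes = 12000, n_replicates = 3,
                                mu_meanlog = log(100), mu_sdlog = 1.3,
                                dispersion = 0.05, n_de = 0, de_lfc = 2,
                                de_min_mean = NULL,
                                lib_size_range = c(0.7, 1.3),
                                conditions = c("control", "treated"),
                                seed = NULL) {
  stopifnot(n_genes >= 1, n_replicates >= 2, dispersion >= 0,
            length(conditions) == 2)
  if (!is.null(names(de_lfc))) n_de <- length(de_lfc)
  stopifnot(n_de <= n_genes)
  out <- list(n_genes = n_genes, n_replicates = n_replicates,
              mu_meanlog = mu_meanlog, mu_sdlog = mu_sdlog,
              dispersion = dispersion, n_de = n_de, de_lfc = de_lfc,
              de_min_mean = de_min_mean, lib_size_range = lib_size_range,
              conditions = conditions, seed = seed)
  class(out) <- "counts_ground_truth"
  out
}

#' Simulate a negative-binomial counts matrix with a spiked truth set
#'
#' Non-differential genes share their mean across conditions; differential
#' genes have the second-condition mean shifted by their signed log2 fold
#' change. Counts are negative-binomial with the ground-truth dispersion and
#' per-sample library-size factors.
#'
#' @param gt a [counts_ground_truth()] object.
#' @return list with `counts` (integer matrix, genes x samples), `condition`
#'   (factor) and `truth` (per gene: baseline mean, signed log2FC, DE flag).
#' @export
generate_counts <- function(gt) {
  stopifnot(inherits(gt, "counts_ground_truth"))
  with_seed(gt$seed, {
    genes <- sprintf("gene_%05d", seq_len(gt$n_genes))
    mu <- stats::rlnorm(gt$n_genes, gt$mu_meanlog, gt$mu_sdlog)
    names(mu) <- genes

    lfc <- stats::setNames(numeric(gt$n_genes), genes)
    if (gt$n_de > 0) {
      if (!is.null(names(gt$de_lfc))) {
        bad <- setdiff(names(gt$de_lfc), genes)
        if (length(bad)) stop("unknown DE gene ids: ",
                              paste(bad, collapse = ", "))
        lfc[names(gt$de_lfc)] <- gt$de_lfc
      } else {
        ids <- sample(genes, gt$n_de)
        n_up <- ceiling(gt$n_de / 2)
        lfc[ids] <- rep(c(abs(gt$de_lfc), -abs(gt$de_lfc)),
                        c(n_up, gt$n_de - n_up))
      }
      if (!is.null(gt$de_min_mean))
        mu[lfc != 0] <- pmax(mu[lfc != 0], gt$de_min_mean)
    }

    n <- gt$n_replicates
    sf <- stats::runif(2 * n, gt$lib_size_range[1], gt$lib_size_range[2])
    condition <- factor(rep(gt$conditions, each = n),
                        levels = gt$conditions)
    mu_mat <- cbind(matrix(mu, gt$n_genes, n),
                    matrix(mu * 2^lfc, gt$n_genes, n))
    mu_mat <- sweep(mu_mat, 2, sf, `*`)
    draws <- if (gt$dispersion > 0)
      stats::rnbinom(length(mu_mat), mu = mu_mat, size = 1 / gt$dispersion)
    else stats::rpois(length(mu_mat), mu_mat)
    counts <- matrix(draws, nrow = gt$n_genes,
                     dimnames = list(genes, paste0(condition, "_",
                                                   rep(seq_len(n), 2))))
    list(counts = counts, condition = condition,
         truth = data.frame(gene = genes, base_mean = mu, lfc = lfc,
                            is_de = lfc != 0, row.names = NULL),
         size_factors_true = sf)
  })
}
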