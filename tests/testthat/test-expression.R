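test_that("ddCt arithmetic follows the 2^(-ddCt) model", {
  ct <- generate_ct_table(c(A = 1, B = 0.5, C = 2), ct_noise_sd = 0,
                          seed = 91)
  res <- ddct(ct)
  expect_equal(res$rel_expression[res$gene == "A"], 1)
  expect_equal(res$percent_change[res$gene == "A"], 0)
  expect_equal(res$rel_expression[res$gene == "B"], 0.5)   # 50% decrease
  expect_equal(res$percent_change[res$gene == "C"], 100)
  expect_error(ddct(ct, reference_gene = "GAPDH"), "missing")
})

test_that("qPCR fold-change recovery matches the generator at low noise", {
  ct <- generate_ct_table(c(CTGF = 0.16, CYR61 = 0.30),
                          ct_noise_sd = 0.1, seed = 92)
  res <- ddct(ct)
  dec <- 100 * (1 - res$rel_expression)
  expect_equal(dec[res$gene == "CTGF"], 84, tolerance = 0.04)
  expect_equal(dec[res$gene == "CYR61"], 70, tolerance = 0.06)
  expect_true(all(res$p_value < 0.01))
})

test_that("identical replicated columns produce zero calls and zero log2FC", {
  set.seed(93)
  base <- matrix(rnbinom(500 * 3, mu = 100, size = 20), 500, 3)
  counts <- cbind(base, base)
  rownames(counts) <- sprintf("g%03d", 1:500)
  de <- de_test(counts, rep(c("a", "b"), each = 3))
  expect_true(all(abs(de$log2fc) < 1e-12))
  expect_true(all(de$call == "ns"))
})

test_that("label swap negates log2FC and exchanges call counts", {
  sim <- generate_counts(counts_ground_truth(n_genes = 3000, n_de = 30,
                                             de_lfc = 2,
                                             de_min_mean = 300,
                                             seed = 94))
  d1 <- de_test(sim$counts, sim$condition)
  d2 <- de_test(sim$counts, factor(sim$condition,
                                   levels = rev(levels(sim$condition))))
  expect_equal(d1$log2fc, -d2$log2fc, tolerance = 1e-12)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-9)
  expect_equal(sum(d1$call == "up"), sum(d2$call == "down"))
  expect_equal(sum(d1$call == "down"), sum(d2$call == "up"))
})

test_that("truth genes at large effect and depth are recalled at >= 95%", {
  sim <- generate_counts(counts_ground_truth(n_genes = 3000, n_de = 40,
                                             de_lfc = 2,
                                             de_min_mean = 500,
                                             seed = 95))
  de <- de_test(sim$counts, sim$condition)
  truth_de <- sim$truth$gene[sim$truth$is_de]
  called <- de$gene[de$call != "ns"]
  expect_gte(mean(truth_de %in% called), 0.95)
})

test_that("exact NB p-values agree with edgeR's exact test at fixed dispersion", {
  library(edgeR)
  set.seed(96)
  mu <- c(20, 50, 120, 400, 1000)
  counts <- t(vapply(mu, function(m)
    rnbinom(6, mu = m * 2^(rep(c(0, 0.8), each = 3)), size = 1 / 0.08),
    numeric(6)))
  rownames(counts) <- paste0("g", seq_along(mu))
  group <- rep(c("a", "b"), each = 3)
  dge <- DGEList(counts = counts, group = group,
                 norm.factors = rep(1, 6),
                 lib.size = rep(mean(colSums(counts)), 6))
  p_ref <- exactTest(dge, dispersion = 0.08)$table$PValue
  p_ours <- vapply(seq_along(mu), function(g)
    sparkq:::nb_exact_p(sum(counts[g, 1:3]), sum(counts[g, 4:6]), 3, 3,
                        0.08), numeric(1))
  expect_equal(p_ours, p_ref, tolerance = 0.1)
})

test_that("p-values are uniform under the global null", {
  sim <- generate_counts(counts_ground_truth(n_genes = 4000,
                                             lib_size_range = c(1, 1),
                                             seed = 97))
  de <- de_test(sim$counts, sim$condition)
  expect_equal(mean(de$p_value < 0.01), 0.01, tolerance = 0.6)
  expect_equal(mean(de$p_value < 0.1), 0.1, tolerance = 0.3)
  expect_equal(sum(de$call != "ns"), 0)
})

test_that("contrast comparison reports sets, intersections and fractions", {
  mk_de <- function(up, down, genes) {
    d <- data.frame(gene = genes,
                    call = factor(ifelse(genes %in% up, "up",
                                         ifelse(genes %in% down, "down",
                                                "ns")),
                                  levels = c("up", "down", "ns")))
    class(d) <- c("de_result", "data.frame")
    d
  }
  genes <- paste0("g", 1:100)
  d1 <- mk_de(paste0("g", 1:20), paste0("g", 21:30), genes)
  d3 <- mk_de(paste0("g", 1:2), paste0("g", 50:52), genes)
  cmp <- compare_contrasts(list(a = d1, b = d1, c = d3))
  expect_equal(cmp$counts$n_up, c(20, 20, 2))
  expect_equal(cmp$further_enhanced_fraction, 0.1)   # 2 of 20 < 5% rule
  ## identical contrasts: intersection equals each set
  cmp2 <- compare_contrasts(list(x = d1, y = d1))
  expect_setequal(cmp2$intersections[[1]]$up, paste0("g", 1:20))
  ## disjoint sets: empty intersections
  d4 <- mk_de(paste0("g", 60:70), character(0), genes)
  cmp3 <- compare_contrasts(list(x = d1, y = d4))
  expect_length(cmp3$intersections[[1]]$up, 0)
  expect_error(compare_contrasts(list(d1, mk_de("x1", "x2",
                                                paste0("x", 1:5)))),
               "universe")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  universe <- letters[1:10]
  gs <- list(s1 = letters[1:4])
  deg <- c("a", "b", "e")
  res <- enrichment_test(deg, gs, universe)
  expect_equal(res$p_value, exhaustive_hyper_p(10, 4, 3, 2),
               tolerance = 1e-12)
  ## boundary: hit list = set = universe
  res2 <- enrichment_test(universe, list(all = universe), universe)
  expect_equal(res2$p_value, 1)
  ## empty hit list
  res3 <- enrichment_test(character(0), gs, universe)
  expect_equal(res3$p_value, 1)
  expect_error(enrichment_test(c("zz"), gs, universe), "universe")
})
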