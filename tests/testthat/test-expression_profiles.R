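toy_models <- function(ids, len) {
  data.frame(gene_id = ids, chrom = "chr1",
             start = seq_along(ids) * 1000L,
             end = seq_along(ids) * 1000L + len - 1L,
             strand = "+", exonic_length_bp = len,
             stringsAsFactors = FALSE)
}

test_that("compute_fpkm applies the definition and its invariances", {
  cm <- count_matrix(matrix(c(10L, 0L), 2, 1,
                            dimnames = list(c("g1", "g2"), "s1")),
                     totals = c(s1 = 1e6))
  models <- toy_models(c("g1", "g2"), c(2000L, 500L))
  f <- compute_fpkm(cm, models)
  expect_equal(f["g1", "s1"], 5)   # 10 / (1 x 2)
  expect_equal(f["g2", "s1"], 0)   # zero count, zero FPKM

  # scaling one sample's counts and total by c leaves FPKM unchanged
  m <- matrix(rpois(20, 50), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  tot <- setNames(rep(2e6, 4), colnames(m))
  f1 <- compute_fpkm(count_matrix(m, tot), toy_models(rownames(m), 800L))
  m2 <- m; m2[, 2] <- m[, 2] * 7L; tot2 <- tot; tot2[2] <- tot[2] * 7
  f2 <- compute_fpkm(count_matrix(m2, tot2), toy_models(rownames(m), 800L))
  expect_equal(f1[, 2], f2[, 2])

  # missing model is an error naming the gene
  expect_error(compute_fpkm(cm, models[1, ]), "g2")
})

test_that("replicate_qc flags planted outliers and respects thresholds", {
  set.seed(30)
  meta <- sim_meta <- sample_meta(
    paste0("r", 1:6), rep("AMT", 6), rep(c("S1", "S2"), each = 3), rep(1:3, 2))
  base <- matrix(2^rnorm(300 * 6, 6, 2), 300, 6,
                 dimnames = list(paste0("g", 1:300), meta$sample_id))
  shared <- 2^rnorm(300, 6, 2)
  for (j in 1:6) base[, j] <- shared * 2^rnorm(300, 0, 0.2)
  expect_length(replicate_qc(base, meta)$outliers, 0)

  # degrade one replicate (extra noise) so only it falls below the bar
  noisy <- base
  noisy[, "r2"] <- shared * 2^rnorm(300, 0, 2)
  expect_equal(replicate_qc(noisy, meta)$outliers, "r2")

  # threshold 1.0 flags every noisy replicate
  expect_setequal(replicate_qc(noisy, meta, qc_pcc_min = 1)$outliers,
                  meta$sample_id)

  # three identical replicates are never flagged
  ident <- base; ident[, 1:3] <- base[, 1]
  expect_false(any(c("r1", "r2", "r3") %in% replicate_qc(ident, meta)$outliers))
})

test_that("pca_samples separates planted clusters deterministically", {
  set.seed(31)
  n_g <- 400
  base <- matrix(2^rnorm(n_g * 8, 6, 1), n_g, 8,
                 dimnames = list(paste0("g", 1:n_g), paste0("s", 1:8)))
  base[1:200, 5:8] <- base[1:200, 5:8] * 8  # cluster shift on many genes
  p <- pca_samples(base)
  expect_true(all(sign(p$coords[1:4, 1]) != sign(p$coords[5:8, 1])))
  expect_lte(sum(p$var_explained), 1)
  # duplicated samples land on coincident coordinates
  dup <- base; dup[, 2] <- dup[, 1]
  pd <- pca_samples(dup)
  expect_equal(pd$coords[1, ], pd$coords[2, ], tolerance = 1e-8)
  # sign convention: largest-|coordinate| entry is positive
  expect_gt(p$coords[which.max(abs(p$coords[, 1])), 1], 0)
  expect_error(pca_samples(matrix(1, 5, 4)), "constant")
})

test_that("size_factors reproduce the median-of-ratios construction", {
  m <- matrix(c(10L, 20L, 30L, 40L, 55L,
                10L, 20L, 30L, 40L, 55L,
                20L, 40L, 60L, 80L, 110L), 5, 3,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  sf <- size_factors(m)
  expect_equal(sf[["s1"]], sf[["s2"]])
  expect_equal(sf[["s3"]] / sf[["s1"]], 2)
  expect_equal(exp(mean(log(sf))), 1)
  # identical columns: all factors one
  expect_equal(unname(size_factors(m[, c(1, 1, 1)])), rep(1, 3))
  # no all-nonzero gene: total-count fallback
  mz <- m; mz[cbind(1:5, rep(1:3, length.out = 5))] <- 0L
  expect_message(size_factors(mz), "total-count")
})

test_that("nb_wald_test basic contracts hold", {
  set.seed(33)
  mu <- exp(runif(500, log(30), log(1000)))
  cnt <- matrix(rnbinom(500 * 6, mu = rep(mu, 6), size = 10), 500, 6,
                dimnames = list(paste0("g", 1:500), paste0("s", 1:6)))
  ga <- paste0("s", 1:3); gb <- paste0("s", 4:6)
  de <- nb_wald_test(cnt, ga, gb)
  # contrast antisymmetry
  de_rev <- nb_wald_test(cnt, gb, ga)
  expect_equal(de$log2fc, -de_rev$log2fc, tolerance = 1e-12)
  expect_equal(de$p, de_rev$p, tolerance = 1e-12)
  # identical normalized counts in both groups: log2FC = 0
  cnt2 <- cnt; cnt2[, 4:6] <- cnt[, 1:3]
  de2 <- nb_wald_test(cnt2, ga, gb)
  expect_equal(de2$log2fc, rep(0, 500))
  # all-zero gene flagged untestable with p = 1
  cnt3 <- cnt; cnt3[1, ] <- 0L
  de3 <- nb_wald_test(cnt3, ga, gb)
  expect_true(de3$untestable[1])
  expect_equal(de3$p[1], 1)
  # BH adjustment matches the textbook rule and is monotone
  expect_equal(de$padj, oracle_bh(de$p))
  expect_true(all(de$padj >= de$p - 1e-15))
})

test_that("call_degs applies all three criteria and is threshold-monotone", {
  de <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   base_mean_a = 10, base_mean_b = 10,
                   log2fc = c(2.5, 1.9, 2.5, 2.5), z = 3,
                   p = 0.01, padj = c(0.04, 0.04, 0.04, 0.2),
                   untestable = FALSE, stringsAsFactors = FALSE)
  attr(de, "groups") <- list(a = "sA", b = "sB")
  class(de) <- c("de_result", "data.frame")
  fpkm <- matrix(c(5, 5, 0.05, 5, 5, 5, 0.05, 5), 4, 2,
                 dimnames = list(de$gene_id, c("sA", "sB")))
  out <- call_degs(de, fpkm)
  expect_equal(out$deg, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$direction[1], "+")
  # relaxing thresholds never shrinks the set
  relaxed <- call_degs(de, fpkm, run_config(deg_abs_lfc_min = 1,
                                            deg_fdr_max = 0.5,
                                            deg_fpkm_min = 0.01))
  expect_true(all(out$deg <= relaxed$deg))
})

test_that("pairwise contrasts enumerate 16 (or 6 single-variety) comparisons", {
  meta <- sim_sample_meta <- acidsweep:::sim_sample_meta()
  tab <- pairwise_contrast_table(meta)
  expect_equal(nrow(tab), 16L)  # 2 x C(4,2) + 4
  expect_equal(sum(tab$type == "parallel"), 4L)
  expect_setequal(tab$contrast[tab$type == "parallel"],
                  c("DS1 vs AS1", "DS2 vs AS2", "DS3 vs AS3", "DS4 vs AS4"))
  one <- pairwise_contrast_table(meta[meta$variety == "AMT", ])
  expect_equal(nrow(one), 6L)   # C(4,2)
  # parallel group A is the AMT side (log2FC = AMT over DSHS)
  par1 <- tab[tab$contrast == "DS3 vs AS3", ]
  expect_true(all(grepl("^A", strsplit(par1$group_a, ",")[[1]])))
  expect_error(pairwise_contrast_table(meta[meta$stage != "S2", ]), "missing")
})

test_that("the packaged pathway sign matrix reproduces the published counts", {
  fx <- tca_matrix_fixture()
  m <- fx$matrix
  expect_equal(nrow(m), 25L)
  expect_equal(nrow(m) / fx$n_pathway_total, 0.76, tolerance = 0.005)
  signs <- as.matrix(m[, 3:6])
  expect_equal(sum(rowSums(signs == "+") > 0), 17L)
  expect_true(all(signs %in% c("", "+", "-")))
})

test_that("tca_deg_matrix counts DEGs per pathway from contrast calls", {
  mk <- function(ids, degs, dirs) {
    de <- data.frame(gene_id = ids, base_mean_a = 1, base_mean_b = 1,
                     log2fc = 3, z = 3, p = 0.001, padj = 0.001,
                     untestable = FALSE, deg = degs, direction = dirs,
                     stringsAsFactors = FALSE)
    class(de) <- c("de_result", "data.frame")
    de
  }
  ids <- c("t1", "t2", "x1")
  pathway <- data.frame(gene_id = c("t1", "t2", "t3"), pathway = "TCA")
  sets <- list("DS1 vs AS1" = mk(ids, c(TRUE, TRUE, TRUE), c("+", "-", "+")),
               "DS2 vs AS2" = mk(ids, c(TRUE, FALSE, FALSE), c("+", "", "")))
  out <- tca_deg_matrix(sets, pathway)
  expect_equal(out$counts$n_genes, 2L)
  expect_equal(out$counts$n_pathway, 3L)
  expect_equal(out$counts$n_any_up, 1L)
  expect_equal(out$counts$n_any_down, 1L)
  expect_equal(out$counts$n_all_up, 1L)
  # empty DEG sets give an empty matrix and zero counts
  empty <- list("DS1 vs AS1" = mk(ids, c(FALSE, FALSE, FALSE), c("", "", "")))
  out0 <- tca_deg_matrix(empty, pathway)
  expect_equal(out0$counts$n_genes, 0L)
  expect_equal(nrow(out0$matrix), 0L)
})

test_that("hypergeometric enrichment is exact and calibrated", {
  bg <- paste0("g", 1:20)
  ann <- data.frame(gene_id = bg[1:5], term = "T1")
  # all five term genes drawn in a five-gene set: p = 1/C(20,5)
  res <- hypergeom_enrichment(bg[1:5], ann, bg)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$rich_factor, 1)
  # a term covering the whole background has p = 1
  ann2 <- data.frame(gene_id = bg, term = "ALL")
  expect_equal(hypergeom_enrichment(bg[1:5], ann2, bg)$p, 1)
  expect_error(hypergeom_enrichment(bg[1:5], ann, character(0)), "background")
  expect_error(hypergeom_enrichment(c("zz"), ann, bg), "subset")

  # permutation null: observed p-values match their theoretical (discrete)
  # null distribution; a one-sample KS against the continuous uniform would
  # reject purely for discreteness
  set.seed(34)
  bg2 <- paste0("h", 1:2000)
  ann3 <- data.frame(gene_id = sample(bg2, 500), term = "T")
  pvals <- replicate(200, {
    hypergeom_enrichment(sample(bg2, 100), ann3, bg2)$p
  })
  ref <- phyper(rhyper(5000, 500, 1500, 100) - 1, 500, 1500, 100,
                lower.tail = FALSE)
  expect_gt(suppressWarnings(ks.test(pvals, ref))$p.value, 0.01)
  # and they are not anti-conservative
  expect_lte(mean(pvals < 0.05), 0.08)
})

test_that("filter_expressed applies the mean-FPKM rule", {
  f <- matrix(c(6, 6, 4, 4, 0, 0), 3, 2, byrow = TRUE,
              dimnames = list(c("hi", "lo", "zero"), c("s1", "s2")))
  expect_equal(filter_expressed(f), "hi")
  expect_setequal(filter_expressed(f, fpkm_min = 0), c("hi", "lo"))
  expect_error(filter_expressed(f, fpkm_min = 100), "no genes")
})
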