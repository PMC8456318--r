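#' FPKM quantification
#'
#' FPKM[g,s] = count[g,s] / ((totals[s] / 1e6) x (exonic_length_bp[g] / 1e3)),
#' i.e. fragments per kilobase of merged exonic length per million mapped
#' fragments.
#'
#' @param cm `count_matrix`.
#' @param models `gene_models` data.frame; every counted gene must have a
#'   model with positive exonic length.
#' @return numeric matrix of FPKM values (genes x samples).
#' @export
compute_fpkm <- function(cm, models) {
  genes <- rownames(cm$counts)
  idx <- match(genes, models$gene_id)
  if (anyNA(idx))
    stop("genes without models: ",
         paste(head(genes[is.na(idx)], 5), collapse = ","),
         if (sum(is.na(idx)) > 5) ", ...")
  len_kb <- models$exonic_length_bp[idx] / 1e3
  if (any(len_kb <= 0)) stop("exonic lengths must be > 0")
  if (any(cm$totals <= 0)) stop("totals must be > 0")
  mill <- cm$totals / 1e6
  fpkm <- sweep(cm$counts, 2, mill, `/`) / len_kb
  dimnames(fpkm) <- dimnames(cm$counts)
  fpkm
}

log2_fpkm <- function(fpkm) log2(fpkm + 1)

#' Replicate quality control by correlation
#'
#' For every condition (variety x stage), computes pairwise Pearson
#' correlations of log2(FPKM + 1) between its replicates; a sample is
#' flagged as an outlier iff its mean correlation with the other replicates
#' of its condition falls below `qc_pcc_min`. Flagged samples are excluded
#' from network construction downstream.
#'
#' @param fpkm FPKM matrix (genes x samples).
#' @param meta `sample_meta`.
#' @param qc_pcc_min flagging threshold (default 0.8).
#' @return list with `outliers` (character vector of sample ids), `pcc`
#'   (data.frame sample_id, condition, mean_pcc) and `kept` sample ids.
#' @export
replicate_qc <- function(fpkm, meta, qc_pcc_min = 0.8) {
  lf <- log2_fpkm(fpkm)
  rows <- list()
  for (cond in unique(meta$condition)) {
    ids <- meta$sample_id[meta$condition == cond]
    if (length(ids) < 2) {
      warning("condition ", cond, " has a single replicate; QC skipped")
      next
    }
    cc <- cor(lf[, ids, drop = FALSE])
    mean_pcc <- (rowSums(cc) - 1) / (length(ids) - 1)
    rows[[cond]] <- data.frame(sample_id = ids, condition = cond,
                               mean_pcc = unname(mean_pcc),
                               stringsAsFactors = FALSE)
  }
  pcc <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  outliers <- pcc$sample_id[pcc$mean_pcc < qc_pcc_min]
  list(outliers = outliers, pcc = pcc,
       kept = setdiff(meta$sample_id, outliers))
}

#' PCA of samples on log2(FPKM + 1)
#'
#' Genes are centered (optionally unit-scaled); sample coordinates come from
#' the SVD of the centered matrix. Deterministic sign convention: on each PC
#' the sample coordinate of largest magnitude is made positive.
#'
#' @param fpkm FPKM matrix.
#' @param n_pc number of components to return (default 2).
#' @param scale. logical, unit-scale genes (default FALSE).
#' @return list with `coords` (samples x PCs), `var_explained` (fraction per
#'   returned PC).
#' @export
pca_samples <- function(fpkm, n_pc = 2, scale. = FALSE) {
  if (ncol(fpkm) < 3) stop("need >= 3 samples")
  x <- t(log2_fpkm(fpkm))
  keep <- apply(x, 2, sd) > 0
  if (!any(keep)) stop("constant expression matrix: PCA undefined")
  x <- scale(x[, keep, drop = FALSE], center = TRUE, scale = scale.)
  sv <- svd(x)
  n_pc <- min(n_pc, length(sv$d))
  coords <- sv$u[, seq_len(n_pc), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pc)], n_pc)
  for (j in seq_len(n_pc)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(rownames(x), paste0("PC", seq_len(n_pc)))
  var_explained <- sv$d^2 / sum(sv$d^2)
  list(coords = coords, var_explained = var_explained[seq_len(n_pc)])
}

#' Median-of-ratios size factors
#'
#' For genes with nonzero counts in every sample, the per-sample factor is
#' the median ratio of the count to the gene's geometric mean; factors are
#' then normalised to geometric mean 1. If no gene is nonzero everywhere,
#' falls back to total-count ratios (with a message).
#'
#' @param counts integer matrix (genes x samples) or `count_matrix`.
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  all_nz <- rowSums(counts == 0) == 0
  if (!any(all_nz)) {
    message("no gene with nonzero counts in all samples; using total-count ratios")
    sf <- colSums(counts)
  } else {
    lg <- log(counts[all_nz, , drop = FALSE])
    lgeo <- rowMeans(lg)
    sf <- apply(exp(lg - lgeo), 2, median)
  }
  sf / exp(mean(log(sf)))
}

#' Negative-binomial Wald test between two sample groups
#'
#' Implements a documented NB Wald test: median-of-ratios size factors;
#' per-gene method-of-moments dispersion from within-group residuals of the
#' normalised counts, moderated toward the across-gene trend and bounded to
#' [1e-8, 10]; log2 fold change of group means with a pseudocount; standard
#' error via the delta method under NB variance mu + alpha mu^2; two-sided
#' normal p-values; Benjamini-Hochberg adjustment across genes.
#'
#' @param counts integer matrix or `count_matrix`.
#' @param group_a,group_b sample ids (>= 2 each). log2FC is A over B; for
#'   variety contrasts pass AMT as `group_a` so "+" means up in AMT.
#' @param contrast optional contrast label.
#' @return data.frame of class `de_result`: gene_id, base_mean_a,
#'   base_mean_b, log2fc, z, p, padj, untestable.
#' @export
nb_wald_test <- function(counts, group_a, group_b, contrast = NULL) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  stopifnot(length(group_a) >= 2, length(group_b) >= 2,
            all(c(group_a, group_b) %in% colnames(counts)))
  sub <- counts[, c(group_a, group_b), drop = FALSE]
  sf <- size_factors(sub)
  norm <- sweep(sub, 2, sf, `/`)
  na <- length(group_a); nb <- length(group_b)
  xa <- norm[, group_a, drop = FALSE]
  xb <- norm[, group_b, drop = FALSE]
  mu_a <- rowMeans(xa); mu_b <- rowMeans(xb)

  # within-group pooled MoM dispersion: var = mu + alpha mu^2
  ss <- rowSums((xa - mu_a)^2) + rowSums((xb - mu_b)^2)
  pooled_var <- ss / (na + nb - 2)
  grand <- (na * mu_a + nb * mu_b) / (na + nb)
  raw_alpha <- (pooled_var - grand) / grand^2
  raw_alpha[!is.finite(raw_alpha)] <- NA
  # moderate the noisy per-gene estimate toward the across-gene central value
  # (few residual df make raw MoM estimates wildly unstable at n = 3 + 3);
  # the central value is a clamped mean, not a median: per-gene moment
  # estimates are right-skewed and their median under-estimates dispersion,
  # which would inflate the Wald type-I error
  central <- mean(pmin(pmax(raw_alpha[grand > 5], 0), 10), na.rm = TRUE)
  if (!is.finite(central)) central <- 0.1
  central <- max(central, 1e-8)
  w <- (na + nb - 2) / (na + nb - 2 + 8)
  alpha <- w * raw_alpha + (1 - w) * central
  alpha[is.na(alpha)] <- central
  alpha <- pmin(pmax(alpha, 1e-8), 10)

  pc <- 0.5 / exp(mean(log(sf)))  # pseudocount on the normalised scale
  log2fc <- log2((mu_a + pc) / (mu_b + pc))
  # delta method: Var(mean_g norm counts) under NB(mu sf_i, alpha)
  inv_sa <- sum(1 / sf[group_a]); inv_sb <- sum(1 / sf[group_b])
  var_a <- mu_a * inv_sa / na^2 + alpha * mu_a^2 / na
  var_b <- mu_b * inv_sb / nb^2 + alpha * mu_b^2 / nb
  se <- sqrt(var_a / (mu_a + pc)^2 + var_b / (mu_b + pc)^2) / log(2)
  z <- log2fc / se
  p <- 2 * pnorm(-abs(z))
  untestable <- mu_a == 0 & mu_b == 0
  p[untestable] <- 1
  z[untestable] <- 0
  log2fc[untestable] <- 0
  out <- data.frame(
    gene_id = rownames(sub), base_mean_a = mu_a, base_mean_b = mu_b,
    log2fc = log2fc, z = z, p = p, padj = p.adjust(p, "BH"),
    untestable = untestable, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast
  attr(out, "groups") <- list(a = group_a, b = group_b)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Call differentially expressed genes
#'
#' DEG iff max(group-mean FPKM) > `deg_fpkm_min` AND BH-adjusted
#' p < `deg_fdr_max` AND |log2FC| > `deg_abs_lfc_min`. Direction "+" means
#' higher in group A (pass AMT as group A so "+" = up in the high-acid
#' variety).
#'
#' @param de `de_result` from [nb_wald_test()].
#' @param fpkm FPKM matrix sharing genes with `de`.
#' @param config `run_config`.
#' @return `de` with added columns `mean_fpkm_a`, `mean_fpkm_b`, `deg`,
#'   `direction`.
#' @export
call_degs <- function(de, fpkm, config = run_config()) {
  groups <- attr(de, "groups")
  idx <- match(de$gene_id, rownames(fpkm))
  if (anyNA(idx)) stop("DE genes missing from FPKM matrix")
  fa <- rowMeans(fpkm[idx, groups$a, drop = FALSE])
  fb <- rowMeans(fpkm[idx, groups$b, drop = FALSE])
  de$mean_fpkm_a <- fa
  de$mean_fpkm_b <- fb
  de$deg <- pmax(fa, fb) > config$deg_fpkm_min &
    de$padj < config$deg_fdr_max &
    abs(de$log2fc) > config$deg_abs_lfc_min &
    !de$untestable
  de$direction <- ifelse(de$log2fc > 0, "+", "-")
  de$direction[!de$deg] <- ""
  de
}

#' Enumerate the pipeline's pairwise contrasts
#'
#' All stage pairs within each variety (2 x choose(4,2) = 12) plus the four
#' parallel-stage between-variety contrasts, 16 in total. For parallel
#' contrasts group A is AMT (log2FC = AMT over DSHS, named "DSi vs ASi" after
#' the published table convention); within-variety contrasts put the later
#' stage in group A.
#'
#' @param meta `sample_meta`.
#' @return data.frame: contrast, type ("within"/"parallel"), group_a and
#'   group_b (comma-joined sample ids).
#' @export
pairwise_contrast_table <- function(meta) {
  ids <- function(v, st) {
    out <- meta$sample_id[meta$variety == v & meta$stage == st]
    if (!length(out)) stop("missing condition: ", v, " ", st)
    out
  }
  rows <- list()
  for (v in intersect(VARIETIES, unique(meta$variety))) {
    vs <- substr(v, 1, 1)
    stages <- intersect(STAGES, unique(meta$stage[meta$variety == v]))
    for (i in seq_along(stages)) for (j in seq_along(stages)) {
      if (i >= j) next
      rows[[length(rows) + 1]] <- data.frame(
        contrast = sprintf("%s%s vs %s%s", vs, stages[i], vs, stages[j]),
        type = "within",
        group_a = paste(ids(v, stages[j]), collapse = ","),
        group_b = paste(ids(v, stages[i]), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (all(VARIETIES %in% meta$variety)) {
    for (st in STAGES) {
      rows[[length(rows) + 1]] <- data.frame(
        contrast = sprintf("D%s vs A%s", st, st),
        type = "parallel",
        group_a = paste(ids("AMT", st), collapse = ","),
        group_b = paste(ids("DSHS", st), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run DE over every contrast and call DEGs
#'
#' @param cm `count_matrix`.
#' @param fpkm FPKM matrix.
#' @param meta `sample_meta`.
#' @param config `run_config`.
#' @param contrasts optional subset of contrast names.
#' @return named list of `de_result` data frames with DEG calls.
#' @export
run_all_contrasts <- function(cm, fpkm, meta, config = run_config(),
                              contrasts = NULL) {
  tab <- pairwise_contrast_table(meta)
  if (!is.null(contrasts)) tab <- tab[tab$contrast %in% contrasts, ]
  res <- lapply(seq_len(nrow(tab)), function(i) {
    de <- nb_wald_test(cm, strsplit(tab$group_a[i], ",")[[1]],
                       strsplit(tab$group_b[i], ",")[[1]],
                       contrast = tab$contrast[i])
    call_degs(de, fpkm, config)
  })
  names(res) <- tab$contrast
  res
}

#' Sign matrix of pathway DEGs across parallel contrasts
#'
#' Builds the published-table-shaped matrix: one row per pathway gene that is
#' a DEG in at least one parallel-stage contrast, one signed entry per
#' contrast, plus the summary counts.
#'
#' @param deg_sets named list of DEG-called `de_result`s for the parallel
#'   contrasts (names like "DS1 vs AS1").
#' @param pathway data.frame (gene_id, pathway); rows are restricted to
#'   `pathway_label` genes.
#' @param pathway_label pathway to tabulate (default `"TCA"`).
#' @return list with `matrix` (data.frame gene_id + one +/- column per
#'   contrast) and `counts` (n_genes, n_pathway, frac_of_pathway, n_any_up,
#'   n_any_down, n_all_up).
#' @export
tca_deg_matrix <- function(deg_sets, pathway, pathway_label = "TCA") {
  pgenes <- pathway$gene_id[pathway$pathway == pathway_label]
  cn <- names(deg_sets)
  signs <- matrix("", length(pgenes), length(cn),
                  dimnames = list(pgenes, cn))
  for (ct in cn) {
    de <- deg_sets[[ct]]
    hit <- de$gene_id %in% pgenes & de$deg
    signs[de$gene_id[hit], ct] <- de$direction[hit]
  }
  any_deg <- rowSums(signs != "") > 0
  m <- data.frame(gene_id = pgenes[any_deg],
                  signs[any_deg, , drop = FALSE],
                  check.names = FALSE, stringsAsFactors = FALSE,
                  row.names = NULL)
  sub <- signs[any_deg, , drop = FALSE]
  counts <- list(
    n_genes = sum(any_deg),
    n_pathway = length(pgenes),
    frac_of_pathway = if (length(pgenes)) sum(any_deg) / length(pgenes) else NA,
    n_any_up = sum(rowSums(sub == "+") > 0),
    n_any_down = sum(rowSums(sub == "-") > 0),
    n_all_up = sum(rowSums(sub == "+") == ncol(sub)))
  list(matrix = m, counts = counts)
}

#' Packaged transcription of the published TCA DEG sign matrix
#'
#' 25 TCA-pathway genes with their +/- direction (up/down in AMT) in the four
#' parallel-stage contrasts; empty cells mean not a DEG in that contrast.
#' The published pathway has 33 TCA-related genes in total.
#'
#' @return list with `matrix` (data.frame) and `n_pathway_total` (33).
#' @export
tca_matrix_fixture <- function() {
  path <- system.file("extdata", "table2.tsv", package = "acidsweep",
                      mustWork = TRUE)
  m <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                       fill = TRUE, na.strings = NULL))
  for (j in 3:6) m[[j]][is.na(m[[j]])] <- ""
  list(matrix = m, n_pathway_total = 33L)
}

#' Hypergeometric enrichment against a user-supplied annotation
#'
#' For each term, p = P(X >= k) with X ~ Hypergeometric(N, K, n): N
#' background genes, K of them carrying the term, n genes in the query set,
#' k of those carrying the term. BH correction across terms; rich factor
#' k / K.
#'
#' @param gene_set character vector, must be a subset of `background`.
#' @param annotation data.frame (gene_id, term); genes outside `background`
#'   are ignored.
#' @param background character vector of background gene ids.
#' @return data.frame: term, k, n, K, N, p, padj, rich_factor, ordered by p.
#' @export
hypergeom_enrichment <- function(gene_set, annotation, background) {
  if (!length(background)) stop("empty background")
  background <- unique(background)
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% background))
    stop("gene_set must be a subset of background")
  ann <- annotation[annotation$gene_id %in% background, ]
  N <- length(background); n <- length(gene_set)
  terms <- unique(ann$term)
  rows <- lapply(terms, function(tm) {
    tg <- unique(ann$gene_id[ann$term == tm])
    K <- length(tg)
    k <- length(intersect(tg, gene_set))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p = p,
               rich_factor = if (K) k / K else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, "BH")
  out[order(out$p), c("term", "k", "n", "K", "N", "p", "padj", "rich_factor")]
}

#' Filter to expressed genes for network construction
#'
#' Keeps genes whose mean FPKM across the retained samples exceeds
#' `fpkm_min` (QC outliers should already be excluded from `samples`).
#'
#' @param fpkm FPKM matrix.
#' @param samples sample ids to average over (default all columns).
#' @param fpkm_min threshold (default 5).
#' @return character vector of kept gene ids.
#' @export
filter_expressed <- function(fpkm, samples = colnames(fpkm), fpkm_min = 5) {
  keep <- rowMeans(fpkm[, samples, drop = FALSE]) > fpkm_min
  if (!any(keep)) stop("no genes pass the expression filter")
  rownames(fpkm)[keep]
}
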