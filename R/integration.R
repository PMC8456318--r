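#' Select candidate acid genes
#'
#' A gene is a candidate iff it carries a pathway label (TCA or
#' transporter), it is a DEG in at least one parallel-stage contrast, and it
#' belongs to one of the key modules. Each record keeps the evidence for all
#' three predicates.
#'
#' @param pathway data.frame (gene_id, pathway).
#' @param deg_sets named list of DEG-called `de_result`s for the parallel
#'   contrasts.
#' @param key_modules named character vector trait -> module label from
#'   [select_key_modules()].
#' @param labels named module labels.
#' @return data.frame: gene_id, pathway, module, deg_contrasts (comma
#'   joined), directions.
#' @export
select_candidates <- function(pathway, deg_sets, key_modules, labels) {
  if (!length(key_modules)) stop("no key modules")
  keyset <- unique(key_modules)
  rows <- list()
  for (i in seq_len(nrow(pathway))) {
    g <- pathway$gene_id[i]
    in_key <- !is.na(labels[g]) && as.character(labels[g]) %in% keyset
    hits <- dirs <- character(0)
    for (ct in names(deg_sets)) {
      de <- deg_sets[[ct]]
      j <- match(g, de$gene_id)
      if (!is.na(j) && de$deg[j]) {
        hits <- c(hits, ct)
        dirs <- c(dirs, de$direction[j])
      }
    }
    if (in_key && length(hits)) {
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = g, pathway = pathway$pathway[i],
        module = as.character(labels[g]),
        deg_contrasts = paste(hits, collapse = ","),
        directions = paste(dirs, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), pathway = character(0),
                      module = character(0), deg_contrasts = character(0),
                      directions = character(0)))
  do.call(rbind, rows)
}

#' Nominate domestication genes by dual-sweep intersection
#'
#' Universe = candidate genes plus TF nodes of both variety networks; a gene
#' is nominated iff its span overlaps at least one F_ST sweep region AND at
#' least one XP-CLR sweep region.
#'
#' @param candidates data.frame from [select_candidates()].
#' @param trn_a,trn_d `mr_network`s (either may be NULL).
#' @param fst_sweeps,xpclr_sweeps `sweep_regions`.
#' @param models `gene_models`.
#' @return data.frame: gene_id, role ("candidate"/"TRN-TF"), fst_region,
#'   xpclr_region (as "start-end" strings).
#' @export
nominate_domestication_genes <- function(candidates, trn_a, trn_d,
                                         fst_sweeps, xpclr_sweeps, models) {
  tf_nodes <- unique(c(if (!is.null(trn_a)) trn_a$tfs,
                       if (!is.null(trn_d)) trn_d$tfs))
  universe <- unique(c(candidates$gene_id, tf_nodes))
  if (!length(universe)) stop("empty candidate/TF universe")
  sub <- models[models$gene_id %in% universe, , drop = FALSE]
  in_fst <- genes_in_regions(sub, fst_sweeps)
  in_xp <- genes_in_regions(sub, xpclr_sweeps)
  nominated <- intersect(in_fst$gene_id, in_xp$gene_id)
  if (!length(nominated))
    return(data.frame(gene_id = character(0), role = character(0),
                      fst_region = character(0), xpclr_region = character(0)))
  data.frame(
    gene_id = nominated,
    role = ifelse(nominated %in% candidates$gene_id, "candidate", "TRN-TF"),
    fst_region = vapply(nominated, function(g) {
      r <- in_fst[in_fst$gene_id == g, ][1, ]
      sprintf("%d-%d", r$region_start, r$region_end)
    }, ""),
    xpclr_region = vapply(nominated, function(g) {
      r <- in_xp[in_xp$gene_id == g, ][1, ]
      sprintf("%d-%d", r$region_start, r$region_end)
    }, ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Stage-3 cross-variety validation of nominated genes
#'
#' NB Wald test restricted to the S3 replicates of both varieties, with
#' Bonferroni-Holm adjustment across the supplied gene list only (the
#' targeted-validation convention). Direction "+" = up in AMT.
#'
#' @param cm `count_matrix`.
#' @param meta `sample_meta`.
#' @param genes gene ids to validate.
#' @return data.frame: gene_id, log2fc, z, p, padj (Holm), direction;
#'   genes absent from the matrix are listed with `tested = FALSE`.
#' @export
s3_validation <- function(cm, meta, genes) {
  a <- meta$sample_id[meta$variety == "AMT" & meta$stage == "S3"]
  d <- meta$sample_id[meta$variety == "DSHS" & meta$stage == "S3"]
  if (length(a) < 2 || length(d) < 2) stop("need >= 2 S3 replicates per variety")
  de <- nb_wald_test(cm, a, d, contrast = "DS3 vs AS3")
  idx <- match(genes, de$gene_id)
  out <- data.frame(gene_id = genes,
                    log2fc = de$log2fc[idx], z = de$z[idx], p = de$p[idx],
                    tested = !is.na(idx), stringsAsFactors = FALSE)
  out$padj <- NA_real_
  out$padj[out$tested] <- p.adjust(out$p[out$tested], "holm")
  out$direction <- ifelse(out$log2fc > 0, "+", "-")
  out$direction[!out$tested] <- ""
  out
}

#' Run the full pipeline on an input bundle
#'
#' Executes FPKM -> replicate QC -> DE over all contrasts -> co-expression
#' modules -> per-variety mutual-rank networks -> hard filter -> F_ST and
#' XP-CLR scans -> sweep calling -> candidate selection -> dual-sweep
#' nomination -> S3 validation.
#'
#' @param bundle list as returned by [simulate_dataset()] (counts, meta,
#'   traits, variants, popmap, ann).
#' @param config `run_config`.
#' @return list of class `pipeline_result` with all stage artifacts.
#' @export
run_pipeline <- function(bundle, config = run_config()) {
  models <- bundle$ann$models
  fpkm <- compute_fpkm(bundle$counts, models)
  qc <- replicate_qc(fpkm, bundle$meta, config$qc_pcc_min)
  meta_kept <- bundle$meta[bundle$meta$sample_id %in% qc$kept, ]

  de <- run_all_contrasts(bundle$counts, fpkm, bundle$meta, config)
  parallel <- de[grep("^DS[1-4] vs AS[1-4]$", names(de))]

  expressed <- filter_expressed(fpkm, qc$kept, config$fpkm_min_expressed)
  lf <- log2_fpkm(fpkm[expressed, qc$kept, drop = FALSE])
  adj <- soft_adjacency(fpkm[expressed, qc$kept, drop = FALSE],
                        beta = config$soft_power)
  lf <- lf[rownames(adj), , drop = FALSE]
  tom <- tom_similarity(adj)
  mods <- detect_modules(1 - tom, expr = lf,
                         min_module_size = config$min_module_size)
  merged <- if (length(mods$sizes) >= 2)
    merge_modules(lf, mods$labels, config$merge_cut_height)
  else list(labels = mods$labels, eigengenes = module_eigengenes(lf, mods$labels))
  traits <- bundle$traits[qc$kept, , drop = FALSE]
  mt <- module_trait_stats(merged$eigengenes$eigengenes, traits, lf,
                           merged$labels)
  key <- select_key_modules(mt)

  candidates <- select_candidates(bundle$ann$pathway, parallel, key,
                                  merged$labels)
  tf_ids <- intersect(bundle$ann$tf_list$gene_id, expressed)
  trn <- list()
  for (v in VARIETIES) {
    ids <- meta_kept$sample_id[meta_kept$variety == v]
    pcc <- pcc_matrix(fpkm[expressed, , drop = FALSE], ids)
    mr <- mutual_rank(pcc)
    cand_ids <- intersect(candidates$gene_id, rownames(pcc))
    trn[[v]] <- if (length(cand_ids) && length(intersect(tf_ids, rownames(pcc))))
      build_trn(mr, pcc, tf_ids, cand_ids, config$mr_pcc_min,
                config$mr_rank_max, variety = v)
    else NULL
  }

  hf <- hard_filter(bundle$variants)
  chrom_len <- max(models$end)
  snp_stats <- wc_fst_per_snp(hf$variants, "POP_BRET", "POP_SINK")
  fst_scan <- fst_windowed_scan(snp_stats, chrom_len, config$window_bp,
                                config$step_bp, config$min_snps_per_window)
  xp_scan <- xpclr_window_score(hf$variants, "POP_BRET", "POP_SINK",
                                chrom_len, config$window_bp, config$step_bp,
                                config$min_snps_per_window)
  fst_sweeps <- call_sweeps(fst_scan, config$fst_top_fraction)
  xp_sweeps <- call_sweeps(xp_scan, config$xpclr_top_fraction)

  universe_n <- nrow(candidates) +
    length(unique(c(if (!is.null(trn$AMT)) trn$AMT$tfs,
                    if (!is.null(trn$DSHS)) trn$DSHS$tfs)))
  nominations <- if (universe_n > 0)
    nominate_domestication_genes(candidates, trn$AMT, trn$DSHS, fst_sweeps,
                                 xp_sweeps, models)
  else data.frame(gene_id = character(0), role = character(0),
                  fst_region = character(0), xpclr_region = character(0))
  validation <- if (nrow(nominations))
    s3_validation(bundle$counts, bundle$meta, nominations$gene_id)
  else NULL

  # descriptive statistic (not a contract): median expression per condition
  med_expr <- tapply(seq_len(nrow(bundle$meta)), bundle$meta$condition,
                     function(i) median(log2_fpkm(
                       fpkm[, bundle$meta$sample_id[i], drop = FALSE])))
  structure(list(
    fpkm = fpkm, qc = qc, de = de, expressed = expressed,
    median_expr_by_condition = med_expr[order(names(med_expr))],
    modules = merged$labels, eigengenes = merged$eigengenes$eigengenes,
    module_trait = mt, key_modules = key, candidates = candidates,
    trn = trn, filter_counts = hf$filter_counts, snp_stats = snp_stats,
    fst_scan = fst_scan, xpclr_scan = xp_scan,
    fst_sweeps = fst_sweeps, xpclr_sweeps = xp_sweeps,
    nominations = nominations, validation = validation,
    config = config), class = "pipeline_result")
}

#' Structured pipeline report
#'
#' Collects the headline numbers of every stage into one list suitable for
#' JSON serialisation; numbers are read from the stage artifacts, never
#' recomputed at render time.
#'
#' @param result `pipeline_result`.
#' @return list of class `pipeline_report`.
#' @export
build_report <- function(result) {
  deg_counts <- lapply(result$de, function(d)
    list(deg = sum(d$deg), up = sum(d$deg & d$direction == "+"),
         down = sum(d$deg & d$direction == "-")))
  rep <- list(
    schema_version = 1L,
    qc = list(outliers = result$qc$outliers),
    median_expr_by_condition = as.list(result$median_expr_by_condition),
    deg_counts = deg_counts,
    n_expressed = length(result$expressed),
    n_modules = length(unique(result$modules[result$modules > 0])),
    n_unassigned = sum(result$modules == 0),
    module_trait_cor = as.data.frame(result$module_trait$trait_cor),
    key_modules = as.list(result$key_modules),
    candidates = result$candidates,
    trn = lapply(result$trn, function(x) if (is.null(x)) NULL else
      list(n_edges = nrow(x$edges), tfs = x$tfs)),
    shared_tfs = if (!is.null(result$trn$AMT) && !is.null(result$trn$DSHS))
      intersect(result$trn$AMT$tfs, result$trn$DSHS$tfs) else character(0),
    hard_filter_counts = as.list(result$filter_counts),
    fst = list(threshold = result$fst_sweeps$threshold,
               n_regions = nrow(result$fst_sweeps$regions)),
    xpclr = list(threshold = result$xpclr_sweeps$threshold,
                 n_regions = nrow(result$xpclr_sweeps$regions)),
    nominations = result$nominations,
    validation = result$validation)
  class(rep) <- c("pipeline_report", "list")
  rep
}

#' Write a report as JSON (deterministic given the pipeline seed)
#'
#' @param report `pipeline_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}
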