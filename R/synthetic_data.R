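#' Simulation specification
#'
#' Defines the stated world for the synthetic inputs: 2 varieties x 4 stages
#' x 3 replicates of negative-binomial counts with block-correlated module
#' structure and planted variety effects; organic-acid traits driven by one
#' module's latent factor; and three diploid populations (two domesticated,
#' one wild) with mosaic-founder linkage disequilibrium and a planted
#' selective sweep in the high-acid domesticated population (POP_SINK).
#'
#' @param ... name = value overrides. Fields and defaults:
#' \describe{
#'   \item{n_genes}{2000 genes tiled on one chromosome.}
#'   \item{module_sizes}{c(120, 100, 80, 60, 40): five co-expression modules.}
#'   \item{module_intra_correlation}{0.8 latent-scale Pearson within modules.}
#'   \item{module_effect_sd}{1 (log2) sd of the shared module factor term.}
#'   \item{n_de_genes}{100 variety-DE genes, half up in AMT, half down.}
#'   \item{n_stage_de_genes}{100 genes with a linear stage trend.}
#'   \item{variety_lfc}{3: planted |log2FC| of variety-DE genes.}
#'   \item{nb_dispersion}{0.1 NB dispersion alpha (var = mu + alpha mu^2).}
#'   \item{library_size_range}{c(8e6, 12e6) total mapped fragments.}
#'   \item{trait_module_index}{2: module whose factor drives MA and CA.}
#'   \item{trait_noise_sd}{0.3 mg/g FW residual noise on MA.}
#'   \item{acid_variety_offset}{1: shift of the acid-module factor in AMT.}
#'   \item{n_tf}{60 transcription factors.}
#'   \item{chromosome_length_bp}{2e6.}
#'   \item{n_snps}{5000.}
#'   \item{pop_sizes}{c(POP_BRET = 30, POP_SINK = 10, WILD = 20) diploids.}
#'   \item{founder_haplotypes}{c(POP_BRET = 12, POP_SINK = 12, WILD = 40).}
#'   \item{f_pop}{terminal Balding-Nichols drift F per population
#'     (c(POP_BRET = 0.03, POP_SINK = 0.03, WILD = 0.03)).}
#'   \item{f_dom_split}{0.08: shared drift of the domesticated-ancestor
#'     branch; total domesticated drift from the species ancestor is thus
#'     larger than the wild population's, as domestication bottlenecks
#'     imply.}
#'   \item{switch_rate}{1e-5 founder-switch probability per bp
#'     (domesticated populations).}
#'   \item{wild_switch_rate}{4e-5, the wild population's switch rate.}
#'   \item{sweep_center_bp}{1e6.}
#'   \item{sweep_strength}{0.9: c0, pull toward the major allele at center.}
#'   \item{sweep_decay_length_bp}{5e4 exponential decay length.}
#'   \item{info_fail_fraction}{0.05 of SNPs planted to fail hard filters.}
#'   \item{rng_seed}{1.}
#' }
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(...) {
  spec <- list(
    n_genes = 2000L,
    module_sizes = c(120L, 100L, 80L, 60L, 40L),
    module_intra_correlation = 0.8,
    module_effect_sd = 1,
    n_de_genes = 100L,
    n_stage_de_genes = 100L,
    variety_lfc = 3,
    nb_dispersion = 0.1,
    library_size_range = c(8e6, 12e6),
    trait_module_index = 2L,
    trait_noise_sd = 0.3,
    acid_variety_offset = 1,
    n_tf = 60L,
    chromosome_length_bp = 2e6,
    n_snps = 5000L,
    pop_sizes = c(POP_BRET = 30L, POP_SINK = 10L, WILD = 20L),
    founder_haplotypes = c(POP_BRET = 12L, POP_SINK = 12L, WILD = 40L),
    f_pop = c(POP_BRET = 0.03, POP_SINK = 0.03, WILD = 0.03),
    f_dom_split = 0.08,
    switch_rate = 1e-5,
    wild_switch_rate = 4e-5,
    sweep_center_bp = 1e6,
    sweep_strength = 0.9,
    sweep_decay_length_bp = 5e4,
    info_fail_fraction = 0.05,
    rng_seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown)) stop("unknown spec fields: ", paste(unknown, collapse = ","))
  spec[names(dots)] <- dots
  if (sum(spec$module_sizes) > spec$n_genes)
    stop("module sizes exceed n_genes")
  if (spec$module_intra_correlation <= 0 || spec$module_intra_correlation >= 1)
    stop("module_intra_correlation must be in (0,1)")
  if (spec$sweep_strength < 0 || spec$sweep_strength > 1)
    stop("sweep_strength c0 must be in [0,1]")
  if (spec$n_snps < 2) stop("n_snps must be >= 2")
  structure(spec, class = "simulation_spec")
}

# Deterministic placement of the planted genes relative to the sweep center:
# a "TCA" gene and a "transporter" gene inside the sweep interval, the AMT
# regulator TF right next to them, and the DSHS regulator far away.
planted_layout <- function(spec) {
  spacing <- floor(spec$chromosome_length_bp / spec$n_genes)
  idx_center <- max(3L, min(spec$n_genes - 3L,
                            as.integer(round(spec$sweep_center_bp / spacing))))
  list(spacing = spacing,
       idx_tca = idx_center,
       idx_transporter = idx_center + 1L,
       idx_tf_amt = idx_center + 2L,
       idx_tf_dshs = max(1L, idx_center - as.integer(
         round(0.8 * spec$sweep_center_bp / spacing))))
}

sim_sample_meta <- function() {
  grid <- expand.grid(replicate = 1:3, stage = STAGES, variety = VARIETIES,
                      stringsAsFactors = FALSE)
  sample_meta(
    sample_id = paste(substr(grid$variety, 1, 1), STAGE_DAFB[grid$stage],
                      grid$replicate, sep = "-"),
    variety = grid$variety, stage = grid$stage, replicate = grid$replicate)
}

#' Simulate the RNA-seq count matrix
#'
#' Latent log2 expression per gene and sample is baseline + module factor
#' (shared within a module, scaled so the intra-module latent Pearson
#' correlation equals `module_intra_correlation`) + planted variety/stage
#' effects; counts are NB(mean = library factor x 2^latent, dispersion
#' alpha). The acid-linked module's factor carries a variety offset (higher
#' in the high-acid variety AMT), mirroring an acid module whose genes run
#' higher in AMT without individually passing the DEG fold-change bar.
#'
#' @param spec `simulation_spec`.
#' @return list with `counts` (`count_matrix`), `meta` (`sample_meta`) and
#'   `truth` (module labels, module factors, DE tables, TF identities,
#'   baselines, library sizes).
#' @export
simulate_counts <- function(spec = simulation_spec()) {
  set.seed(spec$rng_seed)
  meta <- sim_sample_meta()
  n_s <- nrow(meta)
  n_g <- spec$n_genes
  lay <- planted_layout(spec)
  gene_id <- sprintf("G%04d", seq_len(n_g))

  # module membership: random gene indices, planted positives forced into
  # the acid-linked module
  module <- integer(n_g)
  pool <- setdiff(seq_len(n_g), c(lay$idx_tca, lay$idx_transporter,
                                  lay$idx_tf_amt, lay$idx_tf_dshs))
  for (m in seq_along(spec$module_sizes)) {
    take <- sample(pool, spec$module_sizes[m])
    module[take] <- m
    pool <- setdiff(pool, take)
  }
  acid_m <- spec$trait_module_index
  module[c(lay$idx_tca, lay$idx_transporter)] <- acid_m

  # shared per-module, per-sample factors; acid module gets a variety offset
  fac <- matrix(rnorm(length(spec$module_sizes) * n_s), ncol = n_s,
                dimnames = list(NULL, meta$sample_id))
  fac[acid_m, ] <- fac[acid_m, ] +
    spec$acid_variety_offset * (meta$variety == "AMT")

  # baselines (log2 of expected count at the reference library size):
  # designated genes are safely above the WGCNA FPKM filter, background
  # genes span the expressed/unexpressed boundary
  base <- runif(n_g, 0, 11)
  designated <- module > 0L
  base[designated] <- runif(sum(designated), log2(60), log2(3000))

  # variety-DE genes (outside modules, apart from the planted positives)
  de_pool <- setdiff(which(module == 0L),
                     c(lay$idx_tf_amt, lay$idx_tf_dshs))
  de_idx <- sample(de_pool, spec$n_de_genes)
  de_sign <- rep(c(1, -1), length.out = spec$n_de_genes)
  base[de_idx] <- pmax(base[de_idx], log2(60))
  # stage-trend genes (linear in stage, shared by both varieties)
  st_pool <- setdiff(which(module == 0L), c(de_idx, lay$idx_tf_amt, lay$idx_tf_dshs))
  st_idx <- sample(st_pool, spec$n_stage_de_genes)
  st_sign <- rep(c(1, -1), length.out = spec$n_stage_de_genes)
  base[st_idx] <- pmax(base[st_idx], log2(60))

  # TFs: regulators follow the acid factor within their own variety only
  tf_pool <- setdiff(which(module == 0L), c(de_idx, st_idx))
  tf_idx <- c(lay$idx_tf_amt, lay$idx_tf_dshs,
              sample(setdiff(tf_pool, c(lay$idx_tf_amt, lay$idx_tf_dshs)),
                     spec$n_tf - 2L))
  base[tf_idx] <- pmax(base[tf_idx], log2(60))
  tf_family <- rep(c("bHLH", "MYB", "bZIP", "NAC", "WRKY", "TALE"),
                   length.out = spec$n_tf)
  tf_family[1:2] <- c("ERF", "ERF")

  rho <- spec$module_intra_correlation
  a <- spec$module_effect_sd
  e_sd <- a * sqrt((1 - rho) / rho)

  x <- matrix(0, n_g, n_s, dimnames = list(gene_id, meta$sample_id))
  x[] <- base
  inmod <- which(module > 0L)
  x[inmod, ] <- x[inmod, ] + a * fac[module[inmod], , drop = FALSE] +
    matrix(rnorm(length(inmod) * n_s, sd = e_sd), length(inmod), n_s)
  bg <- which(module == 0L)
  x[bg, ] <- x[bg, ] + matrix(rnorm(length(bg) * n_s, sd = 0.5), length(bg), n_s)

  is_amt <- meta$variety == "AMT"
  # variety effects split symmetrically so planted |log2FC| = variety_lfc
  x[de_idx, is_amt] <- x[de_idx, is_amt] + de_sign * spec$variety_lfc / 2
  x[de_idx, !is_amt] <- x[de_idx, !is_amt] - de_sign * spec$variety_lfc / 2
  # planted positives: up in AMT at S3 only (a stage-specific variety
  # effect keeps their within-variety profile coherent with the acid module)
  pos_idx <- c(lay$idx_tca, lay$idx_transporter)
  s3 <- meta$stage == "S3"
  x[pos_idx, is_amt & s3] <- x[pos_idx, is_amt & s3] + spec$variety_lfc / 2
  x[pos_idx, !is_amt & s3] <- x[pos_idx, !is_amt & s3] - spec$variety_lfc / 2
  stage_num <- as.numeric(factor(meta$stage, levels = STAGES)) - 1
  x[st_idx, ] <- x[st_idx, ] +
    outer(st_sign * spec$variety_lfc / 3, stage_num - 1.5)

  # regulator TFs: near-noiseless copy of the acid factor in their variety
  x[lay$idx_tf_amt, is_amt] <- base[lay$idx_tf_amt] +
    a * fac[acid_m, is_amt] + rnorm(sum(is_amt), sd = 0.1)
  x[lay$idx_tf_dshs, !is_amt] <- base[lay$idx_tf_dshs] +
    a * fac[acid_m, !is_amt] + rnorm(sum(!is_amt), sd = 0.1)

  lib <- exp(runif(n_s, log(spec$library_size_range[1]),
                   log(spec$library_size_range[2])))
  names(lib) <- meta$sample_id
  sf <- lib / 1e7  # reference library 10M
  mu <- sweep(2^x, 2, sf, `*`)
  alpha <- spec$nb_dispersion
  size <- if (alpha <= 0) Inf else 1 / alpha
  cnt <- matrix(rnbinom(length(mu), mu = mu, size = size), n_g, n_s,
                dimnames = dimnames(mu))
  truth <- list(
    layout = lay,
    module = setNames(module, gene_id),
    module_factors = fac,
    acid_module = acid_m,
    de_genes = data.frame(
      gene_id = c(gene_id[de_idx], gene_id[pos_idx]),
      lfc = c(de_sign * spec$variety_lfc, rep(spec$variety_lfc, 2)),
      stages = c(rep("all", length(de_idx)), "S3", "S3"),
      stringsAsFactors = FALSE),
    stage_de_genes = gene_id[st_idx],
    tf_genes = data.frame(gene_id = gene_id[tf_idx], family = tf_family,
                          stringsAsFactors = FALSE),
    tf_edges = data.frame(
      tf = gene_id[c(lay$idx_tf_amt, lay$idx_tf_amt,
                     lay$idx_tf_dshs, lay$idx_tf_dshs)],
      target = gene_id[rep(c(lay$idx_tca, lay$idx_transporter), 2)],
      variety = c("AMT", "AMT", "DSHS", "DSHS"),
      stringsAsFactors = FALSE),
    positives = c(TCA = gene_id[lay$idx_tca],
                  transporter = gene_id[lay$idx_transporter]),
    baseline_log2 = setNames(base, gene_id),
    library_sizes = lib)
  list(counts = count_matrix(cnt, totals = round(lib)), meta = meta,
       truth = truth)
}

#' Simulate the organic-acid trait table
#'
#' Malic acid (MA) is an affine function of the acid-linked module's latent
#' factor plus Gaussian noise; citric acid (CA) shares the same factor with
#' a smaller coefficient; oxalic acid (OA) is independent noise. Units mg/g
#' fresh weight, floored at 0.
#'
#' @param spec `simulation_spec`.
#' @param truth ground truth from [simulate_counts()].
#' @return data.frame (rownames = sample ids) with columns OA, MA, CA.
#' @export
simulate_traits <- function(spec, truth) {
  set.seed(spec$rng_seed + 1L)
  f <- truth$module_factors[truth$acid_module, ]
  n <- length(f)
  ma <- 4 + 1.0 * f + rnorm(n, sd = spec$trait_noise_sd)
  ca <- 1.5 + 0.4 * f + rnorm(n, sd = spec$trait_noise_sd / 2)
  oa <- 0.8 + rnorm(n, sd = 0.2)
  out <- data.frame(OA = pmax(oa, 0), MA = pmax(ma, 0), CA = pmax(ca, 0),
                    row.names = names(f))
  out
}

#' Simulate population genotypes with LD and a planted sweep
#'
#' Per-SNP ancestral frequencies are Uniform(0.05, 0.95); population
#' frequencies follow the Balding-Nichols Beta model with per-population F
#' (larger in the domesticated populations). Founder haplotypes are drawn per
#' population and individuals are built as founder mosaics with a per-bp
#' switch rate, which creates linkage disequilibrium whose range grows as the
#' founder count shrinks. In POP_SINK only, SNP frequencies are pulled toward
#' the locally major allele -- the reference population's realized major
#' allele, so the planted sweep is exactly the alternative hypothesis the
#' composite-likelihood scan models -- by c(x) = c0 exp(-|x - center| /
#' decay), planting a selective sweep. INFO annotations are drawn from passing/failing
#' mixtures with known labels so hard filters are exercisable.
#'
#' @param spec `simulation_spec`.
#' @return list with `variants` (`variant_table`), `popmap`, and `truth`
#'   (ancestral/population frequencies, sweep interval, INFO pass labels).
#' @export
simulate_genotypes <- function(spec = simulation_spec()) {
  set.seed(spec$rng_seed + 2L)
  L <- spec$chromosome_length_bp
  pos <- sort(sample.int(L, spec$n_snps))
  p_anc <- runif(spec$n_snps, 0.05, 0.95)
  pops <- names(spec$pop_sizes)
  bn <- function(p, F) rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  # hierarchical Balding-Nichols: the two domesticated populations share a
  # domesticated-ancestor drift step; the wild population drifts from the
  # species ancestor directly
  p_dom <- bn(p_anc, spec$f_dom_split)
  pfreq <- sapply(pops, function(pp) {
    src <- if (pp == "WILD") p_anc else p_dom
    bn(src, spec$f_pop[[pp]])
  })
  cc <- spec$sweep_strength *
    exp(-abs(pos - spec$sweep_center_bp) / spec$sweep_decay_length_bp)

  ind_ids <- unlist(lapply(pops, function(pp)
    sprintf("%s_%02d", pp, seq_len(spec$pop_sizes[[pp]]))))
  popmap <- data.frame(
    individual_id = ind_ids,
    population = rep(pops, times = unlist(spec$pop_sizes[pops])),
    stringsAsFactors = FALSE)

  gaps <- diff(pos)
  geno <- matrix(0L, spec$n_snps, length(ind_ids),
                 dimnames = list(NULL, ind_ids))
  maj_ref <- NULL
  # POP_BRET first: its realized founder-pool majority defines the locally
  # major allele the sweep fixes in POP_SINK (the sweep alternative the scan
  # models, keyed to the reference population's major allele)
  for (pp in c("POP_BRET", setdiff(pops, "POP_BRET"))) {
    # wild populations recombine faster (no domestication bottleneck),
    # giving shorter-range LD on top of the smaller per-founder amplitude
    rate <- if (pp == "WILD") spec$wild_switch_rate else spec$switch_rate
    p_switch <- 1 - exp(-rate * gaps)
    K <- spec$founder_haplotypes[[pp]]
    pf <- pfreq[, pp]
    if (pp == "POP_SINK") pf <- (1 - cc) * pf + cc * maj_ref
    # frequency-matched founder alleles: exactly floor(K p) carriers plus a
    # stochastic remainder, randomly placed. The founder pool then realises
    # the Balding-Nichols frequencies faithfully (no extra founder drift)
    # while mosaic reuse of whole founder segments still creates LD.
    n_alt <- floor(K * pf) + (runif(spec$n_snps) < (K * pf) %% 1)
    u <- matrix(runif(K * spec$n_snps), nrow = K)
    founders <- 1L * (apply(u, 2, rank) <= rep(n_alt, each = K))
    if (pp == "POP_BRET") maj_ref <- as.numeric(colMeans(founders) >= 0.5)
    pfreq[, pp] <- pf
    cols <- which(popmap$population == pp)
    for (j in cols) {
      h <- integer(spec$n_snps)
      for (k in 1:2) {
        switches <- c(TRUE, runif(spec$n_snps - 1) < p_switch)
        seg <- cumsum(switches)
        fid <- sample.int(K, max(seg), replace = TRUE)
        path <- fid[seg]
        h <- h + founders[cbind(path, seq_len(spec$n_snps))]
      }
      geno[, j] <- h
    }
  }

  n_fail <- as.integer(round(spec$info_fail_fraction * spec$n_snps))
  fail_idx <- if (n_fail > 0) sample.int(spec$n_snps, n_fail) else integer(0)
  info_pass <- rep(TRUE, spec$n_snps)
  info_pass[fail_idx] <- FALSE
  n <- spec$n_snps
  sites <- data.table::data.table(
    chrom = "chr1", pos = pos,
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = NA_character_,
    QUAL = runif(n, 100, 1000), QD = runif(n, 5, 35),
    FS = runif(n, 0, 20), MQ = runif(n, 50, 60),
    MQRankSum = runif(n, -3, 3), ReadPosRankSum = runif(n, -3, 3))
  sites$alt <- vapply(sites$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  if (n_fail > 0) {
    which_crit <- sample(1:6, n_fail, replace = TRUE)
    for (i in seq_len(n_fail)) {
      s <- fail_idx[i]
      switch(which_crit[i],
             sites$MQRankSum[s] <- runif(1, -20, -13),
             sites$QUAL[s] <- runif(1, 1, 25),
             sites$QD[s] <- runif(1, 0, 1.5),
             sites$FS[s] <- runif(1, 70, 120),
             sites$MQ[s] <- runif(1, 20, 35),
             sites$ReadPosRankSum[s] <- runif(1, -12, -9))
    }
  }
  truth <- list(
    p_ancestral = p_anc, pop_freq = pfreq, positions = pos,
    sweep_center_bp = spec$sweep_center_bp,
    sweep_interval = c(spec$sweep_center_bp - spec$sweep_decay_length_bp,
                       spec$sweep_center_bp + spec$sweep_decay_length_bp),
    info_pass = info_pass,
    alt_count = rowSums(geno))
  list(variants = variant_table(sites, geno, popmap, n_dropped = 0L),
       popmap = popmap, truth = truth)
}

#' Simulate gene models, TF list and pathway annotation
#'
#' Non-overlapping gene models are tiled along one chromosome in gene-index
#' order, each with two exons whose union defines the exonic length. One
#' designated "TCA" gene and one "transporter" gene sit inside the sweep
#' interval (they are also planted in the acid-linked module with a variety
#' effect by [simulate_counts()]), so the full intersection has a known
#' positive. Remaining pathway labels go to genes far from the sweep.
#'
#' @param spec `simulation_spec`.
#' @param truth ground truth from [simulate_counts()].
#' @return list with `models` (`gene_models` data.frame), `tf_list`
#'   (data.frame gene_id, family), `pathway` (data.frame gene_id, pathway).
#' @export
simulate_annotations <- function(spec, truth) {
  set.seed(spec$rng_seed + 3L)
  lay <- truth$layout
  n_g <- spec$n_genes
  spacing <- lay$spacing
  if (spacing < 200) stop("genes do not fit on the chromosome")
  gene_id <- names(truth$module)
  start <- (seq_len(n_g) - 1L) * spacing + 1L
  glen <- sample(300:min(900, spacing - 50L), n_g, replace = TRUE)
  end <- start + glen - 1L
  # two exons per gene; exonic length = union of the two intervals
  e1_len <- pmax(50L, as.integer(round(glen * runif(n_g, 0.2, 0.5))))
  e2_len <- pmax(50L, as.integer(round(glen * runif(n_g, 0.2, 0.5))))
  e1 <- cbind(start, start + e1_len - 1L)
  e2 <- cbind(end - e2_len + 1L, end)
  exonic <- ifelse(e2[, 1] <= e1[, 2],
                   end - start + 1L,               # overlapping: union = span
                   e1_len + e2_len)
  models <- data.frame(
    gene_id = gene_id, chrom = "chr1", start = start, end = end,
    strand = rep(c("+", "-"), length.out = n_g),
    exonic_length_bp = as.integer(exonic), stringsAsFactors = FALSE)
  class(models) <- c("gene_models", "data.frame")

  center_idx <- c(lay$idx_tca, lay$idx_transporter)
  far <- which(abs((start + end) / 2 - spec$sweep_center_bp) >
                 2 * spec$sweep_decay_length_bp)
  far <- setdiff(far, c(center_idx, lay$idx_tf_amt, lay$idx_tf_dshs))
  other <- sample(far, 27)
  pathway <- data.frame(
    gene_id = c(gene_id[lay$idx_tca], gene_id[other[1:18]],
                gene_id[lay$idx_transporter], gene_id[other[19:27]]),
    pathway = c(rep("TCA", 19), rep("transporter", 10)),
    stringsAsFactors = FALSE)
  list(models = models, tf_list = truth$tf_genes,
       pathway = pathway, exons = list(e1 = e1, e2 = e2))
}

#' Write gene models (with exons) as GFF3
#'
#' @param ann result of [simulate_annotations()].
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  m <- ann$models
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(m))) {
    writeLines(sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       m$chrom[i], m$start[i], m$end[i], m$strand[i],
                       m$gene_id[i]), con)
    e1 <- ann$exons$e1[i, ]; e2 <- ann$exons$e2[i, ]
    writeLines(sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                       m$chrom[i], c(e1[1], e2[1]), c(e1[2], e2[2]),
                       m$strand[i], m$gene_id[i]), con)
  }
  invisible(path)
}

#' Write a variant table as VCF 4.2
#'
#' @param vt `variant_table`.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Qual by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQ rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read pos rank sum\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(vt$geno)), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  s <- vt$sites
  info <- sprintf("QD=%.2f;FS=%.2f;MQ=%.2f;MQRankSum=%.2f;ReadPosRankSum=%.2f",
                  s$QD, s$FS, s$MQ, s$MQRankSum, s$ReadPosRankSum)
  gt <- matrix(gt_code[vt$geno + 1L], nrow(vt$geno), ncol(vt$geno))
  gt[is.na(vt$geno)] <- "./."
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, sprintf("%.2f", s$QUAL),
                ".", info, "GT", apply(gt, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Generate and write the full synthetic input bundle
#'
#' Runs every generator with the spec's seed and writes counts.tsv,
#' samples.csv, traits.csv, genes.gff3, tfs.tsv, pathway.tsv, pop.map,
#' variants.vcf and ground_truth.json into `dir`.
#'
#' @param spec `simulation_spec`.
#' @param dir output directory (created if needed).
#' @return invisibly, the in-memory bundle (counts, meta, traits, variants,
#'   annotations, truth).
#' @export
simulate_dataset <- function(spec = simulation_spec(), dir = NULL) {
  cnt <- simulate_counts(spec)
  traits <- simulate_traits(spec, cnt$truth)
  gen <- simulate_genotypes(spec)
  ann <- simulate_annotations(spec, cnt$truth)
  truth <- c(cnt$truth, gen["truth"])
  bundle <- list(counts = cnt$counts, meta = cnt$meta, traits = traits,
                 variants = gen$variants, popmap = gen$popmap, ann = ann,
                 truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_counts(cnt$counts, file.path(dir, "counts.tsv"))
    data.table::fwrite(cnt$meta[, c("sample_id", "variety", "stage", "replicate")],
                       file.path(dir, "samples.csv"))
    data.table::fwrite(cbind(sample_id = rownames(traits), traits),
                       file.path(dir, "traits.csv"))
    write_gff3(ann, file.path(dir, "genes.gff3"))
    data.table::fwrite(ann$tf_list, file.path(dir, "tfs.tsv"), sep = "\t")
    data.table::fwrite(ann$pathway, file.path(dir, "pathway.tsv"), sep = "\t")
    data.table::fwrite(gen$popmap, file.path(dir, "pop.map"), sep = "\t",
                       col.names = FALSE)
    write_vcf(gen$variants, file.path(dir, "variants.vcf"))
    jsonlite::write_json(
      list(module = as.list(truth$module[truth$module > 0]),
           acid_module = truth$acid_module,
           de_genes = truth$de_genes,
           positives = as.list(truth$positives),
           sweep_interval = truth$sweep_interval),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(bundle)
}
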