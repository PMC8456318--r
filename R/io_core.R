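#' @import data.table
#' @importFrom stats cor cor.test median na.omit p.adjust pnorm prcomp pt
#'   quantile rbeta rbinom rexp rnbinom rnorm runif sd setNames var phyper
#'   hclust cutree as.dist dist
#' @importFrom utils head tail write.table read.table
NULL

VARIETIES <- c("AMT", "DSHS")
STAGES <- c("S1", "S2", "S3", "S4")
STAGE_DAFB <- c(S1 = 15L, S2 = 45L, S3 = 90L, S4 = 120L)
POPULATIONS <- c("POP_BRET", "POP_SINK", "WILD")

#' Sample metadata table
#'
#' Builds and validates the per-sample metadata used throughout the pipeline:
#' two varieties (AMT, the high-acid variety; DSHS, the low-acid variety),
#' four fruit developmental stages S1--S4 sampled at 15/45/90/120 days after
#' full bloom (DAFB), and numbered biological replicates.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param variety character, one of `"AMT"`, `"DSHS"` per sample.
#' @param stage character, one of `"S1".."S4"` per sample.
#' @param replicate integer replicate index (>= 1) per sample.
#' @return A `data.frame` of class `sample_meta` with columns
#'   `sample_id`, `variety`, `stage`, `replicate`, `dafb` and a
#'   `condition` column (`variety.stage`).
#' @export
sample_meta <- function(sample_id, variety, stage, replicate) {
  stopifnot(length(sample_id) == length(variety),
            length(sample_id) == length(stage),
            length(sample_id) == length(replicate))
  if (anyDuplicated(sample_id))
    stop("sample_id values must be unique")
  if (!all(variety %in% VARIETIES))
    stop("variety must be one of: ", paste(VARIETIES, collapse = ", "))
  if (!all(stage %in% STAGES))
    stop("stage must be one of: ", paste(STAGES, collapse = ", "))
  replicate <- as.integer(replicate)
  if (any(replicate < 1L)) stop("replicate must be >= 1")
  out <- data.frame(
    sample_id = as.character(sample_id),
    variety = variety, stage = stage, replicate = replicate,
    dafb = unname(STAGE_DAFB[stage]),
    condition = paste(variety, stage, sep = "."),
    stringsAsFactors = FALSE)
  class(out) <- c("sample_meta", "data.frame")
  out
}

#' Read sample metadata from CSV
#'
#' Expects columns `sample_id,variety,stage,replicate`.
#'
#' @param path CSV file path.
#' @return `sample_meta` data frame.
#' @export
read_sample_meta <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "sample_id"))
  need <- c("sample_id", "variety", "stage", "replicate")
  if (!all(need %in% names(dt)))
    stop("sample metadata must have columns: ", paste(need, collapse = ","))
  sample_meta(dt$sample_id, dt$variety, dt$stage, dt$replicate)
}

#' Count matrix container
#'
#' Genes x samples integer fragment counts plus per-sample total mapped
#' fragments (used as the FPKM denominator). Totals default to column sums,
#' i.e. all mapped fragments fall in annotated genes.
#'
#' @param counts integer matrix, rownames = gene ids, colnames = sample ids.
#' @param totals named numeric vector of total mapped fragments per sample;
#'   defaults to `colSums(counts)`.
#' @return list of class `count_matrix` with elements `counts`, `totals`.
#' @export
count_matrix <- function(counts, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene_id in counts")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  totals <- totals[colnames(counts)]
  if (anyNA(totals)) stop("totals missing for some samples")
  if (any(totals < colSums(counts) - 1e-6))
    stop("totals must be >= per-sample column sums over annotated genes")
  structure(list(counts = counts, totals = totals), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (median library %.2fM)\n",
              nrow(x$counts), ncol(x$counts), median(x$totals) / 1e6))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a gene-level fragment-count matrix (TSV)
#'
#' First column is `gene_id`, remaining columns are sample ids. Cells must be
#' non-negative integers. When `meta` is given, columns are checked against
#' and reordered to the metadata sample order.
#'
#' @param path TSV file path.
#' @param meta optional `sample_meta`; every metadata sample must be present,
#'   and unknown columns raise an error.
#' @param totals optional named totals vector (defaults to column sums).
#' @return `count_matrix`.
#' @export
read_counts <- function(path, meta = NULL, totals = NULL) {
  dt <- data.table::fread(path, header = TRUE, colClasses = list(character = 1))
  if (ncol(dt) < 2) stop("counts file needs gene_id plus >=1 sample column")
  gene_id <- dt[[1]]
  if (anyDuplicated(gene_id)) stop("duplicate gene_id rows in ", path)
  m <- as.matrix(dt[, -1, with = FALSE])
  if (!is.numeric(m) || any(is.na(m)) || any(m != round(m)) || any(m < 0))
    stop("counts file contains non-integer or negative cells")
  storage.mode(m) <- "integer"
  rownames(m) <- gene_id
  if (!is.null(meta)) {
    missing <- setdiff(meta$sample_id, colnames(m))
    if (length(missing))
      stop("samples in metadata absent from counts: ",
           paste(missing, collapse = ","))
    unknown <- setdiff(colnames(m), meta$sample_id)
    if (length(unknown))
      stop("count columns absent from metadata: ",
           paste(unknown, collapse = ","))
    m <- m[, meta$sample_id, drop = FALSE]
  }
  if (is.null(totals)) count_matrix(m) else count_matrix(m, totals)
}

#' Write a count matrix as TSV
#'
#' @param cm `count_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  dt <- data.table::data.table(gene_id = rownames(cm$counts))
  dt <- cbind(dt, data.table::as.data.table(cm$counts))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses `gene` and `exon` features (1-based inclusive coordinates per the
#' GFF3 standard; converted to 0-based half-open internally only for interval
#' arithmetic). The exonic length of a gene is the length of the union of its
#' exon intervals, overlaps merged; genes without exons fall back to the gene
#' span (logged via message).
#'
#' @param path GFF3 file path.
#' @return data.frame of class `gene_models` with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `exonic_length_bp`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  if (!length(genes)) stop("no gene features in ", path)
  gid <- genes$ID
  if (is.null(gid) || anyNA(gid)) stop("gene features must carry ID attributes")
  if (anyDuplicated(gid)) stop("duplicate gene IDs in ", path)
  exons <- gr[gr$type == "exon"]
  first_parent <- function(pl)
    vapply(as.list(pl), function(p) if (length(p)) p[[1]] else NA_character_, "")
  parent <- first_parent(exons$Parent)
  # exon Parent may point at an mRNA; map transcripts up to their gene
  mrna <- gr[gr$type %in% c("mRNA", "transcript")]
  if (length(mrna)) {
    tx2gene <- setNames(first_parent(mrna$Parent), mrna$ID)
    hit <- parent %in% names(tx2gene)
    parent[hit] <- tx2gene[parent[hit]]
  }
  exonic <- setNames(integer(length(gid)), gid)
  if (length(exons)) {
    keep <- parent %in% gid
    ex <- exons[keep]
    exl <- GenomicRanges::reduce(
      GenomicRanges::split(GenomicRanges::granges(ex), parent[keep]))
    lens <- sum(IRanges::width(exl))
    exonic[names(lens)] <- as.integer(lens)
  }
  noex <- exonic == 0L
  if (any(noex)) {
    message(sum(noex), " gene(s) without exons: using gene span as length")
    exonic[noex] <- GenomicRanges::width(genes)[noex]
  }
  out <- data.frame(
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    exonic_length_bp = unname(exonic[gid]),
    stringsAsFactors = FALSE)
  if (any(out$end < out$start)) stop("gene with end < start in ", path)
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Read a population map (TSV: individual_id, population)
#'
#' @param path TSV path without header or with header
#'   `individual_id<TAB>population`.
#' @return data.frame with columns `individual_id`, `population`.
#' @export
read_popmap <- function(path) {
  dt <- data.table::fread(path, header = FALSE, col.names = c("individual_id", "population"))
  if (identical(dt$individual_id[1], "individual_id")) dt <- dt[-1]
  popmap <- data.frame(individual_id = as.character(dt$individual_id),
                       population = as.character(dt$population),
                       stringsAsFactors = FALSE)
  validate_popmap(popmap)
  popmap
}

validate_popmap <- function(popmap) {
  if (anyDuplicated(popmap$individual_id))
    stop("individual assigned to more than one population")
  if (!all(popmap$population %in% POPULATIONS))
    stop("population labels must be in: ", paste(POPULATIONS, collapse = ", "))
  tab <- table(popmap$population)
  if (any(tab < 2)) stop("each population needs >= 2 individuals")
  invisible(popmap)
}

#' Read biallelic SNPs from a VCF into a variant table
#'
#' Keeps biallelic SNPs only (multi-allelic and indel records are dropped and
#' counted); genotypes are coded 0/1/2 alt-allele dosages with `NA` for
#' missing calls. QUAL and the INFO annotations QD, FS, MQ, MQRankSum and
#' ReadPosRankSum are retained when present so that GATK-style hard filtering
#' can be applied downstream.
#'
#' @param path VCF 4.x file (plain text or bgzipped).
#' @param popmap population map data frame (`individual_id`, `population`);
#'   every VCF individual must appear in it.
#' @return list of class `variant_table` with elements `sites` (data.table:
#'   chrom, pos, ref, alt, QUAL, QD, FS, MQ, MQRankSum, ReadPosRankSum),
#'   `geno` (sites x individuals integer matrix), `popmap`, and
#'   `n_dropped` (records removed as non-biallelic-SNP).
#' @export
read_vcf <- function(path, popmap) {
  validate_popmap(popmap)
  vcf <- VariantAnnotation::readVcf(path)
  if (!nrow(vcf)) stop("empty VCF: ", path)
  ind <- colnames(vcf)
  absent <- setdiff(ind, popmap$individual_id)
  if (length(absent))
    stop("VCF individuals missing from population map: ",
         paste(absent, collapse = ","))
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, nrow(vcf))
  alt1[n_alt == 1] <- as.character(unlist(altl[n_alt == 1]))
  keep <- n_alt == 1 & nchar(ref) == 1 & !is.na(alt1) & nchar(alt1) == 1 &
    alt1 %in% c("A", "C", "G", "T") & ref %in% c("A", "C", "G", "T")
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("no biallelic SNPs in ", path)
  vcf <- vcf[keep]
  gt <- VariantAnnotation::geno(vcf)$GT
  code <- matrix(NA_integer_, nrow(gt), ncol(gt),
                 dimnames = list(NULL, colnames(gt)))
  code[gt %in% c("0/0", "0|0")] <- 0L
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  code[gt %in% c("1/1", "1|1")] <- 2L
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  grab <- function(f) if (f %in% colnames(info)) as.numeric(info[[f]]) else rep(NA_real_, nrow(vcf))
  sites <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref[keep], alt = alt1[keep],
    QUAL = as.numeric(VariantAnnotation::qual(vcf)),
    QD = grab("QD"), FS = grab("FS"), MQ = grab("MQ"),
    MQRankSum = grab("MQRankSum"), ReadPosRankSum = grab("ReadPosRankSum"))
  variant_table(sites, code, popmap, n_dropped = n_dropped)
}

variant_table <- function(sites, geno, popmap, n_dropped = 0L) {
  stopifnot(nrow(sites) == nrow(geno))
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord]
  geno <- geno[ord, , drop = FALSE]
  structure(list(sites = sites, geno = geno, popmap = popmap,
                 n_dropped = as.integer(n_dropped)),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d SNPs x %d individuals (%d records dropped)\n",
              nrow(x$sites), ncol(x$geno), x$n_dropped))
  invisible(x)
}

#' Pipeline run configuration
#'
#' All tunable constants of the pipeline with their published defaults:
#' the WGCNA constants (soft power 14, unsigned TOM, minimum module size 40,
#' merge cut height 0.3), the DEG criteria (FPKM > 0.1, FDR < 0.05,
#' |log2FC| > 2), the mutual-rank edge filters (PCC >= 0.3, both directed
#' ranks <= 5), the windowed-scan geometry (10 kb windows, 1 kb step) and
#' the sweep percentile rules (top 5\% F_ST, top 1\% XP-CLR).
#'
#' @param ... name = value overrides of the defaults listed above.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    fpkm_min_expressed = 5,
    deg_fpkm_min = 0.1,
    deg_fdr_max = 0.05,
    deg_abs_lfc_min = 2,
    soft_power = 14,
    tom_type = "unsigned",
    min_module_size = 40L,
    merge_cut_height = 0.3,
    mr_pcc_min = 0.3,
    mr_rank_max = 5,
    window_bp = 10000L,
    step_bp = 1000L,
    min_snps_per_window = 3L,
    fst_top_fraction = 0.05,
    xpclr_top_fraction = 0.01,
    qc_pcc_min = 0.8,
    rng_seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ","))
  cfg[names(dots)] <- dots
  with(cfg, {
    stopifnot(fst_top_fraction > 0, fst_top_fraction < 1,
              xpclr_top_fraction > 0, xpclr_top_fraction < 1,
              window_bp >= step_bp, soft_power >= 1,
              tom_type == "unsigned")
  })
  structure(cfg, class = "run_config")
}

#' Read run configuration from a key: value file
#'
#' Accepts a flat YAML-style file (`key: value` per line, `#` comments).
#'
#' @param path file path.
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  parsed <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  do.call(run_config, setNames(parsed, keys))
}

#' Read an organic-acid trait table
#'
#' CSV with one row per sample and columns `sample_id,OA,MA,CA`
#' (contents in mg/g fresh weight).
#'
#' @param path CSV path.
#' @return data.frame with rownames = sample_id.
#' @export
read_traits <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "sample_id"))
  need <- c("sample_id", "OA", "MA", "CA")
  if (!all(need %in% names(dt)))
    stop("trait table must have columns: ", paste(need, collapse = ","))
  out <- as.data.frame(dt[, c("OA", "MA", "CA"), with = FALSE])
  rownames(out) <- dt$sample_id
  out
}
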