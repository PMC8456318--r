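#' GATK-style hard filtering of SNPs
#'
#' Drops a SNP iff any of: MQRankSum < -12.5, QUAL < 30, QD < 2.0,
#' FS > 60.0, MQ < 40.0, ReadPosRankSum < -8.0 (strict inequalities; a
#' missing annotation passes that criterion).
#'
#' @param vt `variant_table`.
#' @return list with `variants` (passing `variant_table`) and `filter_counts`
#'   (named integer vector per criterion plus `total_dropped`).
#' @export
hard_filter <- function(vt) {
  s <- vt$sites
  fails <- cbind(
    MQRankSum = !is.na(s$MQRankSum) & s$MQRankSum < -12.5,
    QUAL = !is.na(s$QUAL) & s$QUAL < 30,
    QD = !is.na(s$QD) & s$QD < 2.0,
    FS = !is.na(s$FS) & s$FS > 60.0,
    MQ = !is.na(s$MQ) & s$MQ < 40.0,
    ReadPosRankSum = !is.na(s$ReadPosRankSum) & s$ReadPosRankSum < -8.0)
  drop <- rowSums(fails) > 0
  counts <- c(colSums(fails), total_dropped = sum(drop))
  out <- variant_table(s[!drop], vt$geno[!drop, , drop = FALSE], vt$popmap,
                       n_dropped = vt$n_dropped)
  list(variants = out, filter_counts = counts)
}

pop_columns <- function(vt, pop) {
  ids <- vt$popmap$individual_id[vt$popmap$population == pop]
  ids <- intersect(colnames(vt$geno), ids)
  if (length(ids) < 2) stop("population ", pop, " needs >= 2 individuals")
  ids
}

pop_freq_stats <- function(geno_sub) {
  n <- rowSums(!is.na(geno_sub))                  # diploids with calls
  alt <- rowSums(geno_sub, na.rm = TRUE)
  het <- rowSums(geno_sub == 1L, na.rm = TRUE)
  list(n = n, p = ifelse(n > 0, alt / (2 * n), NA_real_),
       h = ifelse(n > 0, het / n, NA_real_))
}

#' Per-SNP Weir-Cockerham F_ST variance components
#'
#' Two-population Weir & Cockerham (1984) estimator from genotype counts:
#' returns the among-population (a), between-individual (b) and
#' within-individual (c) variance components and theta = a / (a + b + c).
#' Sites with fewer than two called diploids in either population, or with
#' a + b + c = 0 (monomorphic across both), are flagged undefined.
#'
#' @param vt `variant_table` (hard-filtered upstream).
#' @param pop_a,pop_b population labels from the popmap.
#' @return data.frame: chrom, pos, n_a, n_b, p_a, p_b, comp_a, comp_b,
#'   comp_c, theta, defined.
#' @export
wc_fst_per_snp <- function(vt, pop_a, pop_b) {
  ga <- vt$geno[, pop_columns(vt, pop_a), drop = FALSE]
  gb <- vt$geno[, pop_columns(vt, pop_b), drop = FALSE]
  sa <- pop_freq_stats(ga); sb <- pop_freq_stats(gb)
  r <- 2
  nbar <- (sa$n + sb$n) / r
  nc <- (r * nbar - (sa$n^2 + sb$n^2) / (r * nbar)) / (r - 1)
  pbar <- (sa$n * sa$p + sb$n * sb$p) / (r * nbar)
  s2 <- (sa$n * (sa$p - pbar)^2 + sb$n * (sb$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (sa$n * sa$h + sb$n * sb$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  tot <- a + b + cc
  defined <- sa$n >= 2 & sb$n >= 2 & is.finite(tot) & tot != 0
  theta <- ifelse(defined, a / tot, NA_real_)
  data.frame(chrom = vt$sites$chrom, pos = vt$sites$pos,
             n_a = sa$n, n_b = sb$n, p_a = sa$p, p_b = sb$p,
             comp_a = a, comp_b = b, comp_c = cc,
             theta = theta, defined = defined,
             stringsAsFactors = FALSE)
}

#' Sliding-window layout
#'
#' Windows start at 1, 1 + step, ... while the start does not exceed the
#' chromosome length; each window ends at min(start + window - 1, length).
#' Coordinates are 1-based inclusive.
#'
#' @param chrom_length_bp chromosome length.
#' @param window_bp window size (default 10 kb).
#' @param step_bp step (default 1 kb).
#' @return data.frame with `start`, `end`.
#' @export
make_windows <- function(chrom_length_bp, window_bp = 10000, step_bp = 1000) {
  starts <- seq(1, chrom_length_bp, by = step_bp)
  data.frame(start = starts,
             end = pmin(starts + window_bp - 1, chrom_length_bp))
}

window_index <- function(pos, windows) {
  # first/last SNP index per window over sorted positions
  lo <- findInterval(windows$start - 1L, pos) + 1L
  hi <- findInterval(windows$end, pos)
  cbind(lo = lo, hi = hi, n = pmax(hi - lo + 1L, 0L))
}

#' Windowed F_ST scan (ratio of sums)
#'
#' Window value = sum(a) / sum(a + b + c) over the defined SNPs falling in
#' the window ("weighted" Weir-Cockerham convention); windows with fewer
#' than `min_snps_per_window` defined SNPs are reported with value `NA`.
#'
#' @param snp_stats per-SNP table from [wc_fst_per_snp()] (single chromosome,
#'   sorted by position).
#' @param chrom_length_bp chromosome length.
#' @param window_bp,step_bp window geometry (defaults 10 kb / 1 kb).
#' @param min_snps_per_window minimum defined SNPs per window (default 3).
#' @return data.frame of class `genome_scan`: chrom, start, end, n_snps,
#'   value; attribute `statistic` = "FST".
#' @export
fst_windowed_scan <- function(snp_stats, chrom_length_bp, window_bp = 10000,
                              step_bp = 1000, min_snps_per_window = 3) {
  ss <- snp_stats[snp_stats$defined, ]
  windows <- make_windows(chrom_length_bp, window_bp, step_bp)
  csum_a <- cumsum(c(0, ss$comp_a))
  csum_t <- cumsum(c(0, ss$comp_a + ss$comp_b + ss$comp_c))
  wi <- window_index(ss$pos, windows)
  num <- csum_a[wi[, "hi"] + 1L] - csum_a[wi[, "lo"]]
  den <- csum_t[wi[, "hi"] + 1L] - csum_t[wi[, "lo"]]
  value <- ifelse(wi[, "n"] >= min_snps_per_window & den != 0,
                  num / den, NA_real_)
  out <- data.frame(chrom = if (nrow(ss)) ss$chrom[1] else "chr1",
                    start = windows$start, end = windows$end,
                    n_snps = wi[, "n"], value = value,
                    stringsAsFactors = FALSE)
  attr(out, "statistic") <- "FST"
  class(out) <- c("genome_scan", "data.frame")
  out
}

#' Cross-population composite-likelihood sweep score per window
#'
#' Surrogate XP-CLR statistic: object-population allele frequencies are
#' modelled as Normal(mu, omega p_ref (1 - p_ref)) truncated to [0, 1],
#' where under neutral drift mu = p_ref and under a sweep of strength c the
#' mean is pulled toward the locally major allele,
#' mu(c) = (1 - c) p_ref + c 1[p_ref >= 0.5]. The drift scale omega is
#' estimated genome-wide as the median of (p_obj - p_ref)^2 / (p_ref(1 -
#' p_ref)). The window score is 2 (max_c sum loglik - sum loglik at c = 0),
#' maximised over `c_grid` and floored at 0.
#'
#' @param vt `variant_table` (hard-filtered upstream).
#' @param ref_pop reference population (default "POP_BRET").
#' @param obj_pop object population under selection (default "POP_SINK").
#' @param chrom_length_bp chromosome length.
#' @param window_bp,step_bp,min_snps_per_window window geometry.
#' @param c_grid sweep-strength grid (default seq(0, 0.95, 0.05)).
#' @return `genome_scan` data.frame (statistic "XPCLR") with attribute
#'   `omega`.
#' @export
xpclr_window_score <- function(vt, ref_pop = "POP_BRET",
                               obj_pop = "POP_SINK", chrom_length_bp,
                               window_bp = 10000, step_bp = 1000,
                               min_snps_per_window = 3,
                               c_grid = seq(0, 0.95, by = 0.05)) {
  stopifnot(0 %in% c_grid)
  gr <- vt$geno[, pop_columns(vt, ref_pop), drop = FALSE]
  go <- vt$geno[, pop_columns(vt, obj_pop), drop = FALSE]
  p_ref <- pop_freq_stats(gr)$p
  p_obj <- pop_freq_stats(go)$p
  usable <- !is.na(p_ref) & !is.na(p_obj) & p_ref > 0 & p_ref < 1
  pos <- vt$sites$pos[usable]
  p_ref <- p_ref[usable]; p_obj <- p_obj[usable]
  v <- p_ref * (1 - p_ref)
  omega <- median((p_obj - p_ref)^2 / v)
  omega <- max(omega, 1e-6)
  sigma <- sqrt(omega * v)
  major <- as.numeric(p_ref >= 0.5)
  ll <- sapply(c_grid, function(cc) {
    mu <- (1 - cc) * p_ref + cc * major
    z <- pnorm(1, mu, sigma) - pnorm(0, mu, sigma)
    dnorm(p_obj, mu, sigma, log = TRUE) - log(pmax(z, 1e-300))
  })
  windows <- make_windows(chrom_length_bp, window_bp, step_bp)
  wi <- window_index(pos, windows)
  csum <- apply(ll, 2, function(col) cumsum(c(0, col)))
  wsum <- csum[wi[, "hi"] + 1L, , drop = FALSE] -
    csum[wi[, "lo"], , drop = FALSE]
  i0 <- which(c_grid == 0)
  score <- 2 * (apply(wsum, 1, max) - wsum[, i0])
  score <- pmax(score, 0)
  score[wi[, "n"] < min_snps_per_window] <- NA_real_
  out <- data.frame(chrom = vt$sites$chrom[1], start = windows$start,
                    end = windows$end, n_snps = wi[, "n"], value = score,
                    stringsAsFactors = FALSE)
  attr(out, "statistic") <- "XPCLR"
  attr(out, "omega") <- omega
  class(out) <- c("genome_scan", "data.frame")
  out
}

#' Linkage-disequilibrium decay curve
#'
#' r^2 is the squared Pearson correlation of genotype dosages between SNP
#' pairs up to `max_dist_bp` apart, averaged within distance bins.
#' Monomorphic SNPs (in the chosen population) are skipped.
#'
#' @param vt `variant_table`.
#' @param pop population label.
#' @param max_dist_bp maximum pair distance (default 300 kb).
#' @param bin_bp bin width (default 1 kb).
#' @return data.frame: bin_midpoint_bp, mean_r2, n_pairs.
#' @export
ld_decay <- function(vt, pop, max_dist_bp = 3e5, bin_bp = 1000) {
  g <- vt$geno[, pop_columns(vt, pop), drop = FALSE]
  pos <- vt$sites$pos
  sds <- apply(g, 1, sd)
  poly <- !is.na(sds) & sds > 0
  g <- g[poly, , drop = FALSE]
  pos <- pos[poly]
  if (nrow(g) < 2) return(data.frame(bin_midpoint_bp = numeric(0),
                                     mean_r2 = numeric(0),
                                     n_pairs = integer(0)))
  z <- t(scale(t(g)))  # standardise each SNP over individuals
  n <- ncol(g)
  nb <- ceiling(max_dist_bp / bin_bp)
  sum_r2 <- numeric(nb); n_pairs <- integer(nb)
  for (i in seq_len(nrow(g) - 1)) {
    jmax <- findInterval(pos[i] + max_dist_bp, pos)
    if (jmax <= i) next
    jr <- (i + 1):jmax
    r <- as.numeric(z[jr, , drop = FALSE] %*% z[i, ]) / (n - 1)
    bins <- pmin(nb, (pos[jr] - pos[i] - 1) %/% bin_bp + 1)
    agg <- rowsum(cbind(r^2, 1), bins)
    idx <- as.integer(rownames(agg))
    sum_r2[idx] <- sum_r2[idx] + agg[, 1]
    n_pairs[idx] <- n_pairs[idx] + agg[, 2]
  }
  keep <- n_pairs > 0
  data.frame(bin_midpoint_bp = (which(keep) - 0.5) * bin_bp,
             mean_r2 = sum_r2[keep] / n_pairs[keep],
             n_pairs = n_pairs[keep])
}

#' Half-decay distance of an LD curve
#'
#' Distance at which the binned mean r^2 first falls halfway from its
#' first-bin value toward its long-range baseline (the mean of the last 10\%
#' of bins, which absorbs the finite-sample r^2 floor of roughly 1/(n-1));
#' `Inf` if it never does within the curve.
#'
#' @param curve data.frame from [ld_decay()].
#' @return distance in bp.
#' @export
ld_half_decay <- function(curve) {
  if (!nrow(curve)) return(NA_real_)
  tail_n <- max(1L, ceiling(nrow(curve) * 0.1))
  baseline <- mean(tail(curve$mean_r2, tail_n))
  half <- baseline + (curve$mean_r2[1] - baseline) / 2
  below <- which(curve$mean_r2 <= half)
  if (!length(below)) return(Inf)
  curve$bin_midpoint_bp[below[1]]
}

#' Call sweep regions from a genome scan
#'
#' Threshold = nearest-rank (1 - top_fraction) order statistic over the
#' defined windows; windows at or above it are selected and merged when
#' overlapping or book-ended (zero gap).
#'
#' @param scan `genome_scan`.
#' @param top_fraction fraction of windows to take (0.05 for F_ST, 0.01 for
#'   XP-CLR).
#' @return list of class `sweep_regions`: `regions` (chrom, start, end,
#'   n_windows), `threshold`, `windows` (the selected windows),
#'   `statistic`.
#' @export
call_sweeps <- function(scan, top_fraction) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  def <- scan[!is.na(scan$value), , drop = FALSE]
  if (!nrow(def)) stop("all windows undefined")
  vals <- sort(def$value)
  k <- max(1L, floor(top_fraction * length(vals)))
  threshold <- vals[length(vals) - k + 1L]
  sel <- def[def$value >= threshold, , drop = FALSE]
  sel <- sel[order(sel$chrom, sel$start), ]
  regions <- list()
  for (ch in unique(sel$chrom)) {
    s <- sel[sel$chrom == ch, ]
    cur_start <- s$start[1]; cur_end <- s$end[1]; nwin <- 1L
    if (nrow(s) > 1) for (i in 2:nrow(s)) {
      if (s$start[i] <= cur_end + 1L) {
        cur_end <- max(cur_end, s$end[i]); nwin <- nwin + 1L
      } else {
        regions[[length(regions) + 1]] <-
          data.frame(chrom = ch, start = cur_start, end = cur_end,
                     n_windows = nwin, stringsAsFactors = FALSE)
        cur_start <- s$start[i]; cur_end <- s$end[i]; nwin <- 1L
      }
    }
    regions[[length(regions) + 1]] <-
      data.frame(chrom = ch, start = cur_start, end = cur_end,
                 n_windows = nwin, stringsAsFactors = FALSE)
  }
  structure(list(regions = do.call(rbind, regions), threshold = threshold,
                 windows = sel, statistic = attr(scan, "statistic")),
            class = "sweep_regions")
}

#' @export
print.sweep_regions <- function(x, ...) {
  cat(sprintf("sweep_regions (%s): %d regions, threshold %.4g\n",
              x$statistic, nrow(x$regions), x$threshold))
  invisible(x)
}

#' Genes overlapping sweep regions
#'
#' A gene is selected iff its [start, end] span overlaps any region by at
#' least 1 bp (1-based inclusive coordinates).
#'
#' @param models `gene_models` data.frame.
#' @param sweeps `sweep_regions`.
#' @return data.frame of selected genes with the first overlapping region's
#'   coordinates (`region_start`, `region_end`).
#' @export
genes_in_regions <- function(models, sweeps) {
  reg <- sweeps$regions
  hits <- list()
  for (i in seq_len(nrow(models))) {
    ov <- which(reg$chrom == models$chrom[i] &
                  reg$start <= models$end[i] & reg$end >= models$start[i])
    if (length(ov)) {
      hits[[length(hits) + 1]] <- data.frame(
        gene_id = models$gene_id[i], chrom = models$chrom[i],
        start = models$start[i], end = models$end[i],
        region_start = reg$start[ov[1]], region_end = reg$end[ov[1]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      region_start = integer(0), region_end = integer(0)))
  do.call(rbind, hits)
}
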