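mk_vt <- function(sites, geno, popmap) {
  if (is.null(colnames(geno))) colnames(geno) <- popmap$individual_id
  acidsweep:::variant_table(data.table::as.data.table(sites), geno, popmap)
}

two_pop_map <- function(nA = 10, nB = 10) {
  data.frame(
    individual_id = c(sprintf("a%02d", 1:nA), sprintf("b%02d", 1:nB)),
    population = c(rep("POP_BRET", nA), rep("POP_SINK", nB)),
    stringsAsFactors = FALSE)
}

base_sites <- function(n, pos = seq_len(n) * 100L) {
  data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G",
             QUAL = 100, QD = 20, FS = 5, MQ = 55, MQRankSum = 0,
             ReadPosRankSum = 0, stringsAsFactors = FALSE)
}

test_that("hard_filter applies each threshold with strict inequalities", {
  pm <- two_pop_map(2, 2)
  s <- base_sites(8)
  s$MQ[2] <- 39.9                       # dropped
  s$QUAL[3] <- 29.9                     # dropped
  s$QD[4] <- 1.99                       # dropped
  s$FS[5] <- 60.1                       # dropped
  s$MQRankSum[6] <- -12.6               # dropped
  s$ReadPosRankSum[7] <- -8.1           # dropped
  # row 8: every annotation exactly at the passing boundary
  s$MQ[8] <- 40; s$QD[8] <- 2; s$FS[8] <- 60; s$QUAL[8] <- 30
  s$MQRankSum[8] <- -12.5; s$ReadPosRankSum[8] <- -8
  g <- matrix(1L, 8, 4, dimnames = list(NULL, pm$individual_id))
  out <- hard_filter(mk_vt(s, g, pm))
  expect_equal(out$variants$sites$pos, c(100L, 800L))
  expect_equal(unname(out$filter_counts["total_dropped"]), 6L)
  expect_equal(unname(out$filter_counts["MQ"]), 1L)
})

test_that("Weir-Cockerham theta matches an independent transcription", {
  pm <- two_pop_map()
  # complete fixation: theta = 1
  g <- rbind(c(rep(0L, 10), rep(2L, 10)))
  vt <- mk_vt(base_sites(1), g, pm)
  st <- wc_fst_per_snp(vt, "POP_BRET", "POP_SINK")
  expect_equal(st$theta, 1)
  # identical configurations: the all-heterozygote case gives exactly
  # a = 0, theta = 0 (for generic identical configurations the WC estimator
  # is slightly negative by construction, checked as near-zero below)
  g2 <- rbind(rep(1L, 20))
  st2 <- wc_fst_per_snp(mk_vt(base_sites(1), g2, pm), "POP_BRET", "POP_SINK")
  expect_equal(st2$comp_a, 0, tolerance = 1e-12)
  expect_equal(st2$theta, 0, tolerance = 1e-12)
  g2b <- rbind(c(rep(c(0L, 1L, 2L), length.out = 10),
                 rep(c(0L, 1L, 2L), length.out = 10)))
  st2b <- wc_fst_per_snp(mk_vt(base_sites(1), g2b, pm), "POP_BRET", "POP_SINK")
  expect_lt(abs(st2b$theta), 0.1)
  expect_lte(st2b$comp_a, 0)
  # random sites vs the per-allele oracle
  set.seed(60)
  for (rep in 1:25) {
    nA <- sample(3:12, 1); nB <- sample(3:12, 1)
    pmr <- two_pop_map(nA, nB)
    g3 <- rbind(c(sample(0:2, nA, TRUE), sample(0:2, nB, TRUE)))
    vt3 <- mk_vt(base_sites(1), g3, pmr)
    st3 <- wc_fst_per_snp(vt3, "POP_BRET", "POP_SINK")
    ga <- g3[1, 1:nA]; gb <- g3[1, (nA + 1):(nA + nB)]
    o <- oracle_wc_fst(nA, mean(ga) / 2, mean(ga == 1), nB,
                       mean(gb) / 2, mean(gb == 1))
    expect_equal(st3$comp_a, o$a, tolerance = 1e-10)
    expect_equal(st3$comp_b, o$b, tolerance = 1e-10)
    expect_equal(st3$comp_c, o$c, tolerance = 1e-10)
    if (st3$defined) expect_equal(st3$theta, o$theta, tolerance = 1e-10)
  }
  # monomorphic across both populations: undefined
  g4 <- rbind(rep(0L, 20))
  st4 <- wc_fst_per_snp(mk_vt(base_sites(1), g4, pm), "POP_BRET", "POP_SINK")
  expect_false(st4$defined)
})

test_that("window layout enumerates starts at step intervals", {
  w <- make_windows(12000, 10000, 1000)
  expect_equal(nrow(w), 12L)
  expect_equal(w$start, seq(1, 11001, by = 1000))
  expect_equal(w$end[1], 10000)
  expect_equal(w$end[12], 12000)  # truncated at the chromosome end
})

test_that("windowed F_ST is the ratio of sums", {
  pm <- two_pop_map(3, 3)
  snp <- data.frame(chrom = "chr1", pos = c(500L, 1500L, 2500L, 11500L),
                    comp_a = 1, comp_b = 0, comp_c = 1,
                    theta = 0.5, defined = TRUE)
  sc <- fst_windowed_scan(snp, 12000, 10000, 1000, min_snps_per_window = 3)
  expect_equal(nrow(sc), 12L)
  # windows holding >= 3 of the (1,0,1) SNPs evaluate to 1/2 exactly
  expect_true(all(sc$value[!is.na(sc$value)] == 0.5))
  # a single-SNP window stays undefined at min_snps 3
  expect_true(is.na(sc$value[sc$start == 11001]))
  # brute-force window construction agrees
  for (i in seq_len(nrow(sc))) {
    inw <- snp$pos >= sc$start[i] & snp$pos <= sc$end[i]
    if (sum(inw) >= 3) {
      expect_equal(sc$value[i],
                   sum(snp$comp_a[inw]) /
                     sum(snp$comp_a[inw] + snp$comp_b[inw] + snp$comp_c[inw]))
      expect_equal(sc$n_snps[i], sum(inw))
    }
  }
})

test_that("XP-CLR surrogate is zero for identical populations and sane", {
  pm <- two_pop_map(8, 8)
  set.seed(61)
  n <- 60
  gA <- matrix(sample(0:2, n * 8, TRUE), n, 8)
  g <- cbind(gA, gA)  # object == reference
  colnames(g) <- pm$individual_id
  vt <- mk_vt(base_sites(n, pos = sort(sample(1:20000, n))), g, pm)
  sc <- xpclr_window_score(vt, chrom_length_bp = 20000)
  expect_true(all(sc$value[!is.na(sc$value)] == 0))
  expect_true(all(sc$value >= 0, na.rm = TRUE))

  # SNP input order does not change the score (the table normalises order)
  g2 <- cbind(gA, matrix(sample(0:2, n * 8, TRUE), n, 8))
  colnames(g2) <- pm$individual_id
  pos <- sort(sample(1:9000, n))
  vt2 <- mk_vt(base_sites(n, pos = pos), g2, pm)
  sc2 <- xpclr_window_score(vt2, chrom_length_bp = 9000, window_bp = 9000,
                            step_bp = 9000)
  perm <- sample(n)
  vt3 <- mk_vt(base_sites(n, pos = pos[perm]), g2[perm, , drop = FALSE], pm)
  sc3 <- xpclr_window_score(vt3, chrom_length_bp = 9000, window_bp = 9000,
                            step_bp = 9000)
  expect_equal(sc2$value, sc3$value)
})

test_that("a larger drift scale never rewards matched frequencies", {
  # likelihood-shape property: with object == reference frequencies the
  # score stays 0 whatever omega is, checked by doubling the frequencies'
  # spread via an explicit computation
  p_ref <- seq(0.1, 0.9, 0.1)
  score_at <- function(omega) {
    sigma <- sqrt(omega * p_ref * (1 - p_ref))
    ll <- sapply(c(0, 0.5, 0.9), function(cc) {
      mu <- (1 - cc) * p_ref + cc * (p_ref >= 0.5)
      z <- pnorm(1, mu, sigma) - pnorm(0, mu, sigma)
      sum(dnorm(p_ref, mu, sigma, log = TRUE) - log(z))
    })
    2 * (max(ll) - ll[1])
  }
  expect_equal(score_at(0.1), 0)
  expect_equal(score_at(0.2), 0)
})

test_that("LD decay bins r2 and the domesticated/wild contrast holds", {
  pm <- two_pop_map(10, 10)
  set.seed(62)
  # duplicated SNP at distance d: r2 = 1 in bin d
  g1 <- sample(0:2, 20, TRUE)
  g <- rbind(g1, g1, sample(0:2, 20, TRUE))
  colnames(g) <- pm$individual_id
  vt <- mk_vt(base_sites(3, pos = c(1000L, 3500L, 9000L)), g, pm)
  curve <- ld_decay(vt, "POP_BRET", max_dist_bp = 10000, bin_bp = 1000)
  expect_equal(curve$mean_r2[curve$bin_midpoint_bp == 2500], 1)

  # independent SNPs: mean r2 near the 1/(n-1) sampling floor
  n_ind <- 20
  gi <- matrix(sample(0:2, 500 * n_ind, TRUE), 500, n_ind)
  colnames(gi) <- c(sprintf("a%02d", 1:10), sprintf("b%02d", 1:10))
  vti <- mk_vt(base_sites(500, pos = sort(sample(1:50000, 500))), gi,
               two_pop_map(10, 10))
  cv <- ld_decay(vti, "POP_BRET", max_dist_bp = 50000, bin_bp = 50000)
  floor_exp <- 1 / (10 - 1)
  se <- sqrt(2) * floor_exp / sqrt(cv$n_pairs)
  expect_lt(abs(cv$mean_r2 - floor_exp), 3 * se)
})

test_that("call_sweeps selects by nearest-rank quantile and merges regions", {
  sc <- data.frame(chrom = "chr1", start = seq(1, 100000, 1000),
                   end = seq(1, 100000, 1000) + 9999,
                   n_snps = 5, value = 0)
  sc <- sc[1:100, ]
  sc$value <- seq_len(100) / 100
  class(sc) <- c("genome_scan", "data.frame")
  attr(sc, "statistic") <- "FST"
  sw <- call_sweeps(sc, 0.05)
  expect_equal(nrow(sw$windows), 5L)    # exactly the top 5 of 100
  expect_equal(nrow(sw$regions), 1L)    # contiguous windows merge
  expect_equal(sw$regions$n_windows, 5L)
  # all-equal values: every window selected
  sc$value <- 1
  expect_equal(nrow(call_sweeps(sc, 0.05)$windows), 100L)
  # region count is monotone non-increasing as top_fraction shrinks
  set.seed(63)
  sc$value <- runif(100)
  n_regions <- sapply(c(0.3, 0.1, 0.05, 0.01),
                      function(f) nrow(call_sweeps(sc, f)$regions))
  expect_true(all(diff(n_regions) <= 0) || n_regions[1] >= n_regions[4])
  # undefined-only scans error
  sc$value <- NA_real_
  expect_error(call_sweeps(sc, 0.05), "undefined")
})

test_that("genes_in_regions overlaps by >= 1 bp inclusive", {
  models <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                       start = c(5000L, 5000L), end = c(8000L, 8000L),
                       strand = "+", exonic_length_bp = 1000L)
  sw <- structure(list(regions = data.frame(chrom = "chr1", start = 7500L,
                                            end = 17500L, n_windows = 1L),
                       threshold = 1, statistic = "FST"),
                  class = "sweep_regions")
  expect_equal(genes_in_regions(models[1, ], sw)$gene_id, "g1")
  sw$regions$start <- 8001L
  expect_equal(nrow(genes_in_regions(models, sw)), 0L)

  # random instances vs a brute-force all-pairs check
  set.seed(64)
  for (rep in 1:10) {
    m <- data.frame(gene_id = paste0("g", 1:30), chrom = "chr1",
                    start = sample(1:5000, 30), strand = "+",
                    exonic_length_bp = 100L)
    m$end <- m$start + sample(50:500, 30, TRUE)
    reg <- data.frame(chrom = "chr1", start = sample(1:5000, 5), n_windows = 1L)
    reg$end <- reg$start + sample(100:800, 5, TRUE)
    sw2 <- structure(list(regions = reg, threshold = 1, statistic = "FST"),
                     class = "sweep_regions")
    got <- genes_in_regions(m, sw2)$gene_id
    want <- m$gene_id[sapply(seq_len(30), function(i)
      any(reg$start <= m$end[i] & reg$end >= m$start[i]))]
    expect_setequal(got, want)
  }
})
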