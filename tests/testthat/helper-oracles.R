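# Independent oracles: deliberately naive re-implementations used to check
# the package's vectorised code paths. Keep these loop-based and close to
# the defining formulas.

# topological overlap, straight from the definition
oracle_tom <- function(adj) {
  n <- nrow(adj)
  out <- matrix(NA_real_, n, n)
  k <- numeric(n)
  for (i in 1:n) k[i] <- sum(adj[i, -i])
  for (i in 1:n) for (j in 1:n) {
    if (i == j) { out[i, j] <- 1; next }
    num <- 0
    for (u in 1:n) if (u != i && u != j) num <- num + adj[i, u] * adj[u, j]
    out[i, j] <- (num + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
  }
  out
}

# mutual rank by exhaustive sorting
oracle_mr <- function(pcc) {
  n <- nrow(pcc)
  ranks <- matrix(NA_real_, n, n)
  for (i in 1:n) {
    others <- setdiff(1:n, i)
    r <- rank(-pcc[i, others], ties.method = "average")
    ranks[i, others] <- r
  }
  mr <- sqrt(ranks * t(ranks))
  diag(mr) <- NA
  mr
}

# Weir & Cockerham (1984) two-population theta, transcribed per allele
# (sums over both alleles, the full multi-allelic form reduced to 2 pops)
oracle_wc_fst <- function(nA, pA, hA, nB, pB, hB) {
  r <- 2
  nbar <- (nA + nB) / r
  C2 <- ((nA - nbar)^2 + (nB - nbar)^2) / ((r - 1) * nbar^2) # squared CV
  nc <- nbar * (1 - C2 / r * (r - 1))  # == (r nbar - sum n^2/(r nbar))/(r-1)
  comp <- function(freqA, freqB, hetA, hetB) {
    pbar <- (nA * freqA + nB * freqB) / (r * nbar)
    s2 <- (nA * (freqA - pbar)^2 + nB * (freqB - pbar)^2) / ((r - 1) * nbar)
    hbar <- (nA * hetA + nB * hetB) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    c <- hbar / 2
    c(a, b, c)
  }
  # sum components over the two alleles (heterozygosity identical for both)
  x <- comp(pA, pB, hA, hB) + comp(1 - pA, 1 - pB, hA, hB)
  list(a = x[1] / 2, b = x[2] / 2, c = x[3] / 2,
       theta = x[1] / (x[1] + x[2] + x[3]))
}

# interval union length by sweeping positions
oracle_union_length <- function(starts, ends) {
  pts <- sort(unique(unlist(Map(seq, starts, ends))))
  length(pts)
}

# adjusted Rand index from the contingency table
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  ex <- si * sj / choose(n, 2)
  if ((si + sj) / 2 - ex == 0) return(1)
  (sij - ex) / ((si + sj) / 2 - ex)
}

# Benjamini-Hochberg by the textbook step-up rule
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# small count fixture: blocks of correlated genes via shared factor
make_block_counts <- function(n_per_block = 50, n_blocks = 3, n_samples = 24,
                              rho = 0.8, seed = 1) {
  set.seed(seed)
  a <- 1
  e_sd <- a * sqrt((1 - rho) / rho)
  x <- do.call(rbind, lapply(seq_len(n_blocks), function(m) {
    f <- rnorm(n_samples)
    t(replicate(n_per_block, 8 + a * f + rnorm(n_samples, sd = e_sd)))
  }))
  rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%02d", seq_len(n_samples))
  list(expr = x, labels = rep(seq_len(n_blocks), each = n_per_block))
}

tiny_spec <- function(...) {
  simulation_spec(n_genes = 400L, module_sizes = c(60L, 50L, 40L),
                  n_de_genes = 20L, n_stage_de_genes = 20L, n_tf = 10L,
                  n_snps = 400L, chromosome_length_bp = 4e5,
                  sweep_center_bp = 2e5, ...)
}
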