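#' Soft-thresholded unsigned adjacency
#'
#' a_ij = |cor(x_i, x_j)|^beta on log2(FPKM + 1), diagonal 1. Zero-variance
#' genes are dropped with a warning.
#'
#' @param fpkm FPKM matrix restricted to the genes/samples of interest.
#' @param beta soft power (default 14).
#' @param log_transform apply log2(x + 1) first (default TRUE; set FALSE if
#'   the matrix is already on the analysis scale).
#' @return adjacency matrix with attribute `beta`.
#' @export
soft_adjacency <- function(fpkm, beta = 14, log_transform = TRUE) {
  if (ncol(fpkm) < 3) stop("need >= 3 samples")
  x <- if (log_transform) log2_fpkm(fpkm) else fpkm
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped")
    x <- x[sds > 0, , drop = FALSE]
  }
  adj <- abs(cor(t(x)))^beta
  diag(adj) <- 1
  attr(adj, "beta") <- beta
  adj
}

#' Topological overlap matrix (unsigned)
#'
#' omega_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) for
#' i != j, where k_i is the connectivity sum_u a_iu (u != i) and the
#' numerator sum excludes u in {i, j}; omega_ii = 1.
#'
#' @param adj adjacency matrix from [soft_adjacency()].
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(adj) {
  stopifnot(nrow(adj) == ncol(adj))
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a  # sum_u a_iu a_uj including u = i or j contributes 0 (diag 0)
  num <- num + a
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect co-expression modules from TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on 1 - TOM. The dendrogram is cut
#' at the merge height (scanned up to its 0.99 quantile) that yields the
#' largest number of clusters meeting `min_module_size` (ties broken toward
#' the lower height); clusters at least twice the minimum size are then
#' recursively re-clustered on their own subtree so that distinct modules
#' glued together by a single global cut are still separated (modules split
#' in the process are re-joined later by [merge_modules()]). Genes in
#' clusters below the size threshold are unassigned (label 0), then rescued
#' into the module whose eigengene they correlate with above
#' `reassign_cor_min`; a final margined module-membership pass relocates
#' genes another module's eigengene tracks decisively better.
#'
#' @param dissim TOM dissimilarity (1 - TOM) with gene dimnames.
#' @param expr expression matrix (genes x samples) on the analysis scale,
#'   used for eigengene-based rescue; pass NULL to skip rescue.
#' @param min_module_size minimum module size (default 40).
#' @param reassign_cor_min eigengene correlation needed to rescue an
#'   unassigned gene (default 0.3).
#' @return list of class `module_set`: `labels` (named integer; 0 =
#'   unassigned), `sizes`, `tree` (hclust).
#' @export
detect_modules <- function(dissim, expr = NULL, min_module_size = 40,
                           reassign_cor_min = 0.3) {
  genes <- rownames(dissim)
  n <- length(genes)
  if (n < min_module_size) {
    return(structure(list(labels = setNames(integer(n), genes),
                          sizes = integer(0), tree = NULL),
                     class = "module_set"))
  }
  best_cut <- function(d) {
    tree <- hclust(as.dist(d), method = "average")
    heights <- sort(unique(tree$height))
    heights <- heights[heights <= quantile(tree$height, 0.99)]
    best <- NULL; best_n <- -1L
    for (h in heights) {
      cl <- cutree(tree, h = h)
      ok <- sum(table(cl) >= min_module_size)
      if (ok > best_n) { best_n <- ok; best <- cl }
    }
    list(cl = best, n = best_n, tree = tree)
  }
  top <- best_cut(dissim)
  clusters <- list()
  recurse <- function(idx) {
    sub <- best_cut(dissim[idx, idx, drop = FALSE])
    parts <- split(idx, sub$cl)
    parts <- parts[lengths(parts) >= min_module_size]
    if (length(parts) < 2) {
      clusters[[length(clusters) + 1]] <<- idx
      return(invisible())
    }
    for (p in parts) {
      if (length(p) >= 2 * min_module_size && length(p) < length(idx))
        recurse(p)
      else clusters[[length(clusters) + 1]] <<- p
    }
  }
  for (p in split(seq_len(n), top$cl)) {
    if (length(p) < min_module_size) next
    if (length(p) >= 2 * min_module_size) recurse(p)
    else clusters[[length(clusters) + 1]] <- p
  }
  labels <- integer(n)
  ord <- order(-lengths(clusters))
  for (m in seq_along(ord)) labels[clusters[[ord[m]]]] <- m
  names(labels) <- genes
  tree <- top$tree
  if (!is.null(expr) && any(labels > 0L)) {
    # (1) rescue unassigned genes whose eigengene correlation clears the bar;
    # (2) module-membership consistency pass: a gene is moved only when
    # another module's eigengene tracks it decisively better (margin 0.2)
    # than its own (kME refinement; protects genes the height cut glued onto
    # an unrelated cluster without letting eigengene drift churn modules)
    kme_margin <- 0.2
    for (pass in 1:2) {
      eig <- module_eigengenes(expr, labels)
      cc <- cor(t(expr), eig$eigengenes)
      top <- max.col(cc)
      top_cor <- cc[cbind(seq_len(nrow(cc)), top)]
      new_lab <- as.integer(colnames(eig$eigengenes)[top])
      un <- labels == 0L
      labels[un & top_cor > reassign_cor_min] <-
        new_lab[un & top_cor > reassign_cor_min]
      cur_cor <- rep(NA_real_, length(labels))
      asg <- which(labels > 0L)
      cur_cor[asg] <- cc[cbind(asg, match(as.character(labels[asg]),
                                          colnames(eig$eigengenes)))]
      move <- labels > 0L & !is.na(cur_cor) &
        top_cor > cur_cor + kme_margin & new_lab != labels
      if (!any(move) ) break
      labels[move] <- new_lab[move]
    }
  }
  structure(list(labels = labels, sizes = table(labels[labels > 0L]),
                 tree = tree), class = "module_set")
}

# renumber clusters 1..m by decreasing size; undersized clusters -> 0
relabel_modules <- function(cl, min_module_size) {
  tab <- sort(table(cl), decreasing = TRUE)
  keep <- names(tab)[tab >= min_module_size]
  out <- integer(length(cl))
  for (m in seq_along(keep)) out[cl == as.integer(keep[m])] <- m
  out
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d modules (sizes %s), %d unassigned\n",
              length(x$sizes), paste(x$sizes, collapse = ","),
              sum(x$labels == 0L)))
  invisible(x)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right singular vector of the
#' per-gene z-scored module expression over samples, with its sign chosen so
#' the mean correlation with member genes is >= 0. Single-gene modules use
#' that gene's z-score.
#'
#' @param expr expression matrix (genes x samples) on the analysis scale.
#' @param labels named module labels (0 = unassigned, skipped).
#' @return list with `eigengenes` (samples x modules matrix, columns named by
#'   module label) and `var_explained` per module.
#' @export
module_eigengenes <- function(expr, labels) {
  mods <- sort(unique(labels[labels > 0L]))
  if (!length(mods)) stop("no modules")
  eig <- matrix(NA_real_, ncol(expr), length(mods),
                dimnames = list(colnames(expr), as.character(mods)))
  ve <- setNames(numeric(length(mods)), as.character(mods))
  for (i in seq_along(mods)) {
    g <- names(labels)[labels == mods[i]]
    z <- t(scale(t(expr[g, , drop = FALSE])))
    z <- z[rowSums(!is.finite(z)) == 0, , drop = FALSE]
    if (nrow(z) == 1L) {
      v <- as.numeric(z)
      ve[i] <- 1
    } else {
      sv <- svd(t(z), nu = 1, nv = 0)
      v <- sv$u[, 1]
      ve[i] <- sv$d[1]^2 / sum(sv$d^2)
    }
    if (mean(cor(v, t(z))) < 0) v <- -v
    eig[, i] <- v / sqrt(sum(v^2))
  }
  list(eigengenes = eig, var_explained = ve)
}

#' Merge modules with similar eigengenes
#'
#' Single-linkage clustering of modules on eigengene dissimilarity
#' 1 - cor; groups below `merge_cut_height` are merged, eigengenes
#' recomputed, and the procedure iterates to a fixed point.
#'
#' @param expr expression matrix (genes x samples).
#' @param labels named module labels.
#' @param merge_cut_height dissimilarity cut (default 0.3).
#' @return list with updated `labels` and `eigengenes`.
#' @export
merge_modules <- function(expr, labels, merge_cut_height = 0.3) {
  repeat {
    mods <- sort(unique(labels[labels > 0L]))
    eig <- module_eigengenes(expr, labels)
    if (length(mods) < 2) break
    d <- 1 - cor(eig$eigengenes)
    grp <- cutree(hclust(as.dist(d), method = "single"),
                  h = merge_cut_height)
    if (max(grp) == length(mods)) break
    new <- labels
    for (g in unique(grp)) {
      members <- mods[grp == g]
      new[labels %in% members] <- min(members)
    }
    # renumber contiguously by size
    tab <- sort(table(new[new > 0L]), decreasing = TRUE)
    remap <- setNames(seq_along(tab), names(tab))
    labels <- ifelse(new > 0L, remap[as.character(new)], 0L)
    names(labels) <- names(new)
    labels <- setNames(as.integer(labels), names(new))
  }
  list(labels = labels, eigengenes = module_eigengenes(expr, labels))
}

#' Module-trait and module-sample statistics
#'
#' Pearson correlations of each eigengene with each trait (plus Student-t
#' p-values) and with one-hot per-sample indicators; gene significance
#' GS (gene-trait correlation) and module membership MM (gene-eigengene
#' correlation) for every gene.
#'
#' @param eigengenes samples x modules matrix.
#' @param traits data.frame of traits (rows aligned to samples).
#' @param expr expression matrix (genes x samples).
#' @param labels named module labels.
#' @return list of class `module_trait_cor`: `trait_cor`, `trait_p`
#'   (traits x modules), `sample_cor` (modules x samples), `gs` (genes x
#'   traits), `mm` (genes x modules), `labels`, `sizes`.
#' @export
module_trait_stats <- function(eigengenes, traits, expr, labels) {
  stopifnot(nrow(traits) == nrow(eigengenes))
  tmat <- as.matrix(traits)
  const <- apply(tmat, 2, sd) == 0
  if (any(const)) {
    warning("constant trait(s) flagged undefined: ",
            paste(colnames(tmat)[const], collapse = ","))
  }
  n <- nrow(eigengenes)
  trait_cor <- suppressWarnings(cor(eigengenes, tmat))
  tstat <- trait_cor * sqrt((n - 2) / pmax(1 - trait_cor^2, 1e-12))
  trait_p <- 2 * pt(-abs(tstat), n - 2)
  onehot <- diag(n)
  dimnames(onehot) <- list(rownames(eigengenes), rownames(eigengenes))
  sample_cor <- cor(eigengenes, onehot)  # modules x samples
  gs <- suppressWarnings(cor(t(expr), tmat))
  mm <- cor(t(expr), eigengenes)
  sizes <- table(labels[labels > 0L])
  structure(list(trait_cor = t(trait_cor), trait_p = t(trait_p),
                 sample_cor = sample_cor, gs = gs, mm = mm,
                 labels = labels, sizes = sizes),
            class = "module_trait_cor")
}

#' Select the key module per trait
#'
#' The key module for a trait is the one maximising |module-trait PCC|;
#' ties break toward the smaller p-value, then the larger module.
#'
#' @param mt `module_trait_cor` from [module_trait_stats()].
#' @return named character vector trait -> module label.
#' @export
select_key_modules <- function(mt) {
  mods <- colnames(mt$trait_cor)
  if (!length(mods)) stop("no modules")
  sizes <- as.integer(mt$sizes[mods])
  out <- vapply(rownames(mt$trait_cor), function(tr) {
    ac <- abs(mt$trait_cor[tr, ])
    pv <- mt$trait_p[tr, ]
    ord <- order(-ac, pv, -sizes)
    mods[ord[1]]
  }, "")
  out
}
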