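#' Pearson correlation matrix over one variety's samples
#'
#' @param fpkm FPKM matrix restricted to expressed genes.
#' @param samples sample ids of the variety (>= 3).
#' @param log_transform apply log2(x + 1) first (default TRUE).
#' @return symmetric PCC matrix; zero-variance genes are excluded with a
#'   warning.
#' @export
pcc_matrix <- function(fpkm, samples = colnames(fpkm), log_transform = TRUE) {
  if (length(samples) < 3) stop("need >= 3 samples")
  x <- fpkm[, samples, drop = FALSE]
  if (log_transform) x <- log2_fpkm(x)
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) excluded from PCC matrix")
    x <- x[sds > 0, , drop = FALSE]
  }
  cor(t(x))
}

#' Mutual-rank matrix from a PCC matrix
#'
#' rank_AB is B's position when A's partners are ordered by decreasing PCC
#' (best partner rank 1; self excluded; PCC ties receive average ranks).
#' MR_AB = sqrt(rank_AB x rank_BA), symmetric, with MR = 1 iff A and B are
#' mutually best partners.
#'
#' @param pcc symmetric PCC matrix.
#' @return MR matrix (diagonal NA) with attribute `ranks` (the directed rank
#'   matrix, rows = source gene).
#' @export
mutual_rank <- function(pcc) {
  stopifnot(nrow(pcc) == ncol(pcc))
  n <- nrow(pcc)
  ranks <- matrix(NA_real_, n, n, dimnames = dimnames(pcc))
  for (i in seq_len(n)) {
    v <- pcc[i, -i]
    ranks[i, -i] <- rank(-v, ties.method = "average")
  }
  mr <- sqrt(ranks * t(ranks))
  diag(mr) <- NA_real_
  attr(mr, "ranks") <- ranks
  mr
}

#' Build a TF-candidate mutual-rank network
#'
#' Retains TF-candidate edges with PCC >= `mr_pcc_min` and both directed
#' ranks <= `mr_rank_max`; MR is stored as edge weight. Ranks are computed
#' over the full gene universe of `pcc` (they depend on universe size).
#'
#' @param mr MR matrix from [mutual_rank()].
#' @param pcc matching PCC matrix.
#' @param tf_list character vector of TF gene ids present in the matrix.
#' @param candidates character vector of candidate gene ids (non-empty).
#' @param mr_pcc_min minimum PCC (default 0.3).
#' @param mr_rank_max maximum directed rank (default 5).
#' @param include_tf_tf also keep TF-TF edges (default FALSE).
#' @param variety optional context label.
#' @return list of class `mr_network`: `edges` (node_a, node_b, pcc, rank_ab,
#'   rank_ba, mr), `tfs` (TFs with >= 1 retained edge), `candidates`,
#'   `variety`.
#' @export
build_trn <- function(mr, pcc, tf_list, candidates, mr_pcc_min = 0.3,
                      mr_rank_max = 5, include_tf_tf = FALSE,
                      variety = NA_character_) {
  genes <- rownames(pcc)
  tf_list <- intersect(tf_list, genes)
  candidates <- intersect(candidates, genes)
  if (!length(candidates)) stop("no candidate genes present in matrix")
  ranks <- attr(mr, "ranks")
  pairs <- expand.grid(node_a = tf_list,
                       node_b = if (include_tf_tf) union(candidates, tf_list)
                                else candidates,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$node_a != pairs$node_b, ]
  ia <- match(pairs$node_a, genes); ib <- match(pairs$node_b, genes)
  pairs$pcc <- pcc[cbind(ia, ib)]
  pairs$rank_ab <- ranks[cbind(ia, ib)]
  pairs$rank_ba <- ranks[cbind(ib, ia)]
  pairs$mr <- mr[cbind(ia, ib)]
  keep <- pairs$pcc >= mr_pcc_min & pairs$rank_ab <= mr_rank_max &
    pairs$rank_ba <= mr_rank_max
  edges <- pairs[keep, , drop = FALSE]
  # undirected de-duplication for TF-TF pairs
  if (include_tf_tf && nrow(edges)) {
    key <- ifelse(edges$node_a < edges$node_b,
                  paste(edges$node_a, edges$node_b),
                  paste(edges$node_b, edges$node_a))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  rownames(edges) <- NULL
  structure(list(edges = edges, tfs = sort(unique(edges$node_a)),
                 candidates = candidates, variety = variety),
            class = "mr_network")
}

#' @export
print.mr_network <- function(x, ...) {
  cat(sprintf("mr_network (%s): %d edges, %d TFs, %d candidates\n",
              x$variety, nrow(x$edges), length(x$tfs), length(x$candidates)))
  invisible(x)
}

#' Compare two variety networks
#'
#' @param net_a,net_d `mr_network`s built over the same TF universe.
#' @param tf_families optional data.frame (gene_id, family) for per-family
#'   histograms.
#' @return list with `shared_tfs`, `unique_a`, `unique_d`, and (when
#'   families are given) `family_counts_a`, `family_counts_d`.
#' @export
network_comparison <- function(net_a, net_d, tf_families = NULL) {
  out <- list(shared_tfs = intersect(net_a$tfs, net_d$tfs),
              unique_a = setdiff(net_a$tfs, net_d$tfs),
              unique_d = setdiff(net_d$tfs, net_a$tfs))
  if (!is.null(tf_families)) {
    fam <- function(tfs) {
      f <- tf_families$family[match(tfs, tf_families$gene_id)]
      sort(table(f), decreasing = TRUE)
    }
    out$family_counts_a <- fam(net_a$tfs)
    out$family_counts_d <- fam(net_d$tfs)
  }
  out
}
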