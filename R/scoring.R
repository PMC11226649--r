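# Per-cell signature scoring (rank-based and control-bin), one-vs-rest
# marker derivation, and the macrophage cluster-selection rule.

#' Rank-based per-cell signature score
#'
#' UCell-style statistic: within each cell, all genes of the matrix are
#' ranked by decreasing expression (ties get average ranks), ranks beyond
#' `r_max` are capped at `r_max + 1`, and the score is
#' `max(0, 1 - U / (n * r_max))` where `U = sum(ranks of signature genes) -
#' n(n+1)/2` is the Mann-Whitney U of the signature genes against the rest
#' and `n` is the number of signature genes present. Scores lie in \[0, 1\],
#' equal 1 exactly when the signature genes occupy the top ranks, and are
#' invariant to any strictly monotone transform of a cell's expression
#' vector (so raw, log-normalized or spatial expression all give the same
#' score).
#'
#' @param expr Cells x genes expression matrix (the log-normalized layer by
#'   convention).
#' @param sig A [gene_signature] or character vector of genes.
#' @param r_max Rank cap (default 1500, the published default of the
#'   rank-based scorer).
#' @return Named numeric vector of scores, one per cell.
#' @export
rank_cell_scores <- function(expr, sig, r_max = 1500) {
  stopifnot(r_max >= 1)
  expr <- as_dense_expr(expr)
  genes <- match_signature_genes(sig_genes(sig), colnames(expr), sig_name(sig))
  n <- length(genes)
  sig_idx <- match(genes, colnames(expr))
  scores <- apply(expr, 1L, function(x) {
    r <- rank(-x, ties.method = "average")
    r <- pmin(r, r_max + 1)
    u <- sum(r[sig_idx]) - n * (n + 1) / 2
    max(0, 1 - u / (n * r_max))
  })
  stats::setNames(as.numeric(scores), rownames(expr))
}

#' Control-bin module score
#'
#' Reimplementation of the standard module score: genes are binned into
#' `n_bins` equal-count bins by their average expression over all cells; for
#' each signature gene, `n_ctrl` control genes are drawn (with replacement)
#' from its bin; the score of a cell is the mean expression of the signature
#' genes minus the mean over the pooled control draws. Deterministic given
#' `seed` (controls are drawn per signature gene, in signature order).
#'
#' @inheritParams rank_cell_scores
#' @param n_bins Number of expression bins (reduced with a warning when there
#'   are fewer genes than bins).
#' @param n_ctrl Control genes drawn per signature gene.
#' @param seed Integer seed for the control draws.
#' @return Named numeric vector of scores (centred near 0; unbounded).
#' @export
module_score <- function(expr, sig, n_bins = 24, n_ctrl = 100, seed = 1L) {
  stopifnot(n_bins >= 1, n_ctrl >= 1)
  expr <- as_dense_expr(expr)
  genes <- match_signature_genes(sig_genes(sig), colnames(expr), sig_name(sig))
  n_genes <- ncol(expr)
  if (n_genes < n_bins) {
    warnf("fewer genes (%d) than bins (%d); using %d bins", n_genes, n_bins, n_genes)
    n_bins <- n_genes
  }
  avg <- colMeans(expr)
  bin <- ceiling(rank(avg, ties.method = "first") * n_bins / n_genes)
  names(bin) <- colnames(expr)
  ctrl <- local_seed(seed, {
    unlist(lapply(genes, function(g) {
      members <- colnames(expr)[bin == bin[g]]
      sample(members, n_ctrl, replace = TRUE)
    }))
  })
  sig_mean <- rowMeans(expr[, genes, drop = FALSE])
  ctrl_mean <- rowMeans(expr[, ctrl, drop = FALSE])  # duplicates keep weight
  stats::setNames(sig_mean - ctrl_mean, rownames(expr))
}

#' One-vs-rest marker genes and top-10 cluster signatures
#'
#' For each cluster, genes expressed in at least `min_pct` of the cluster's
#' cells and with log2 fold change of at least `min_log2fc` (computed from
#' expm1 means of the log-normalized values with pseudocount 1) are tested
#' with a two-sided Wilcoxon rank-sum test against all other cells.
#' Benjamini-Hochberg correction is applied across the tested genes within
#' each cluster, and the cluster's signature is the top `n_top` genes by
#' log2 fold change among those with q < 0.05.
#'
#' @param expr Cells x genes log-normalized matrix.
#' @param cells Data.frame with `cell_id` and `cluster` columns aligned to
#'   `expr` rows.
#' @param n_top Signature size (default 10).
#' @param min_pct Minimum expressing fraction within the cluster.
#' @param min_log2fc Minimum log2 fold change.
#' @return List with `markers` (data.frame: cluster, gene, log2fc, p, q,
#'   pct_in, pct_out) and `signatures` (named list of [gene_signature] with
#'   `own_cluster` set).
#' @export
derive_cluster_signatures <- function(expr, cells, n_top = 10, min_pct = 0.1,
                                      min_log2fc = 0.25) {
  expr <- as_dense_expr(expr)
  cl <- cells$cluster[match(rownames(expr), cells$cell_id)]
  if (anyNA(cl)) stopf("all expr rows must have a cluster annotation")
  tab <- table(cl)
  usable <- names(tab)[tab >= 3]
  skipped <- setdiff(names(tab), usable)
  if (length(skipped))
    warnf("clusters with <3 cells skipped: %s", paste(skipped, collapse = ", "))
  if (length(usable) < 2) stopf("need >=2 clusters with >=3 cells")

  res <- list(); sigs <- list()
  for (k in usable) {
    in_k <- cl == k
    stats_k <- wilcox_markers(expr, in_k, min_pct, min_log2fc)
    if (nrow(stats_k) == 0) {
      warnf("cluster %s: no genes pass the pct/log2fc filters", k)
      next
    }
    stats_k$q <- bh_adjust(stats_k$p)
    stats_k <- cbind(cluster = k, stats_k, stringsAsFactors = FALSE)
    res[[k]] <- stats_k
    hit <- stats_k[stats_k$q < 0.05, , drop = FALSE]
    hit <- hit[order(-hit$log2fc), , drop = FALSE]
    n_sig <- min(n_top, nrow(hit))
    if (n_sig < n_top)
      warnf("cluster %s: only %d significant genes for a top-%d signature",
            k, n_sig, n_top)
    if (n_sig > 0)
      sigs[[k]] <- gene_signature(k, hit$gene[seq_len(n_sig)], own_cluster = k)
  }
  markers <- if (length(res)) do.call(rbind, res) else
    data.frame(cluster = character(0), gene = character(0), log2fc = numeric(0),
               p = numeric(0), q = numeric(0), pct_in = numeric(0),
               pct_out = numeric(0))
  rownames(markers) <- NULL
  list(markers = markers, signatures = sigs)
}

# Vectorized one-vs-rest Wilcoxon rank-sum (normal approximation with tie
# correction) over the columns of expr, restricted to genes passing the
# fold-change and expression-fraction filters.
wilcox_markers <- function(expr, in_group, min_pct, min_log2fc) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  pct_in <- colMeans(expr[in_group, , drop = FALSE] > 0)
  pct_out <- colMeans(expr[!in_group, , drop = FALSE] > 0)
  mean_in <- colMeans(expm1(expr[in_group, , drop = FALSE]))
  mean_out <- colMeans(expm1(expr[!in_group, , drop = FALSE]))
  log2fc <- log2(mean_in + 1) - log2(mean_out + 1)
  keep <- which(pct_in >= min_pct & log2fc >= min_log2fc)
  if (length(keep) == 0)
    return(data.frame(gene = character(0), log2fc = numeric(0), p = numeric(0),
                      pct_in = numeric(0), pct_out = numeric(0)))
  p <- vapply(keep, function(j) {
    r <- rank(expr[, j])
    w <- sum(r[in_group])                      # rank sum of the cluster
    mu <- n1 * (n + 1) / 2
    ties <- table(expr[, j])
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (w - mu) / sqrt(sigma2)
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
  data.frame(gene = colnames(expr)[keep], log2fc = log2fc[keep], p = p,
             pct_in = pct_in[keep], pct_out = pct_out[keep],
             stringsAsFactors = FALSE)
}

#' Mean score per group
#'
#' @param scores Named numeric vector of per-cell scores.
#' @param cells Data.frame with `cell_id` and the grouping column.
#' @param group_by Name of the grouping column (default `"cluster"`).
#' @return Data.frame (group, mean_score) ordered by descending mean.
#' @export
cluster_mean_scores <- function(scores, cells, group_by = "cluster") {
  g <- cells[[group_by]][match(names(scores), cells$cell_id)]
  if (anyNA(g)) stopf("all scored cells must appear in `cells`")
  m <- tapply(scores, g, mean)
  out <- data.frame(group = names(m), mean_score = as.numeric(m),
                    stringsAsFactors = FALSE)
  out[order(-out$mean_score), , drop = FALSE]
}

#' Select macrophage (TAM) clusters by the one-standard-deviation rule
#'
#' A cluster is selected when its mean per-cell macrophage-signature score
#' exceeds the dataset-wide mean by more than `k_sd` standard deviations of
#' the per-cell scores (strict inequality). With zero score variance nothing
#' is selected.
#'
#' @param scores Named per-cell score vector (e.g. from
#'   [rank_cell_scores()]).
#' @param cells Data.frame with `cell_id` and `cluster`.
#' @param k_sd Number of standard deviations above the mean (default 1).
#' @return List with `selected` (character vector of cluster labels),
#'   `threshold`, `dataset_mean`, `dataset_sd` and `cluster_means`.
#' @export
select_tam_clusters <- function(scores, cells, k_sd = 1.0) {
  if (length(scores) < 2) stopf("need >=2 scored cells")
  mu <- mean(scores); sd_all <- stats::sd(scores)
  if (sd_all == 0) warnf("score standard deviation is 0; nothing selected")
  thr <- mu + k_sd * sd_all
  cm <- cluster_mean_scores(scores, cells, "cluster")
  sel <- cm$group[cm$mean_score > thr]
  list(selected = sel, threshold = thr, dataset_mean = mu,
       dataset_sd = sd_all, cluster_means = cm)
}
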