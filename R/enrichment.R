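# Covariate-adjusted gene ranking for a binary response, and preranked
# gene-set enrichment (running-sum statistic with a gene-permutation null).

#' Rank genes by association with a binary response, adjusting for a covariate
#'
#' Genes with nonzero counts in at least 20% of samples are kept. Counts are
#' converted to log2-CPM with pseudocount 0.5, fitted by least squares on
#' `~ covariate + response`, and the response coefficient is converted to a
#' moderated t statistic using [squeeze_variances()] across genes. The
#' returned ranking is sorted by decreasing statistic; ties keep stable
#' input order.
#'
#' @param counts Samples x genes count matrix.
#' @param response Binary labels (factor or character), named by sample or
#'   aligned to rows; the second factor level is the "positive" direction.
#' @param covariate Covariate labels (e.g. cancer type), same alignment.
#' @param min_frac_nonzero Detection filter (default 0.2).
#' @return Data.frame (gene, statistic) sorted by decreasing statistic.
#' @export
rank_genes <- function(counts, response, covariate,
                       min_frac_nonzero = 0.2) {
  counts <- as.matrix(counts)
  align <- function(v) {
    if (!is.null(names(v)) && !is.null(rownames(counts))) v[rownames(counts)] else v
  }
  response <- factor(align(response))
  covariate <- factor(align(covariate))
  if (nlevels(response) != 2) stopf("response must have exactly 2 levels")
  if (any(table(response) < 3)) stopf("need >=3 samples per response group")

  keep <- colMeans(counts > 0) >= min_frac_nonzero
  counts <- counts[, keep, drop = FALSE]
  if (ncol(counts) == 0) stopf("no genes pass the detection filter")

  lib <- rowSums(counts)
  logcpm <- log2((counts + 0.5) / (lib + 1) * 1e6)

  X <- stats::model.matrix(~ covariate + response)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stopf("design is confounded: response is not estimable given the covariate")
  fit <- stats::lm.fit(X, logcpm)
  df_res <- nrow(X) - ncol(X)
  if (df_res < 1) stopf("no residual degrees of freedom")
  s2 <- colSums(fit$residuals^2) / df_res
  s2 <- pmax(s2, 1e-300)
  sq <- squeeze_variances(s2, df_res)
  xtxi <- chol2inv(qr.R(qrX))
  c_resp <- xtxi[ncol(X), ncol(X)]
  beta <- fit$coefficients[ncol(X), ]
  tstat <- beta / sqrt(sq$s2_post * c_resp)

  ord <- order(-tstat)  # stable: ties keep input (column) order
  data.frame(gene = colnames(counts)[ord], statistic = as.numeric(tstat[ord]),
             stringsAsFactors = FALSE)
}

as_ranked_vector <- function(ranked) {
  if (is.data.frame(ranked)) {
    v <- stats::setNames(ranked$statistic, ranked$gene)
  } else v <- ranked
  if (anyNA(v)) stopf("ranking contains NA")
  if (anyDuplicated(names(v))) stopf("duplicate genes in ranking")
  v[order(-v)]  # stable sort keeps input order on ties
}

#' Gene-set enrichment score (running sum)
#'
#' Walks the ranking from top to bottom; at a signature gene ("hit") the
#' running sum increases by `|r|^weight_exp` normalized over hits, at a miss
#' it decreases by `1/(N - N_hits)`. The enrichment score is the running-sum
#' value of maximal absolute deviation from zero (signed). ES is in
#' \[-1, 1\]: +1 when the signature occupies the top of the ranking, -1 when
#' it occupies the bottom.
#'
#' @param ranked Named statistic vector or data.frame (gene, statistic);
#'   sorted internally by decreasing statistic.
#' @param sig A [gene_signature] or character vector; must hit at least one
#'   ranked gene and not cover the whole ranking.
#' @param weight_exp Weighting exponent on |statistic| (default 1).
#' @return List with `es` and `running_sum` (named by ranked genes).
#' @export
gsea_es <- function(ranked, sig, weight_exp = 1) {
  r <- as_ranked_vector(ranked)
  genes <- sig_genes(sig)
  hits <- names(r) %in% genes
  n_hits <- sum(hits); n <- length(r)
  if (n_hits == 0) stopf("signature has no genes in the ranking")
  if (n_hits == n) stopf("signature covers the entire ranking")
  w <- abs(r)^weight_exp
  inc <- ifelse(hits, w / sum(w[hits]), -1 / (n - n_hits))
  rs <- cumsum(inc)
  list(es = signed_extreme(rs), running_sum = rs)
}

# Signed maximal deviation of a running sum. A tied positive/negative
# extreme (possible with exact rational increments) resolves to the positive
# side; the tolerance absorbs order-of-summation floating noise.
signed_extreme <- function(rs) {
  max_p <- max(rs); min_p <- min(rs)
  tol <- 1e-9 * (max_p - min_p + 1e-300)
  if (max_p + min_p >= -tol) max_p else min_p
}

#' Permutation p-value and normalized enrichment score
#'
#' The null distribution of the enrichment score is generated from random
#' gene sets of the same size drawn from the ranking. The p-value is
#' one-tailed in the direction of the observed ES over sign-matched null
#' scores, with the +1 permutation floor: `p = (1 + #{sign-matched |null| >=
#' |ES|}) / (1 + #sign-matched)`. `NES = ES / mean(|null ES| of matching
#' sign)`; when no sign-matched permutation exists NES is `NaN` with a
#' warning. Deterministic given `seed`.
#'
#' @inheritParams gsea_es
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return Data.frame row: signature, size, es, nes, p, n_perm,
#'   leading_edge (comma-separated genes).
#' @export
gsea_permutation <- function(ranked, sig, n_perm = 10000, seed = 1L,
                             weight_exp = 1) {
  stopifnot(n_perm >= 100)
  r <- as_ranked_vector(ranked)
  genes <- sig_genes(sig)
  obs <- gsea_es(r, genes, weight_exp)
  n <- length(r)
  n_hits <- sum(names(r) %in% genes)
  w <- abs(r)^weight_exp
  miss_dec <- -1 / (n - n_hits)
  null_es <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      hit_idx <- sample.int(n, n_hits)
      inc <- rep(miss_dec, n)
      inc[hit_idx] <- w[hit_idx] / sum(w[hit_idx])
      signed_extreme(cumsum(inc))
    }, numeric(1))
  })
  matched <- null_es * sign(obs$es) > 0
  n_match <- sum(matched)
  p <- (1 + sum(abs(null_es[matched]) >= abs(obs$es))) / (1 + n_match)
  if (n_match == 0) {
    warnf("no sign-matched permutations for '%s'; NES undefined", sig_name(sig))
    nes <- NaN
    p <- 1 / (n_perm + 1)
  } else {
    nes <- obs$es / mean(abs(null_es[matched]))
  }
  peak <- if (obs$es >= 0) which.max(obs$running_sum) else
    which.min(obs$running_sum)
  le <- if (obs$es >= 0) {
    intersect(names(r)[seq_len(peak)], genes)
  } else {
    intersect(names(r)[peak:n], genes)
  }
  data.frame(signature = sig_name(sig), size = n_hits, es = obs$es,
             nes = nes, p = p, n_perm = n_perm,
             leading_edge = paste(le, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Run a panel of signatures through preranked GSEA
#'
#' @inheritParams gsea_permutation
#' @param signatures Named list of signatures (unique names required).
#' @return Data.frame of [gsea_permutation()] rows sorted by decreasing NES,
#'   with BH q-values across the panel.
#' @export
run_gsea_panel <- function(ranked, signatures, n_perm = 10000, seed = 1L,
                           weight_exp = 1) {
  if (length(signatures) == 0) stopf("empty signature panel")
  nm <- names(signatures) %||% vapply(signatures, sig_name, character(1))
  if (anyDuplicated(nm)) stopf("duplicate signature names in panel")
  res <- do.call(rbind, lapply(seq_along(signatures), function(i) {
    s <- signatures[[i]]
    if (!inherits(s, "gene_signature")) s <- gene_signature(nm[i], s)
    gsea_permutation(ranked, s, n_perm = n_perm, seed = seed + i - 1L,
                     weight_exp = weight_exp)
  }))
  res$q <- bh_adjust(res$p)
  res[order(-res$nes), , drop = FALSE]
}
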