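# Independent brute-force oracles. These deliberately avoid the package's
# code paths (no rank(), no cumsum tricks shared with the implementation)
# so agreement is informative.

# Rank-capped signature score computed from first principles: the rank of a
# gene is 1 + (number of strictly larger genes) + half the ties among the
# rest, capped at r_max + 1.
oracle_rank_score <- function(x, sig_idx, r_max) {
  n_genes <- length(x)
  r <- numeric(n_genes)
  for (j in seq_len(n_genes)) {
    larger <- sum(x > x[j])
    ties <- sum(x == x[j]) - 1
    r[j] <- min(1 + larger + ties / 2, r_max + 1)
  }
  n <- length(sig_idx)
  u <- sum(r[sig_idx]) - n * (n + 1) / 2
  max(0, 1 - u / (n * r_max))
}

# Running-sum enrichment score by explicit walk.
oracle_es <- function(stat_sorted, is_hit, weight_exp = 1) {
  n <- length(stat_sorted)
  nh <- sum(is_hit)
  denom_hit <- sum(abs(stat_sorted[is_hit])^weight_exp)
  rs <- 0; max_p <- 0; min_p <- 0
  for (i in seq_len(n)) {
    if (is_hit[i]) {
      rs <- rs + abs(stat_sorted[i])^weight_exp / denom_hit
    } else {
      rs <- rs - 1 / (n - nh)
    }
    if (rs > max_p) max_p <- rs
    if (rs < min_p) min_p <- rs
  }
  # tied extremes resolve to the positive side (tolerance for float noise)
  if (max_p + min_p >= -1e-9 * (max_p - min_p + 1e-300)) max_p else min_p
}

# k nearest neighbours of point i by full sort of explicit distances,
# breaking ties at the k-th distance by row order.
oracle_knn_ids <- function(x, y, i, k) {
  d <- sqrt((x - x[i])^2 + (y - y[i])^2)
  ord <- order(d, seq_along(d))
  ord <- ord[ord != i]
  ord[seq_len(k)]
}

# Complete-linkage agglomeration by direct search over the current distance
# matrix, labels merged lexicographically.
oracle_complete_linkage <- function(d) {
  labs <- rownames(d)
  active <- as.list(labs)
  dm <- d
  merges <- list()
  while (length(active) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a >= b) next
      h <- max(d[active[[a]], active[[b]]])
      if (h < best_h - 1e-12) { best_h <- h; best <- c(a, b) }
    }
    merged <- sort(c(active[[best[1]]], active[[best[2]]]))
    merges[[length(merges) + 1]] <- list(members = merged, height = best_h)
    active <- c(active[-best], list(merged))
  }
  merges
}

# Small aligned expression fixture: named cells/genes with given matrix.
toy_expr <- function(values, n_cells, n_genes,
                     cells = sprintf("c%02d", seq_len(n_cells)),
                     genes = sprintf("g%02d", seq_len(n_genes))) {
  matrix(values, n_cells, n_genes, dimnames = list(cells, genes))
}
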