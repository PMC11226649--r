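# Score-threshold subset assignment and k-nearest-neighbour cell-type
# composition for spatial cell tables.

#' Assign spatial subset membership by score thresholds
#'
#' Strict threshold semantics: score > `hi` is a member of the subset,
#' score < `lo` is a non-member, anything in between (including scores equal
#' to either threshold) is unassigned and excluded from composition
#' analyses.
#'
#' @param scores Named numeric score vector (e.g. rank-based signature
#'   scores).
#' @param hi Membership threshold (default 0.8).
#' @param lo Non-membership threshold (default 0.4); must be < `hi`.
#' @return Named character vector in `{"member", "nonmember", "unassigned"}`.
#' @export
assign_by_threshold <- function(scores, hi = 0.8, lo = 0.4) {
  if (lo >= hi) stopf("lo (%g) must be strictly less than hi (%g)", lo, hi)
  out <- rep("unassigned", length(scores))
  out[scores > hi] <- "member"
  out[scores < lo] <- "nonmember"
  stats::setNames(out, names(scores))
}

#' Neighbourhood composition by k nearest neighbours
#'
#' For every focal cell, its `k` nearest cells by Euclidean distance in the
#' plane (self excluded; ties at the k-th distance broken by table order of
#' `cell_id`) are collected, and the pooled neighbour labels are normalized
#' to fractions. Pooling counts (rather than averaging per-cell fractions)
#' weights dense regions naturally.
#'
#' @param cells Data.frame with `cell_id`, `x`, `y` and a label column.
#' @param focal Logical vector / index / character cell_ids designating the
#'   focal subset (non-empty).
#' @param k Number of neighbours (default 5); must satisfy `k < nrow(cells)`.
#' @param label_col Name of the label column (default `"celltype"`).
#' @return List with `composition` (named fractions summing to 1), `counts`
#'   (pooled neighbour counts), `n_focal` and `k`.
#' @export
knn_composition <- function(cells, focal, k = 5, label_col = "celltype") {
  stopifnot(k >= 1)
  n <- nrow(cells)
  if (n <= k) stopf("need more than k = %d cells", k)
  if (is.character(focal)) focal <- cells$cell_id %in% focal
  if (is.numeric(focal)) focal <- seq_len(n) %in% focal
  if (!any(focal)) stopf("focal subset is empty")
  labs <- cells[[label_col]]
  x <- cells$x; y <- cells$y
  if (any(!is.finite(x)) || any(!is.finite(y))) stopf("coordinates must be finite")

  fidx <- which(focal)
  pooled <- table(factor(character(0), levels = unique(labs)))
  for (i in fidx) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    d2[i] <- Inf                               # self excluded
    ord <- order(d2, seq_len(n))               # k-th ties: table (cell_id) order
    nb <- ord[seq_len(k)]
    pooled <- pooled + table(factor(labs[nb], levels = names(pooled)))
  }
  total <- sum(pooled)
  list(composition = stats::setNames(as.numeric(pooled) / total, names(pooled)),
       counts = stats::setNames(as.integer(pooled), names(pooled)),
       n_focal = length(fidx), k = k)
}

#' Sensitivity sweep of the neighbourhood composition over k
#'
#' @inheritParams knn_composition
#' @param ks Values of k to sweep (default `c(1, 5, 10, 20)`).
#' @return Data.frame with columns k, label, fraction, count.
#' @export
knn_sweep <- function(cells, focal, ks = c(1, 5, 10, 20),
                      label_col = "celltype") {
  do.call(rbind, lapply(ks, function(k) {
    comp <- knn_composition(cells, focal, k = k, label_col = label_col)
    data.frame(k = k, label = names(comp$counts),
               fraction = comp$composition, count = comp$counts,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}
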