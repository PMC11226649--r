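# Signature-specificity metrics in an all-cell-type atlas, and the
# gold-standard gate.

#' Specificity metrics for cluster signatures
#'
#' For each signature, per-cluster mean scores over all cells give
#' `metric1`, the margin between the best and second-best cluster mean
#' (0 when the top two tie), and `best_hit_overall`, the best-scoring
#' cluster. Repeating the best-hit comparison within each cancer type gives
#' `metric2`, the number of cancer types whose best-hit cluster equals the
#' signature's own cluster (a tie for best hit within a cancer type counts
#' as no match).
#'
#' @param score_list Named list: signature name -> named per-cell score
#'   vector (e.g. from [rank_cell_scores()]).
#' @param cells Data.frame with `cell_id`, `cluster` and `cancer_type`.
#' @param own_cluster Named character vector mapping signature name to its
#'   own cluster; alternatively taken from `gene_signature` objects via
#'   `attr`. Required for every signature scored.
#' @return Data.frame with one row per signature: signature, own_cluster,
#'   metric1, metric2, n_cancer_types, best_hit_overall.
#' @export
specificity_metrics <- function(score_list, cells, own_cluster) {
  stopifnot(is.list(score_list), !is.null(names(score_list)))
  missing <- setdiff(names(score_list), names(own_cluster))
  if (length(missing))
    stopf("own_cluster mapping missing for: %s", paste(missing, collapse = ", "))
  cancers <- unique(cells$cancer_type)
  out <- lapply(names(score_list), function(sg) {
    sc <- score_list[[sg]]
    own <- own_cluster[[sg]]
    if (!own %in% cells$cluster)
      stopf("own cluster '%s' of signature '%s' absent from the data", own, sg)
    idx <- match(names(sc), cells$cell_id)
    if (anyNA(idx)) stopf("scored cells missing from `cells` for '%s'", sg)
    cl <- cells$cluster[idx]; ca <- cells$cancer_type[idx]

    pooled <- sort(tapply(sc, cl, mean), decreasing = TRUE)
    tied <- length(pooled) > 1 && pooled[1] == pooled[2]
    metric1 <- if (length(pooled) > 1 && !tied) as.numeric(pooled[1] - pooled[2]) else 0
    best_overall <- if (tied) NA_character_ else names(pooled)[1]

    metric2 <- sum(vapply(cancers, function(cc) {
      in_c <- ca == cc
      if (!any(in_c)) return(FALSE)
      m <- sort(tapply(sc[in_c], cl[in_c], mean), decreasing = TRUE)
      if (length(m) > 1 && m[1] == m[2]) return(FALSE)  # tie: no match
      names(m)[1] == own
    }, logical(1)))
    data.frame(signature = sg, own_cluster = own, metric1 = metric1,
               metric2 = metric2, n_cancer_types = length(cancers),
               best_hit_overall = best_overall, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Gate gold-standard signatures
#'
#' A signature is gold standard when its own cluster is the best hit in at
#' least `m2_min` cancer types, its pooled best/second-best margin is
#' strictly greater than `m1_min`, and the pooled best hit is its own
#' cluster.
#'
#' @param records Data.frame from [specificity_metrics()].
#' @param m1_min Strict lower threshold on metric1 (default 0.1).
#' @param m2_min Minimum number of matching cancer types (default 3).
#' @return `records` with a logical `gold_standard` column appended.
#' @export
gate_gold_standard <- function(records, m1_min = 0.1, m2_min = 3) {
  records$gold_standard <- records$metric2 >= m2_min &
    records$metric1 > m1_min &
    !is.na(records$best_hit_overall) &
    records$best_hit_overall == records$own_cluster
  records
}
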