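# Synthetic multi-study single-cell atlas with planted clusters, markers,
# batch effects and condition-dependent sample compositions.

#' Configuration for the single-cell atlas simulator
#'
#' Defaults emulate a small multi-study tumour-macrophage atlas: several
#' studies, a handful of samples each, negative-binomial counts with
#' overdispersion typical of droplet scRNA-seq, disjoint marker blocks per
#' cluster, gene-wise multiplicative study batch factors, and Dirichlet
#' sample compositions (concentration 10 per cluster) optionally shifted per
#' condition.
#'
#' @param n_studies Number of studies (batches).
#' @param n_samples_per_study Samples per study.
#' @param n_clusters Number of planted cell clusters.
#' @param n_genes Number of genes.
#' @param cells_per_sample Length-2 integer range; cell counts per sample are
#'   drawn uniformly from it.
#' @param markers_per_cluster Marker genes planted per cluster (disjoint
#'   blocks).
#' @param marker_log2fc Log2 fold change of marker-gene means in their own
#'   cluster (>= 0).
#' @param batch_sd SD of the per-study, per-gene log-normal batch factor
#'   (`0` disables batch effects).
#' @param nb_dispersion Negative-binomial dispersion: variance =
#'   mu + mu^2 * dispersion.
#' @param baseline_mean Baseline mean count per gene per cell.
#' @param condition_effects Named list: condition -> named numeric vector of
#'   log2 shifts of the Dirichlet concentration for specific clusters
#'   (cluster labels are `C1..Ck`). `NULL` means a single "control" condition.
#' @param seed Integer seed; the simulation is deterministic given the seed.
#' @return A classed config list.
#' @export
sc_sim_config <- function(n_studies = 3, n_samples_per_study = 4,
                          n_clusters = 6, n_genes = 500,
                          cells_per_sample = c(100L, 200L),
                          markers_per_cluster = 10, marker_log2fc = 2,
                          batch_sd = 0.2, nb_dispersion = 0.5,
                          baseline_mean = 0.5, condition_effects = NULL,
                          seed = 1L) {
  cfg <- list(n_studies = as.integer(n_studies),
              n_samples_per_study = as.integer(n_samples_per_study),
              n_clusters = as.integer(n_clusters),
              n_genes = as.integer(n_genes),
              cells_per_sample = as.integer(cells_per_sample),
              markers_per_cluster = as.integer(markers_per_cluster),
              marker_log2fc = marker_log2fc, batch_sd = batch_sd,
              nb_dispersion = nb_dispersion, baseline_mean = baseline_mean,
              condition_effects = condition_effects, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_studies >= 1, n_samples_per_study >= 1, n_clusters >= 1,
              n_genes >= 1, markers_per_cluster >= 0, marker_log2fc >= 0,
              batch_sd >= 0, nb_dispersion > 0, baseline_mean > 0,
              length(cells_per_sample) == 2, all(cells_per_sample >= 1),
              cells_per_sample[1] <= cells_per_sample[2])
  })
  if (cfg$markers_per_cluster * cfg$n_clusters > cfg$n_genes)
    stopf("markers_per_cluster x n_clusters (%d) exceeds n_genes (%d)",
          cfg$markers_per_cluster * cfg$n_clusters, cfg$n_genes)
  if (!is.null(condition_effects)) {
    stopifnot(is.list(condition_effects), !is.null(names(condition_effects)))
    bad <- unlist(lapply(condition_effects, function(e)
      setdiff(names(e), paste0("C", seq_len(cfg$n_clusters)))))
    if (length(bad)) stopf("condition_effects name unknown clusters: %s",
                           paste(unique(bad), collapse = ", "))
  }
  class(cfg) <- "sc_sim_config"
  cfg
}

#' Simulate a multi-study single-cell atlas
#'
#' Counts are negative binomial with gene-level mean `baseline_mean`,
#' multiplied by `2^marker_log2fc` for the marker genes of a cell's cluster
#' and by a per-study, per-gene log-normal batch factor. Per-sample cluster
#' compositions are Dirichlet(10 * 2^shift) draws; conditions cycle over the
#' samples of each study so that conditions are balanced across studies.
#'
#' @param config A [sc_sim_config()].
#' @return List with `counts` (sparse cells x genes), `cells` (data.frame:
#'   cell_id, study, sample, patient, cancer_type, tissue, cluster) and
#'   `truth` (cluster_of_cell, marker_genes, sample_condition,
#'   planted_enriched_clusters).
#' @export
simulate_sc_atlas <- function(config) {
  stopifnot(inherits(config, "sc_sim_config"))
  c0 <- config
  local_seed(c0$seed, {
    clusters <- paste0("C", seq_len(c0$n_clusters))
    genes <- sprintf("gene%04d", seq_len(c0$n_genes))
    marker_genes <- list()
    if (c0$markers_per_cluster > 0) {
      for (k in seq_len(c0$n_clusters)) {
        idx <- ((k - 1L) * c0$markers_per_cluster + 1L):(k * c0$markers_per_cluster)
        marker_genes[[clusters[k]]] <- genes[idx]
      }
    }

    conditions <- names(c0$condition_effects) %||% "control"
    alpha0 <- rep(10, c0$n_clusters)
    names(alpha0) <- clusters

    # per-study per-gene multiplicative batch factor
    batch <- matrix(exp(stats::rnorm(c0$n_studies * c0$n_genes, 0, c0$batch_sd)),
                    nrow = c0$n_studies)

    rows <- list(); mats <- list()
    samp_cond <- character(0)
    cell_counter <- 0L
    for (s in seq_len(c0$n_studies)) {
      study <- sprintf("study%02d", s)
      for (j in seq_len(c0$n_samples_per_study)) {
        sample_id <- sprintf("%s_s%02d", study, j)
        cond <- conditions[((j - 1L) %% length(conditions)) + 1L]
        samp_cond[sample_id] <- cond
        alpha <- alpha0
        if (!is.null(c0$condition_effects)) {
          eff <- c0$condition_effects[[cond]]
          if (length(eff)) alpha[names(eff)] <- alpha[names(eff)] * 2^eff
        }
        comp <- as.numeric(rdirichlet1(alpha))
        rng <- c0$cells_per_sample
        n_cells <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
        cl <- sample(clusters, n_cells, replace = TRUE, prob = comp)
        mu <- matrix(c0$baseline_mean, n_cells, c0$n_genes)
        if (c0$markers_per_cluster > 0 && c0$marker_log2fc > 0) {
          for (k in seq_len(c0$n_clusters)) {
            in_k <- cl == clusters[k]
            if (any(in_k)) {
              gi <- match(marker_genes[[clusters[k]]], genes)
              mu[in_k, gi] <- mu[in_k, gi] * 2^c0$marker_log2fc
            }
          }
        }
        mu <- sweep(mu, 2L, batch[s, ], `*`)
        cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                     size = 1 / c0$nb_dispersion),
                      nrow = n_cells)
        ids <- sprintf("cell%07d", cell_counter + seq_len(n_cells))
        cell_counter <- cell_counter + n_cells
        rownames(cnt) <- ids
        mats[[sample_id]] <- cnt
        rows[[sample_id]] <- data.frame(
          cell_id = ids, study = study, sample = sample_id,
          patient = sub("_s", "_p", sample_id),
          cancer_type = sprintf("cancer%02d", s),  # one cancer type per study
          tissue = "tumour", cluster = cl, stringsAsFactors = FALSE)
      }
    }
    counts <- as_sparse(do.call(rbind, mats))
    colnames(counts) <- genes
    cells <- do.call(rbind, rows)
    rownames(cells) <- NULL

    planted <- lapply(c0$condition_effects %||% list(), function(e)
      names(e)[e > 0])
    truth <- list(
      cluster_of_cell = stats::setNames(cells$cluster, cells$cell_id),
      marker_genes = marker_genes,
      sample_condition = samp_cond,
      planted_enriched_clusters = planted)
    list(counts = counts, cells = cells, truth = truth)
  })
}

# One Dirichlet draw via normalized gammas.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}
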