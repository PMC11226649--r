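#!/usr/bin/env Rscript
# Stage 7: cluster co-occurrence across samples (Spearman), ordination of
# samples by composition (PCoA on Euclidean distances), similarity of
# clusters by mean expression (complete-linkage dendrogram, Newick), and
# marker-percentile membership profiles.

library(tamtools)

ds <- read_dataset("scratch/sim/sc/matrix.mtx", "scratch/sim/sc/cells.csv")
ln <- lognormalize(ds$counts)
pr <- sample_cluster_proportions(ds$cells)

rho <- spearman_cooccurrence(pr$props)
utils::write.csv(rho, "results/07_cooccurrence_spearman.csv")

emb <- pcoa(as.matrix(stats::dist(pr$props)), n_axes = 2)
utils::write.csv(data.frame(sample = rownames(emb$points), emb$points),
                 "results/07_pcoa_samples.csv", row.names = FALSE)
cat(sprintf("PCoA: first two axes carry %.0f%% of the positive inertia\n",
            100 * sum(emb$eig[1:2]) / sum(emb$eig[emb$eig > 0])))

hc <- hierarchical_cluster_means(ln, ds$cells)
if (requireNamespace("ape", quietly = TRUE)) {
  ape::write.tree(ape::as.phylo(hc), "results/07_cluster_dendrogram.nwk")
}

# percentile membership of each cluster's top planted marker
truth <- jsonlite::fromJSON("scratch/sim/sc_truth.json")
marks <- vapply(truth$marker_genes, `[`, character(1), 1)
pm_rows <- lapply(names(marks), function(k) {
  pm <- suppressWarnings(
    marker_percentile_membership(ln, ds$cells, marks[[k]], n_bins = 20))
  data.frame(marker = marks[[k]], own_cluster = k,
             bin = seq_len(nrow(pm)),
             own_fraction = pm[, k], row.names = NULL)
})
pm_tab <- do.call(rbind, pm_rows)
utils::write.csv(pm_tab, "results/07_marker_percentiles.csv", row.names = FALSE)
top_bin <- pm_tab[pm_tab$bin == 20, ]
cat("Own-cluster fraction among top-percentile expressors of each marker:\n")
print(top_bin[, c("marker", "own_cluster", "own_fraction")])
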