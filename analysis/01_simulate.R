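#!/usr/bin/env Rscript
# Stage 1: generate the three synthetic datasets that drive the workflow.
#
# * a multi-study single-cell macrophage atlas with 6 planted clusters,
#   10 markers each, study batch effects, and a composition shift of
#   cluster C3 in the "case" condition (emulating an enriched TAM subset);
# * a bulk immunotherapy cohort (responders vs non-responders across three
#   cancer types) in which responders up-regulate one signature;
# * a spatial table with two disjoint niches: ECM-macrophages co-located
#   with fibroblasts, IFNG-macrophages with T cells.
#
# Large intermediates go to scratch/sim/ (regenerated on demand); a small
# summary lands in results/.

library(tamtools)

out_data <- "scratch/sim"; out_res <- "results"
dir.create(out_data, recursive = TRUE, showWarnings = FALSE)
dir.create(out_res, recursive = TRUE, showWarnings = FALSE)

## single-cell atlas -------------------------------------------------------
sc_cfg <- sc_sim_config(
  n_studies = 3, n_samples_per_study = 8, n_clusters = 6, n_genes = 300,
  cells_per_sample = c(150, 250), markers_per_cluster = 10,
  marker_log2fc = 2, batch_sd = 0.2,
  condition_effects = list(ctrl = c(), case = c(C3 = 1.5)), seed = 101)
sc <- simulate_sc_atlas(sc_cfg)
write_dataset(sc$counts, sc$cells, file.path(out_data, "sc"))
saveRDS_free <- function(x, path) {  # truth as plain JSON, not binary
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE), path)
}
truth_out <- list(marker_genes = sc$truth$marker_genes,
                  sample_condition = as.list(sc$truth$sample_condition),
                  planted_enriched_clusters = sc$truth$planted_enriched_clusters)
saveRDS_free(truth_out, file.path(out_data, "sc_truth.json"))

## bulk cohort -------------------------------------------------------------
sig_panel <- lapply(stats::setNames(0:4, c("ECMMac", "IFNGMac", "StressMac",
                                           "MetalloMac", "HemeMac")),
                    function(o) sprintf("gene%04d", o * 10 + 1:10))
bulk_cfg <- bulk_sim_config(
  n_samples = 120, n_genes = 2000, signatures = sig_panel,
  signature_effect_log2fc = c(IFNGMac = 1, ECMMac = -0.8),
  seed = 102)
bulk <- simulate_bulk_cohort(bulk_cfg)
utils::write.csv(data.frame(sample = rownames(bulk$counts), bulk$counts,
                            check.names = FALSE),
                 file.path(out_data, "bulk_counts.csv"), row.names = FALSE)
utils::write.csv(bulk$samples, file.path(out_data, "bulk_samples.csv"),
                 row.names = FALSE)
write_signatures(sig_panel, file.path(out_data, "panel.gmt"))

## spatial table -----------------------------------------------------------
profiles <- list(
  ECMMac  = c(COL1A1 = 6, COL1A2 = 5, COL3A1 = 4, CD68 = 3, CXCL9 = 0.1, CD3D = 0.1, ACTA2 = 0.2, NKG7 = 0.1),
  Fibro   = c(COL1A1 = 8, COL1A2 = 7, COL3A1 = 6, CD68 = 0.1, CXCL9 = 0.1, CD3D = 0.1, ACTA2 = 5, NKG7 = 0.1),
  IFNGMac = c(COL1A1 = 0.2, COL1A2 = 0.2, COL3A1 = 0.1, CD68 = 3, CXCL9 = 6, CD3D = 0.1, ACTA2 = 0.2, NKG7 = 0.3),
  Tcell   = c(COL1A1 = 0.1, COL1A2 = 0.1, COL3A1 = 0.1, CD68 = 0.1, CXCL9 = 0.3, CD3D = 6, ACTA2 = 0.1, NKG7 = 4),
  OtherMac = c(COL1A1 = 0.3, COL1A2 = 0.3, COL3A1 = 0.2, CD68 = 3, CXCL9 = 0.3, CD3D = 0.1, ACTA2 = 0.2, NKG7 = 0.2))
sp_cfg <- spatial_sim_config(
  width = 1000, height = 1000,
  niches = list(
    list(center = c(250, 250), radius = 120, n_cells = 300,
         mixture = c(ECMMac = 0.45, Fibro = 0.45, OtherMac = 0.1)),
    list(center = c(750, 750), radius = 120, n_cells = 300,
         mixture = c(IFNGMac = 0.45, Tcell = 0.45, OtherMac = 0.1))),
  background_density = 2e-4,
  background_mixture = c(OtherMac = 0.6, Tcell = 0.2, Fibro = 0.2),
  celltype_profiles = profiles, seed = 103)
sp <- simulate_spatial(sp_cfg)
utils::write.csv(cbind(sp$cells, sp$expr), file.path(out_data, "spatial.csv"),
                 row.names = FALSE)

summary <- data.frame(
  dataset = c("single_cell", "bulk", "spatial"),
  units = c(nrow(sc$counts), nrow(bulk$counts), nrow(sp$cells)),
  features = c(ncol(sc$counts), ncol(bulk$counts), ncol(sp$expr)),
  note = c("6 clusters, C3 shifted 1.5 log2 in 'case' samples",
           "responders: IFNGMac +1, ECMMac -0.8 log2FC",
           "two niches: ECMMac+Fibro and IFNGMac+Tcell"))
utils::write.csv(summary, file.path(out_res, "01_simulation_summary.csv"),
                 row.names = FALSE)
cat("Simulated:\n"); print(summary)
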