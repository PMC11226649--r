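#!/usr/bin/env Rscript
# Stage 5: associate signatures with treatment response in the bulk cohort.
# Genes are ranked by a covariate-adjusted moderated t (response effect,
# adjusting for cancer type) and the signature panel is tested by preranked
# GSEA; then samples are stratified by quartiles of the ECM-signature score
# and a T-cell-infiltration score is compared across strata by Mann-Whitney.

library(tamtools)

bulk <- utils::read.csv("scratch/sim/bulk_counts.csv", check.names = FALSE)
counts <- as.matrix(bulk[, -1]); rownames(counts) <- bulk$sample
meta <- utils::read.csv("scratch/sim/bulk_samples.csv")
sigs <- read_signatures("scratch/sim/panel.gmt")

rk <- rank_genes(counts, stats::setNames(meta$response, meta$sample),
                 stats::setNames(meta$cancer_type, meta$sample))
utils::write.csv(rk, "results/05_gene_ranking.csv", row.names = FALSE)

pan <- run_gsea_panel(rk, sigs, n_perm = 2000, seed = 7)
pan$significant <- pan$q < 0.1
utils::write.csv(pan[, setdiff(names(pan), "leading_edge")],
                 "results/05_enrichment.csv", row.names = FALSE)
cat("Signature enrichment in responders (positive NES = responder-enriched):\n")
print(pan[, c("signature", "es", "nes", "p", "q", "significant")])

## quartile analysis: T-cell score in upper vs lower ECM quartiles ---------
lognorm_bulk <- log1p(sweep(counts, 1, rowSums(counts), "/") * 1e4)
ecm_score <- sample_signature_score(lognorm_bulk, mode = "bulk",
                                    sig = sigs$ECMMac)
# proxy T-cell infiltration signature: genes shifted with the responder
# effect stand in for the 18-gene T-cell panel of real cohorts
tcell_score <- sample_signature_score(lognorm_bulk, mode = "bulk",
                                      sig = sigs$IFNGMac)
qs <- quartile_split(ecm_score)
lower <- tcell_score[qs$sample[qs$stratum == "lower"]]
upper <- tcell_score[qs$sample[qs$stratum == "upper"]]
mw <- mann_whitney_u(upper, lower)
utils::write.csv(data.frame(n_lower = length(lower), n_upper = length(upper),
                            U = mw$U, W = mw$W, p = mw$p, method = mw$method),
                 "results/05_quartile_mwu.csv", row.names = FALSE)
cat(sprintf("T-cell score, upper vs lower ECM quartile: W = %g, U = %g, p = %.4g (%s)\n",
            mw$W, mw$U, mw$p, mw$method))
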