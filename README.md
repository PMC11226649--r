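# tamtools

Statistical toolkit for downstream analysis of pan-cancer single-cell
atlases of tumour-associated macrophages (TAMs). Tumour macrophages span a
spectrum of states — interferon-stimulated, stress-response, extracellular-
matrix (collagen-producing), metallothionein-high, proliferating and more —
and their per-sample composition carries signal about tissue site, tumour
genotype and response to immune checkpoint inhibitors. `tamtools` provides
the analysis layer that turns a clustered atlas (cluster labels are inputs,
not computed here) into those claims, for computational biologists working
with single-cell, bulk and spatial transcriptomics.

## What it implements

* **Per-cell signature scoring** — a rank-based (UCell-style) score
  `max(0, 1 − U/(n·r_max))` from capped within-cell ranks, invariant to
  monotone transforms of expression; and a control-bin module score (mean
  signature expression minus expression-matched controls).
* **Cluster signatures** — one-vs-rest Wilcoxon markers with pct/log2FC
  filters; signatures are each cluster's top-10 significant genes by fold
  change.
* **TAM cluster selection** — clusters whose mean macrophage-signature
  score exceeds the dataset mean by one standard deviation of the per-cell
  scores.
* **Signature specificity** — metric 1 (margin between best and second-best
  cluster mean score) and metric 2 (number of cancer types whose best-hit
  cluster is the signature's own), gated into "gold-standard" signatures at
  metric 2 ≥ 3 and metric 1 > 0.1.
* **Differential composition** — arcsin-√ transformed cluster proportions
  with empirical-Bayes variance moderation (trigamma moment matching),
  moderated t/F tests and BH q-values (q < 0.1).
* **Response association** — covariate-adjusted moderated-t gene ranking on
  log-CPM plus preranked GSEA (running-sum ES, gene-permutation null, NES,
  BH across the panel).
* **Quartile comparisons** — per-sample signature scores, quartile strata,
  Mann-Whitney U with exact enumeration for small samples.
* **Spatial analysis** — subset membership by strict score thresholds
  (> 0.8 member, < 0.4 non-member) and pooled k-nearest-neighbour
  cell-type composition.
* **Co-occurrence & profiling** — Spearman cluster co-occurrence, PCoA
  (classical MDS) of composition distances, cluster-mean dendrograms, and
  marker-percentile cluster membership.
* **Synthetic data** — negative-binomial multi-study single-cell atlases
  with planted clusters/markers/batch effects/composition shifts, bulk
  responder cohorts with signature-linked effects, and spatial niche
  patterns — so every stage is testable with known ground truth.

## Worked example

Simulate a small two-condition atlas with a composition shift planted in
cluster C3, then recover it:

```r
library(tamtools)

cfg <- sc_sim_config(n_studies = 2, n_samples_per_study = 10,
                     n_clusters = 6, n_genes = 300,
                     condition_effects = list(ctrl = c(), case = c(C3 = 1.5)),
                     seed = 101)
sim <- simulate_sc_atlas(cfg)
pr  <- sample_cluster_proportions(sim$cells)
res <- moderated_test(pr$props, sim$truth$sample_condition[rownames(pr$props)])
res[order(res$q), c("cluster", "statistic", "p", "q")]
```

Running the full pipeline version of this (`analysis/04_proportions.R`, 24
samples over 3 studies) prints:

```
  cluster  statistic            p            q significant
3      C3 -6.4750031 9.480996e-11 5.688598e-10        TRUE
6      C6  2.8575269 4.269565e-03 1.280869e-02        TRUE
2      C2  1.6232748 1.045307e-01 1.646595e-01       FALSE
...
Top-q cluster: C3 (planted: C3)
```

The planted cluster is the top hit by q-value (the negative t means C3's
transformed proportion is higher in "case" samples; C6's mild positive hit
is the compositional echo — other clusters shrink when C3 grows). In the
bulk stage (`analysis/05_enrichment.R`), the signature planted up in
responders attains ES = 1.0 (NES 2.51, q = 0.003) and the one planted down
attains ES = −1.0 (NES −2.44, q = 0.003), with the three null signatures
non-significant.

The numbered scripts under `analysis/` run the whole workflow end to end
(simulate → signatures → scoring/specificity → composition → enrichment →
spatial → co-occurrence), writing intermediate datasets to `scratch/sim/`
and result tables to `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

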