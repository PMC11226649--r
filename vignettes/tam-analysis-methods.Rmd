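---
title: "Methods: signature scoring and composition analysis for TAM atlases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature scoring and composition analysis for TAM atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tamtools)
```

# Scope

`tamtools` implements the downstream statistical machinery of a pan-cancer
single-cell analysis of tumour-associated macrophages (TAMs): per-cell
gene-signature scoring, selection of macrophage clusters, assessment of
signature specificity in an all-cell-type setting, differential cluster
composition between sample groups, association of signatures with
immunotherapy response in bulk cohorts, quartile-stratified comparisons,
spatial subset assignment with neighbourhood composition, and
marker-percentile profiling. Upstream steps — dataset curation, batch
integration, graph clustering, embedding — are out of scope: cluster labels
are *inputs* here.

Because the real atlases behind such analyses are far too large to ship or
rebuild, every stage is exercised on synthetic data with known ground truth.
The generators are first-class, tested code, and the package's claims are
calibration and recovery claims about those generators' outputs, not about
any particular published dataset.

# Per-cell signature scoring

## Rank-based score

`rank_cell_scores()` is a UCell-style statistic. Within each cell, all genes
are ranked by decreasing expression with average ranks for ties; ranks
beyond `r_max` are truncated to `r_max + 1`. With $n$ signature genes
present and $U = \sum_i r_i - n(n+1)/2$ the Mann–Whitney U of the signature
against the remaining genes,

$$\mathrm{score} = \max\!\left(0,\; 1 - \frac{U}{n\,r_\mathrm{max}}\right) \in [0, 1].$$

The score is 1 exactly when the signature genes occupy the top $n$ ranks
and 0 when all of them fall at or beyond the rank cap. Because only
within-cell ranks enter, the score is invariant to any strictly monotone
transform of a cell's expression vector — raw counts, log-normalized values
and spatial expression give identical scores, which is why the same scorer
serves single-cell, bulk-profile and spatial tables.

Numerical choices: ties get average ranks *before* capping (the standard
rank-statistic convention; capping first would distort tied groups
straddling the cap). The floor at 0 keeps the documented range when every
signature gene exceeds `r_max`. The default `r_max = 1500` is the published
default of the rank-based scorer this reimplements; tests and small examples
use smaller caps so the cap is actually exercised.

## Control-bin module score

`module_score()` reimplements the standard "module score": genes are split
into `n_bins = 24` equal-count bins of average expression; each signature
gene contributes `n_ctrl = 100` control genes drawn with replacement from
its bin; the score is mean signature expression minus the mean over the
pooled control draws. Draws are made per signature gene in signature order
under a caller-provided seed, so scores are exactly reproducible and a test
can re-enumerate the draws. On a constant matrix, or when a bin's genes are
identical, the score is exactly zero.

## Missing genes

Gene symbols are matched case-sensitively. Signature genes absent from a
matrix are dropped with a warning; if fewer than half of a signature is
present the operation errors. This policy is a package decision — upstream
tools are silent on it — and is deliberately strict so silently meaningless
scores cannot propagate.

# Cluster signatures and TAM selection

`derive_cluster_signatures()` performs one-vs-rest two-sided Wilcoxon
rank-sum tests per gene (normal approximation with tie correction),
restricted to genes expressed in at least 10% of the cluster and with log2
fold change of at least 0.25, where fold change is computed from `expm1`
means of log-normalized values with a pseudocount of 1 — the defaults of the
widely used marker-finder this stands in for. Benjamini–Hochberg correction
is applied within each cluster, and the cluster's signature is the top 10
genes by fold change among those with q < 0.05. Clusters with fewer than 3
cells are skipped.

`select_tam_clusters()` encodes the selection rule used to pull macrophage
clusters out of heterogeneous studies: score every cell with a macrophage
signature, then select clusters whose mean score strictly exceeds the
dataset mean plus `k_sd` (default 1) standard deviations *of the per-cell
scores over the entire dataset*. We interpret "signature value for the
entire dataset" as the mean per-cell score, and the SD as the per-cell SD
rather than the SD of cluster means, which would be unstable with few
clusters; both interpretations coincide in the well-separated cases the rule
is meant for. With zero score variance nothing is selected (strict
inequality).

# Signature specificity and the gold-standard gate

Inside an atlas that also contains non-macrophage cells, a useful cluster
signature must still single out its own cluster. `specificity_metrics()`
computes, per signature:

* **metric 1** — the margin between the best and second-best cluster mean
  score, pooled over all cells. A tie for best yields 0.
* **metric 2** — the number of cancer types in which the best-hit cluster
  equals the signature's own cluster (a within-cancer tie counts as no
  match).

`gate_gold_standard()` then requires metric 2 ≥ 3 cancer types, metric 1
strictly greater than 0.1, and the pooled best hit equal to the own cluster.
Where the margin is computed (pooled vs per-cancer) is genuinely ambiguous
in the source method description; we compute the pooled margin for the gate
because the gate pairs a single margin threshold with a separate per-cancer
count, and the per-cancer repetition is exactly what metric 2 captures.

# Differential cluster composition

`sample_cluster_proportions()` tabulates per-sample cluster fractions.
`moderated_test()` follows the propeller-style recipe: transform fractions
by the variance-stabilizing arcsin-square-root $y = \arcsin\sqrt{p}$, fit
per-cluster group-mean linear models, and moderate the residual variances
jointly across clusters with an empirical-Bayes scaled-F prior
(`squeeze_variances()`): with $e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$,
the prior degrees of freedom $d_0$ solve
$\psi'(d_0/2) = \mathrm{var}(e) - \overline{\psi'(d/2)}$ by Newton inversion
of the trigamma function, and posterior variances are the blend
$(d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$. When the observed spread of
log-variances is no larger than expected under a common variance, $d_0$ is
infinite and all posterior variances collapse to $s_0^2$. Two groups give a
moderated t with $d_0 + d$ degrees of freedom; more groups give a moderated
F. Significance is controlled by BH q-values with the conventional q < 0.1
threshold.

Design decisions: samples enter unweighted (the minimal published
behaviour; cell-count weighting is a possible extension), moderation pools
across clusters only, samples are treated as independent units (repeated
samples per patient are not modelled — a documented limitation), and robust
down-weighting of outlier variances is not implemented.

Calibration is verified, not assumed: under a Dirichlet-multinomial null
(concentration 10 per cluster, 8 samples of ~500 cells, two balanced
groups) the empirical type-I error at $\alpha = 0.05$ is 0.050 ± 0.002
across 10,000 replicates, and with moderation disabled (`prior_df = 0`) the
statistic equals the classical pooled-variance t-test to 10 decimal places.

# Response association: ranking and preranked GSEA

`rank_genes()` produces a covariate-adjusted per-gene association statistic
for a binary response: genes detected in ≥ 20% of samples are kept, counts
become log2-CPM with pseudocount 0.5, a least-squares fit on
`~ covariate + response` yields the response coefficient, and variance
moderation across genes (the same `squeeze_variances()` machinery) converts
it to a moderated t. This deliberately substitutes a moderated-t ranker for
a negative-binomial GLM: the enrichment stage only requires a
covariate-adjusted ranking, the substitution reuses a tested component, and
the NB model's dispersion shrinkage is out of scope. Confounded designs
(response collinear with the covariate) are rejected rather than silently
dropped.

`gsea_es()` is the classic running-sum enrichment statistic: hits add
$|r_i|^{w}$ normalized over hits ($w = 1$ by default), misses subtract
$1/(N - N_\mathrm{hits})$, and the enrichment score is the signed maximal
deviation. On the measure-zero event that the positive and negative extremes
tie exactly (possible with rational increments, e.g. single-gene sets), the
positive extreme wins — a deterministic convention shared by the test
oracles, with a $10^{-9}$ relative tolerance absorbing
order-of-summation floating-point noise.

`gsea_permutation()` uses a gene-permutation null (random same-size gene
sets), matching the preranked tool it reimplements, with the $+1$
permutation floor $p \ge 1/(n_\mathrm{perm}+1)$ and
$\mathrm{NES} = ES / \overline{|ES_\mathrm{null}|}$ over sign-matched
permutations. The adaptive multilevel p-value refinement of the reference
implementation is intentionally omitted; p-values below the floor are
reported at the floor. `run_gsea_panel()` applies BH across the signature
panel.

# Quartiles, co-occurrence, ordination, percentiles

* `quartile_split()` uses linear-interpolation quantiles at 25%/75% with
  strict inequalities; ties at a threshold go to the middle stratum. The
  source analyses report group sizes that are not exact quartiles of their
  cohort and do not state their tie rule, so this documented rule is used
  rather than guessing an unstated one.
* `mann_whitney_u()` reports U and the rank-sum W of the first sample,
  with exact enumeration of all $\binom{n}{n_1}$ labellings when
  $n \le 12$ and a tie- and continuity-corrected normal approximation
  otherwise (within 0.02 of exact for $n_1 = n_2 = 6$).
* `spearman_cooccurrence()` is Spearman's rho across samples on cluster
  fractions; `pcoa()` double-centres $-\tfrac12 D^2$ and embeds on positive
  eigenvalues (classical metric MDS), reporting but never embedding
  negative eigenvalues; `hierarchical_cluster_means()` clusters per-cluster
  mean expression profiles with Euclidean complete linkage by default.
* `marker_percentile_membership()` restricts to positively expressing
  cells, orders them, forms equal-count bins (ties stay together in the
  lower bin), and reports per-bin cluster composition — "which clusters do
  the top expressors of this marker come from". The default 100 bins
  mirrors per-percentile profiling; reduced automatically (with a warning)
  when fewer positive cells exist.

# Spatial subsets

`assign_by_threshold()` applies the strict published semantics: score
> 0.8 means the cell belongs to the subset, < 0.4 means it does not, and
scores in between (including the thresholds themselves) stay unassigned and
are excluded from composition analyses. `knn_composition()` pools, over all
focal cells, the labels of each cell's k nearest Euclidean neighbours
(self excluded; ties at the k-th distance broken by table order), then
normalizes. Pooled counts — rather than per-cell fraction averaging —
naturally weight dense regions. k is not stated by the source method, so
the default is k = 5 with `knn_sweep()` provided for sensitivity over
k ∈ {1, 5, 10, 20}. Unassigned cells remain eligible *as neighbours* under
their cell-type label; membership is only required of the focal subset.

# The synthetic-data generators

`simulate_sc_atlas()` draws negative-binomial counts (variance
$\mu + \mu^2\phi$) with disjoint per-cluster marker blocks multiplied by
$2^{\mathrm{log2FC}}$, gene-wise multiplicative log-normal batch factors per
study, and per-sample cluster compositions from a Dirichlet with
concentration 10 per cluster whose log-weights shift with the sample's
condition. Concentration 10 gives sample-to-sample compositional
variability comparable to what cell-type proportion studies report, which
is what the moderated test needs to be exercised realistically.
`simulate_bulk_cohort()` plants responder shifts on signature genes over
log-normal gene abundances, mild cancer-type offsets, and log-normal
library sizes, with responders balanced within cancer type so response and
covariate are not confounded by construction. `simulate_spatial()` places
uniform background cells and uniform-in-disk niche cells with per-type mean
expression profiles times log-normal noise.

What the generators do *not* emulate — and therefore what passing tests do
not demonstrate about real data: doublets, ambient RNA, UMI saturation,
gene-gene correlation beyond cluster structure, spatial segmentation
errors, and batch effects that interact with cluster identity. The
generators exist to verify the *statistical contracts* of the pipeline
(calibration under the null, recovery of planted effects, exact threshold
semantics), not to reproduce any published cohort.

# Problem sizes and reproducibility

The shipped analysis scripts and acceptance checks use deliberately compact
problem sizes — a ~4,600-cell, 300-gene atlas over 3 studies and 24
samples; a 120-sample, 2,000-gene bulk cohort; ~800 spatial cells; 2,000
null replicates for calibration; 20 seeds for recovery rates — chosen so
the whole workflow re-runs from scratch in minutes on one CPU while leaving
every statistical property measurable. All generators and permutation
procedures are deterministic given their seed, and seeded operations
restore the caller's RNG state.

# Known limitations

* The moderated composition test assumes independent samples; repeated
  samples per patient inflate the effective n.
* The gene-permutation GSEA null ignores inter-gene correlation, as does
  the preranked tool it mirrors; p-values under correlated signatures are
  anti-conservative in the same way.
* The moderated-t gene ranker is not a negative-binomial model; very low
  counts with strong library-size imbalance are better served by a count
  model upstream.
* Brute-force neighbour search is quadratic in cell number; it is exact and
  fine up to ~10^5 cells but a tree-based search would be needed beyond.
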