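# amfesnet

Biomarker selection and relevance-network construction for small two-class
expression studies (case vs control, thousands of genes, tens of samples —
the typical shape of blood-based microarray cohorts in neurodegenerative
disease research). The package is aimed at analysts who need a small,
statistically calibrated gene panel plus a dependency network over it, with
every stage reproducible from one seed.

## What it computes

**AMFES selection.** Genes are ranked by an ensemble of linear SVMs trained
on random gene subsets S₁…Sₘ. A gene's score averages its objective-change
weight over the subsets containing it,

    θ_m(g) = Σᵢ I(g ∈ Sᵢ) · weightᵢ(g) / Σᵢ I(g ∈ Sᵢ),
    weightᵢ(g) = objᵢ(v₁…v_s) − objᵢ(v₁⁽ᵍ⁾…v_s⁽ᵍ⁾)      (= ½·w_g² for linear kernels)

with the ensemble grown until ‖θ_{m−1} − θ_m‖² / ‖θ_{m−1}‖² < 0.01, and the
ranking recursively refined on the top half down to a final three. Relevance
is calibrated by *artificial genes* (within-gene permutations of real
genes): each real gene's **gene-index** is the fraction of probes ranked
above it. Over r = max(5, int(500/n + 0.5)) stratified training–validation
pairs, the cutoff p\* is the smallest gene-index whose average validation
accuracy beats the all-genes baseline; the panel is every gene with index
≤ p\* in a final all-samples ranking.

**MI target networks.** Pairwise dependence over the panel is the
Gaussian-KDE mutual-information estimate (nats)

    Î(X,Y) = (1/M) Σ_w log[ M·Σ_u e^−(Δx²+Δy²)/2h² / (Σ_u e^−Δx²/2h² · Σ_u e^−Δy²/2h²) ]

computed by a loop-reordered fast path that is numerically identical to the
naive estimator. Edges keep only MI values exceeding a permutation-derived
null maximum (30 repetitions by default); hierarchical clustering of the MI
matrix yields the clustergram order.

**Evaluation.** Stratified cross-validated SVM decision values pooled into
one ROC; AUC is the exact Mann–Whitney pair-counting probability.

## Worked example

```r
library(amfesnet)

spec <- synthetic_spec(n_genes = 500, n_informative = 15,
                       n_samples_per_class = 14, effect_size = 2, seed = 42)
gen <- generate_dataset(spec)
gen$dataset
#> expression_dataset: 500 genes x 28 samples (14 case / 14 control)

sel <- select_genes(gen$dataset, seed = 42)
sel
#> amfes_selection: 9 genes at p* = 0 (baseline acc 0.819, r = 18 pairs)
mean(gen$informative_genes %in% sel$panel)
#> [1] 0.6
```

Out of 500 genes the selector keeps 9 (1.8%), all of them outranking every
artificial probe (p\* = 0); 9 of the 15 planted markers are recovered — at
effect 2 SD and 14 samples per class the weakest planted genes are not
reliably separable from noise, which is expected behaviour, not a defect.

```r
panel <- subset_dataset(gen$dataset, genes = sel$panel)
X <- standardize(panel)$values
mi <- pairwise_mi(X, h = 0.25)
thr <- permutation_threshold(X, h = 0.25, n_perm = 30, seed = 42)
net <- build_network(mi, as.numeric(thr), permutation_count = 30)
net
#> target_network: 9 nodes, 9 edges (MI > 0.8382)
cluster_order(mi)
#> cluster_order over 9 genes: g0014, g0004, g0009, g0002, g0012, g0001, ...

evaluate_panel(gen$dataset, sel$panel, k_folds = 5, seed = 42)
#> roc_result: AUC = 1.00000 (14 case vs 14 control, 29 curve points)
```

Only 9 of the 36 possible panel edges survive the permutation threshold
(0.84 nats — the largest MI ever seen across 30 fully label-and-pair
destroying permutations), and the 9-gene panel classifies held-out samples
perfectly under 5-fold cross-validation.

`run_pipeline()` chains all stages and writes six artifacts (panel, per-class
MI matrices, GraphML network, clustergram order, JSON report) that reproduce
byte-for-byte from the same config. A thin CLI with subcommands
(`simulate`, `select`, `mi`, `network`, `clustergram`, `evaluate`, `run`)
lives at `inst/cli/amfesnet.R`.

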