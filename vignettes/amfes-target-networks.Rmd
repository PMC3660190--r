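---
title: "Ensemble SVM biomarker selection and MI target networks: methods"
author: "amfesnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble SVM biomarker selection and MI target networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amfesnet)
```

## The problem

Small two-class expression studies — a few thousand probes, a few dozen
blood samples, a case/control label — need three things from an analysis
toolkit: a defensible way to pick a small biomarker panel out of thousands
of candidates, a dependency structure ("target network") over the panel that
suggests which markers act together, and an honest estimate of how well the
panel classifies unseen samples. `amfesnet` implements one coherent
methodology for all three, built around ensemble SVM feature ranking,
Gaussian-kernel mutual information, and permutation-calibrated network
thresholds, and ships a synthetic-data generator with planted ground truth
so the whole chain is testable end to end.

## Ranking: ensemble SVM scores

At a ranking stage with $k$ genes, the toolkit draws random subsets
$S_1, \dots, S_m$ of $j$ genes each and trains a linear soft-margin SVM
$C_i$ on every subset. A gene's score is the average, over the subsets that
contain it, of its *objective-change weight*:

$$\theta_m(g) \;=\; \frac{\sum_i I(g \in S_i)\,\mathrm{weight}_i(g)}
 {\sum_i I(g \in S_i)},
 \qquad
 \mathrm{weight}_i(g) \;=\; \mathrm{obj}_i(v_1,\dots,v_s)
 - \mathrm{obj}_i(v_1^{(g)},\dots,v_s^{(g)}),$$

where $v_1 \ldots v_s$ are the support vectors of $C_i$, $v^{(g)}$ drops
gene $g$ from a vector, and the dual coefficients are held fixed. For the
linear kernel this difference collapses to $\tfrac12 w_g^2$, half the
squared primal weight — an identity the test suite verifies against the
explicit dual-objective recomputation. Scoring genes inside random
subsets (rather than one global fit) lets weakly informative genes be
judged in many contexts, the motivation for subset ensembles over recursive
feature elimination.

Ranking is staged: all $k$ genes are ranked once, then only the top
$\lceil k/2 \rceil$ are re-ranked while the bottom half keeps its order,
recursively, until a final re-ranking of the top three. Cheap early stages
winnow; expensive late stages refine.

### Ensemble growth and convergence

The ensemble stops growing when the score vector stabilizes:

$$\frac{\lVert \theta_{m-1} - \theta_m \rVert^2}{\lVert \theta_{m-1} \rVert^2} < 0.01 .$$

A design point we settled empirically: the natural growth unit is a full
*coverage cycle* — $\lceil k/j \rceil$ subsets dealt from a fresh shuffle so
every gene's score receives one more observation — not a single subset. A
single added subset touches only $j$ of $k$ coordinates, so the relative
change above is $O(j/k)$ and the test fires immediately, leaving each score
an average of roughly one noisy weight; with cycle-wise growth the compared
vectors are genuinely refreshed and planted-marker recovery improves
markedly (the test suite asserts recall of at least 0.5 with panels under
10% of genes on 1000-gene benchmarks, a bound single-subset growth did not
reach). The ensemble starts at $\max(10, \lceil k/j \rceil)$ subsets and is
capped at 500.

Defaults, all configurable through `amfes_config()`:

| knob | default | why |
|---|---|---|
| kernel / C | linear, 1 | the objective-change weight is exact and cheap for linear kernels |
| subset size $j$ | $\max(3, \lceil\sqrt{k}\rceil)$ | keeps per-SVM dimensionality below the sample count |
| probes | one per original gene | index resolution of $1/k$ |
| validation fraction | 0.3, stratified | balanced pairs at the study's tiny $n$ |
| convergence tol | 0.01 | relative squared-norm change per cycle |

## Calibration: artificial genes and the gene-index

Relevance needs a null scale. Each *artificial gene* (probe) is an
independent within-gene permutation of a randomly chosen real gene's sample
values: marginals preserved, label association destroyed. Probes are ranked
together with the real genes, and each real gene receives a **gene-index**
— the fraction of probes ranked strictly above it, a number in $[0,1]$
where 0 means the gene outranks every probe.

## Selection: the p* cutoff

With $n$ learning samples the toolkit draws
$r = \max(5, \mathrm{int}(500/n + 0.5))$ stratified training–validation
pairs (so $n = 28$ gives $r = 18$). Per pair, ranking plus gene-indices are
computed on the training part with fresh probes; candidate cutoffs $p_i$
(the distinct observed index values, plus 0) are then scored by the average
validation accuracy $av(p_i)$ of an SVM trained on the genes with index
$\le p_i$. Scanning ascending, selection stops at the first candidate whose
$av$ strictly exceeds the all-genes baseline; if none does, the candidate
with maximal $av$ wins, ties to the smaller cutoff. (The scan also stops
once a candidate reaches accuracy 1.0: nothing can strictly exceed it and
the tie-break prefers smaller cutoffs, so the outcome is provably the same
as exhaustive evaluation.) A final ranking on *all* learning samples with
fresh probes turns $p^\*$ into a concrete panel: the genes with index
$\le p^\*$.

An empty candidate panel predicts the majority training class, so the
degenerate cutoff $p = 0$ with no gene above every probe is well-defined.

## Mutual information

Dependence between panel genes is measured by the Gaussian-KDE plug-in
estimate of mutual information; kernel normalization constants cancel,
leaving (in nats)

$$\hat I(X,Y) = \frac1M \sum_w \log
 \frac{M\,\sum_u e^{-\left[(x_w-x_u)^2 + (y_w-y_u)^2\right]/2h^2}}
      {\sum_u e^{-(x_w-x_u)^2/2h^2}\; \sum_u e^{-(y_w-y_u)^2/2h^2}} .$$

`kde_mi_naive()` computes exactly this, from scratch, per pair — the
reference path. `pairwise_mi()` is the production path: each gene's
$M \times M$ kernel matrix and marginal row sums are computed once, and the
per-sample summation is hoisted to the outer loop, so every sample-pair
kernel distance is evaluated once per gene rather than once per gene pair
(loop-nest optimization). The two paths agree to $10^{-10}$ on every tested
instance; that equivalence is the module's central correctness claim.

Numerical conventions:

* **Natural log.** The bivariate-Gaussian closed form
  $-\tfrac12\ln(1-\rho^2)$ is then exact: at $\rho = 0.9$, $M = 2000$,
  $h = 0.25$ the estimate lands within 0.2 nats of 0.830.
* **Bandwidth** $h = 0.25$ by default, *on standardized rows* (population
  convention: mean 0, variance 1, denominator $M$). Standardizing first is
  what makes a single default meaningful.
* **Negative estimates are reported as-is.** The plug-in estimator is
  biased; the bias is strongly positive when $h$ is narrow relative to the
  data spread (at $h = 0.25$, $M \approx 20$, independent pairs sit near
  +0.7 nats and none go negative) and shrinks as the kernel widens, at
  which point sampling noise pushes an appreciable fraction of independent
  pairs below zero (asserted at $h = 1.5$ on standardized noise). Both
  regimes are exercised in the tests; summaries count all $N^2$ entries,
  diagonal included, with exact zeros in neither sign bucket.
* The independence limit $|\hat I| < 0.05$ nats is reached by $M = 2000$ at
  $h = 0.25$; at $M = 500$ the bias still sits near 0.09 nats, so small-$M$
  estimates should be read against a null calibration, which is precisely
  what the network threshold provides.

## Target network and clustergram

The network-building null: independently permute each gene's sample values
(destroying all between-gene dependence), recompute the full pairwise MI
matrix, record its maximum off-diagonal entry; after `n_perm` (default 30)
repetitions the threshold is the largest null maximum, and an edge exists
iff its MI *strictly* exceeds it. We read "permuting MI values of gene
pairs" as permuting the underlying expression values per gene — the only
reading that yields a null distribution of MI magnitudes. On 200
independent-noise genes this leaves fewer than 1% (typically zero) of pairs
connected.

The clustergram orders genes by agglomerative clustering of the MI-matrix
rows under Euclidean distance with average linkage (the distance is the
named default of the original workflow; the linkage is our fixed choice),
ties broken by input order. Identical rows merge at height zero; planted
MI blocks come out contiguous in the leaf order.

## Evaluation

`cross_val_scores()` runs stratified k-fold cross-validation (default
$k = 5$, automatic leave-one-out when the smaller class has fewer than $k$
samples), standardizing per training fold, so each sample is scored by a
model that never saw it. Decision values are pooled into a single ROC —
common practice at tiny $n$ — with per-fold AUCs also reported. AUC is the
Mann–Whitney pair-counting probability with ties at one half; the curve
enumerates all distinct thresholds, and its trapezoidal area equals the
pair-counting value exactly (asserted, not assumed, in the tests).

## What the synthetic generator does and does not emulate

`generate_dataset()` plants: informative genes whose class means differ by
`effect_size` noise-SD units; correlated blocks sharing a latent factor
(`gene = sqrt(rho) * factor + sqrt(1-rho) * noise`, pairwise correlation
$\rho$ in expectation); everything else pure Gaussian noise. Defaults mirror
the microarray case/control shape the methodology targets: order $10^3$
genes, 14–20 samples per class, effect 2 SD. It does **not** model chip
artifacts (dye bias, saturation, probe cross-hybridization), heavy-tailed
or correlated noise, or batch effects — so green tests certify algorithmic
correctness and statistical behaviour under clean Gaussian conditions, not
robustness to real microarray pathology. With `effect_size = 0` the
generator is the negative control: any correct selector's recall must be
indistinguishable from chance.

Problem sizes in the test-suite benchmarks (1000 genes, 14–20 per class, 5
or 3 seeds; 200 genes for the network null) are the package's chosen
working points for these study shapes: large enough that ranking, probe
calibration, thresholding and cross-validation all operate in their
intended regime, small enough to iterate on.

## Degenerate inputs and tie-breaks

* Constant genes standardize to all-zero rows, flagged, never fatal.
* Equal ranking scores: stable sort, original input order.
* A converged-test denominator of zero reports "not converged".
* Panels smaller than two genes are padded from the top of the final
  ranking before network stages (flagged in the report).
* Determinism: every seeded entry point saves and restores the caller's RNG
  state; one master seed derives all stage seeds, and an identical
  configuration reproduces every artifact byte for byte.

## Known limitations

* The objective-change weight formula is linear-kernel only (nonlinear
  kernels would need their own kernel-matrix recomputation); there is no
  multiclass support.
* Scores from different recursion stages are ensemble averages over
  different gene pools, so the reported per-gene scores are comparable
  within a stage segment but not across segments; the authoritative output
  is the order itself.
* Panel selection and its cross-validated evaluation run on the same
  samples unless a held-out test fraction is configured
  (`amfes_config(test_fraction = )`), so default AUCs carry selection
  optimism — acceptable for ranking panels, not for certifying clinical
  performance.
* No bandwidth selection for the MI estimator; $h$ is a knob, and
  comparisons across datasets are only meaningful at a shared $h$ on
  standardized values.
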