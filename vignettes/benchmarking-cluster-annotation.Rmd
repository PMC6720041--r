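---
title: "Benchmarking cluster-level cell-type annotation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking cluster-level cell-type annotation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scTypeBench)
```

`scTypeBench` assigns cell-type labels to scRNA-seq cell clusters by
scoring every (cell type, cluster) pair with five different methods, and
provides the evaluation and robustness machinery needed to decide which
method to trust on a given kind of data. This vignette documents the
statistical model behind each component, the parameters that matter, the
numerical conventions, and the design decisions taken where the design was
genuinely open.

## Input model

All scoring operates on the cluster-average matrix: for gene $x$ and
cluster $y$,
$$\check{E}_{xy} = \frac{1}{|C_y|} \sum_{c \in C_y} e_{xc},$$
the arithmetic mean of *raw* counts over the member cells. No log
transform and no library-size normalization are applied: averaging then
commutes with global rescaling, and each method sees the same untouched
input. Normalization, batch correction and the clustering itself are
upstream of this package by design.

Cell-type signatures come in three forms. A *gene set* is a named list of
marker identifiers. A *continuous profile* is a genes × types matrix of
expression values (the LM22 leukocyte matrix is the canonical shape). A
*binary* signature marks each type's top-expressed genes with 1. The
bridge between forms is the top-5% rule: per type column, the
$\lceil 0.05\,G \rceil$ highest-valued genes are the markers. Ceiling
(never rounding) guarantees a non-empty selection at any positive
fraction; ties at the cutoff are broken by descending value then
ascending gene identifier, so every thresholding step is deterministic.
Gene identifiers match by exact, case-sensitive string comparison; an
explicit `fold_gene_case()` helper exists for mixing mouse- and
human-cased symbols, because silent case-folding can corrupt a benchmark.

## The five scorers

**ORA.** The cluster's "expressed" gene list is its top fraction of
$\check{E}_{xy}$ (default the same 5% rule; the cutoff is configurable
because any expression threshold here is an analysis choice, not a fact
of the data). The gene universe is the intersection of the signature's
gene union with the matrix's genes; both the cluster list and each marker
set are intersected with it before forming the 2×2 table, and the score
is $-\log_{10} p$ of the one-sided Fisher exact test (`stats::fisher.test`).
A set sharing no gene with the matrix yields an explicit missing entry,
never a zero.

**GSEA (preranked).** Genes are ranked per cluster; the default ranking
metric is descending average expression within the cluster — the only
cluster-intrinsic ordering available from $\check{E}_{xy}$ alone — with a
z-score-against-other-clusters alternative behind a flag. The enrichment
score is the signed extremum of the weighted Kolmogorov–Smirnov running
sum (hits add $|w|^p / \sum_{\text{hits}} |w|^p$, misses subtract
$1/(N - N_{\text{hit}})$; exponent $p = 1$ by default, $p = 0$ giving the
classic unweighted statistic). Significance comes from gene-label
permutations, one-sided on the positive enrichment direction, with the
add-one estimator $p = (1 + \#\{ES^\ast \ge ES\})/(n_{\text{perm}} + 1)$;
the $-\log_{10}$ transform is floored at $1/(n_{\text{perm}} + 1)$ so it
is always finite. The permutation null for a cluster depends only on set
size, so it is cached across same-sized sets. Because the null statistic
is evaluated only at hit positions (the walk decreases between hits),
each permutation costs $O(k \log k)$ rather than $O(G)$.

**GSVA-style scoring.** Stage 1 estimates, per gene, the cross-cluster
cdf of its expression with a Gaussian kernel of bandwidth $s_i/4$
(constant genes get 0.5 everywhere; a Poisson kernel suited to raw count
scales is available — which kernel fits averaged counts best is left to
the user, Gaussian being the upstream default for continuous values).
Stage 2 ranks genes per cluster by that estimate and weights them with
the symmetric rank statistic $r = |G/2 - \text{rank}|$, emphasizing both
extremes. Stage 3 runs the weighted walk with hit mass $\propto r^\tau$
($\tau = 1$) and miss step $1/(G - |S|)$. Stage 4 reports the largest
positive deviation minus the magnitude of the largest negative deviation
(a maximum-absolute-deviation mode exists). The score needs at least 3
clusters — below that the cross-cluster cdf estimate is meaningless — and
is used directly for ROC analysis without a null model, since the
cross-cluster construction already makes scores relative.

**ν-SVR deconvolution.** Each cluster profile is treated as a bulk
mixture and regressed on the signature matrix with a linear
ν-support-vector regression (`e1071::svm`), after z-scoring the mixture
and every signature column over the shared genes. The ν grid
{0.25, 0.5, 0.75} is the established choice for this estimator; the fit
with the lowest reconstruction RMSE wins, negative coefficients are
clipped and the vector renormalized to proportions. One degenerate
geometry is worth knowing about: if the signature columns sum to a
constant vector (marker blocks exactly tiling the gene space), they are
collinear with the regression intercept and the minimum-norm solution
redistributes weight across types before clipping. Real signatures
always contain genes outside any single type's marker block, which
breaks the collinearity.

**Directional neighbor voting.** Cluster columns ("test") and signature
columns ("train") are concatenated over shared genes; all pairwise
Spearman correlations form a network whose entries are replaced by their
average-tie ranks over the whole flattened matrix (diagonal included),
scaled into (0, 1]. Each type's single training column casts votes
$v_y = A_{y,t} / \deg(y)$ with $\deg(y)$ the cluster's total network
degree — the votes-received over votes-possible convention of neighbor
voting. The score is the single-positive AUROC
$(\text{rank}(v_y) - 1)/(n_{\text{cl}} - 1)$ with average ranks on ties.
The usual symmetrization of train→test and test→train AUROC matrices is
deliberately absent: votes flow only from signatures to clusters, which
is what makes the method a directional annotator rather than a
replicability measure. Whether signature columns should also receive
votes is not recoverable from the method's provenance; this
implementation lets them contribute to the degree only, and the toy
brute-force oracle in the test suite pins that choice.

## Evaluation conventions

All scores for a method are concatenated into one labeled vector, one
entry per (type, cluster) pair, truth 1 iff the gold standard assigns
that type to that cluster. Clusters without a gold label — and, under a
type restriction, clusters whose gold label falls outside the evaluated
set — are dropped with a logged count, as are missing score entries
(never imputed). Restricting to "expected cell types only" is an
evaluation-time filter by default, with `restrict_scoring = TRUE`
additionally restricting the signatures fed to the scorers; both modes
exist because a restriction can legitimately be applied at either level,
and they answer different questions.

ROC curves sweep one threshold per distinct score (ties grouped into a
single step); the AUC is the trapezoid integral, which equals the
Mann–Whitney statistic with half credit for ties. PR curves use the same
sweep with step-wise average precision
$\sum_k (R_k - R_{k-1}) P_k$. Step integration was chosen over the
nonlinear interpolation some curve libraries use because it is exactly
reproducible by a brute-force enumeration oracle; against interpolating
implementations, small numeric differences in PR AUC are expected.
Top-hit accuracy counts a cluster correct only when the gold type is the
*unique* score maximum — ties at the top are conservative misses, since a
tie gives the annotator no basis to pick the right label. Gold-rank
tables use average ranks on ties and bin by signature gene count
(default bins 1–2, 3–5, 6–10, 11–20, 21–50, >50).

## Subsampling robustness

Two degradation protocols mirror the two signature kinds. Gene sets lose
genes outright: at removal fraction $f$, a set of size $n$ keeps a
uniform random subset of $\max(1, \text{round}((1-f)\,n))$ genes, with
rounding half away from zero (R's banker's rounding would make the
7-gene set at $f = 0.5$ keep 3 genes rather than 4) and a one-gene
floor. The removal grid runs 0.10, …, 0.90 and ends at 0.99: near-total
removal is the informative endpoint, and the one-gene floor keeps every
set alive there. Profiles keep their dimensions: per type column, the
top-5% genes are identified and a uniform random $\lceil f k \rceil$ of
them are overwritten with that column's minimum value. When a signature
exists only as gene sets, the profile methods are instead fed the binary
matrix of each gene-set subsample (`profile_path = "binarize_sets"`).
The reference protocol uses 1000 replicates per fraction; the count is
configurable, and the package's own simulations use 100 replicates per
fraction, which bounds the Monte-Carlo standard error of a mean AUC well
below the 0.02 tolerance used in the trend checks. Replicates run on
independent seeded substreams, so the whole experiment reproduces from
one seed.

## The synthetic generator

`generate_dataset()` plants one cluster per type. Counts are negative
binomial with per-gene baseline means drawn from a mean-preserving
lognormal (sdlog 0.5 by default) around `background_mean`; each type's
markers have their mean multiplied by `effect_size` in their own
cluster; Bernoulli dropout zeroes entries. The per-gene baseline
heterogeneity matters: a perfectly flat background would make every
non-marker gene an exact tie — a degenerate input for the rank-based
methods that no real count matrix or LM22-style profile resembles. The
continuous profile signature returned with the fixture is the noiseless
expected mean $(1 - p_{\text{drop}})\,\mu$, the gene sets are the planted
marker lists, and the gold standard maps cluster $i$ to type $i$.

What the generator does *not* emulate: batch effects, doublets,
realistic library-size variation, cross-type marker co-expression
hierarchies, and the long-tailed cluster-size imbalance of real tissues.
Passing the planted-structure tests therefore demonstrates that each
method recovers clean, strong signal through the whole pipeline — it does
not predict relative method rankings on real data, where signature
quality and cluster granularity dominate.

One behavior worth recording: on the synthetic continuous profile, the
shared lognormal baseline makes all signature columns strongly
rank-correlated with every cluster, compressing the margins the voting
network can exploit; neighbor voting on the *binary* signature (markers
only) separates planted types cleanly, while the continuous variant
plateaus below perfect accuracy on the same fixture. The benchmark's
method variants exist precisely because such representation effects are
real.

## Problem sizes and reproducibility

The package's own simulations use a 2000-gene, 8-type fixture (25
markers per type, 50 cells per cluster, effect 8, dropout 0.1) for
end-to-end recovery, and a 500-gene, 5-type moderate-signal fixture
(effect 3, dispersion 1, dropout 0.3) for the robustness decay curves,
with GSEA at 50–200 permutations in simulation loops and 1000 for single
analyses. These sizes were chosen so the full suite exercises every code
path at desk scale; all of them are parameters, not constants. Every
stochastic entry point takes a seed, permutation and subsampling streams
are derived from it, and two runs with the same configuration and seed
produce identical outputs.

## Known limitations

- ORA's expression cutoff is an interpretation: the fraction of
  "expressed" genes per cluster is inherently arbitrary, and the default
  merely reuses the 5% binarization rule for symmetry.
- GSEA here implements the preranked statistic and permutation *p* only —
  no FDR, no normalized enrichment score, no phenotype permutation.
- GSVA scores are raw statistics; the package deliberately provides no
  *p*-values for them.
- The deconvolution scorer omits quantile normalization and
  absolute-mode scaling found in some deconvolution pipelines.
- Neighbor voting uses the unsupervised one-column-per-type variant; the
  many-marker-sets AUROC mode is out of scope.
- Confusion-matrix analysis and statistical comparison of AUCs between
  methods are not implemented.
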