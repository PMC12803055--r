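---
title: "Methods: metrics, protocols and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metrics, protocols and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scembedeval)
```

# What this package evaluates

A cell embedding assigns each cell a vector $z_i \in \mathbb{R}^d$.
Whether the embedding came from a pretrained foundation model, an
autoencoder, or plain PCA on highly variable genes, the questions asked of
it are the same: does it separate biological populations, does it mix
technical batches, does it preserve spatial tissue organization, and does
it carry enough information for supervised transfer and perturbation
modeling? This vignette documents the statistics and protocols the package
implements, the parameters that matter, the synthetic worlds used to test
them, and the design choices made where the underlying conventions are
genuinely open.

# Zero-shot clustering and embedding metrics

**Unified clustering.** A kNN graph (exact Euclidean neighbors, ties broken
by cell order, $k = 15$ by default) is clustered with Leiden modularity
community detection. No standard exists for choosing the resolution, so we
bisect it — doubling/halving until the target cluster count (the number of
annotated cell types) is bracketed, then bisecting up to 25 evaluations —
and return the partition whose cluster count is closest to the target.
This is a declared convention of the package: the choice of algorithm, of
$k$, and of the resolution rule are not prescribed by the metrics
themselves. The procedure is seeded and deterministic; disconnected graphs
are clustered jointly.

**Partition agreement.** ARI, NMI, homogeneity, completeness and the
Fowlkes–Mallows index are computed from the contingency table. Entropies
use the natural log (the base cancels in every ratio). Degenerate cases
follow the limits of agreement: two constant partitions score NMI/HOM/COM
1; exactly one constant partition scores NMI 0; ARI returns 1 when its
chance-correction denominator vanishes and the partitions agree. These
conventions matter only on pathological inputs and are covered by tests.

**Embedding-space scores.** ASW uses the silhouette with $s(i) = 0$ for
singleton classes. Acc@kNN is a $k{=}5$ nearest-neighbor majority vote
under stratified 5-fold cross-validation, with vote ties resolved by the
nearest single neighbor. cLISI/iLISI compute the inverse Simpson's index
of the label composition of the $k_\mathrm{lisi} = 50$ nearest neighbors
(plug-in proportions on the fixed neighborhood, not a perplexity-weighted
kernel), average it over cells, normalize the raw value from $[1, C]$ to
$[0, 1]$, and report cLISI as $1 - \text{normalized}$ so every score in
the report is higher-is-better. BRAS is the mean over cell types of
$1 - |\mathrm{ASW}_\mathrm{batch}|$; the absolute value is required for
the claimed $[0,1]$ range, since a raw $1 - \mathrm{ASW}$ can reach 2.
kBET performs a per-cell $\chi^2$ goodness-of-fit test of the
$k_\mathrm{kbet} = 50$-neighborhood batch composition against the global
batch frequencies at $\alpha = 0.05$, pooling batches whose expected
neighborhood count falls below 1; under perfect mixing its expectation is
$1 - \alpha$. Graph connectivity is computed per label on the symmetrized
kNN subgraph ($k_\mathrm{gc} = 15$) induced by that label's cells. None of
the neighborhood sizes are canonical; all sit in `batch_metric_config()`.

# Spatial-domain metrics

Counts are library-normalized to the median library and log1p-transformed.
Marker genes are ranked per predicted domain by a one-vs-rest Wilcoxon
rank-sum AUC and the top 10 per domain are pooled. The spatial weight
graph is binary symmetric kNN with $k_\mathrm{spatial} = 6$ (the hex-like
Visium convention); for lattice data an explicit rook-adjacency graph can
be supplied instead, and the generators emit one. Moran's I and Geary's C
are computed per marker gene and summarized by the median; the report
carries $I$ and $1 - C$.

CHAOS standardizes coordinates per axis using the population (1/n)
variance, then averages each spot's distance to its nearest same-cluster
spot. On sparse layouts this mean can exceed 1, so the reported
$1 - \mathrm{CHAOS}$ is floored at 0 with the raw value kept as an
attribute. PAS marks a spot abnormal when more than half of its spatial
neighbors carry a different label (self excluded) and reports
$1 - \mathrm{PAS}$. When an explicit neighbor graph is supplied the
abnormality threshold uses each spot's own neighbor count — on a lattice,
corner spots have two rook neighbors, and "more than half" means more
than one. This is why the checkerboard anchor (every spot abnormal) holds
on the rook graph but cannot hold for Euclidean kNN on a finite grid: a
corner's four nearest Euclidean neighbors include two diagonal/distance-2
spots of its own color.

Invariances: all three scores are invariant to translation and uniform
scaling; PAS and the autocorrelation graph are invariant to rotation
through rank-based neighbors. CHAOS standardizes each axis separately, so
it is exactly rotation-invariant only when the two axes have equal
variance (true for square grids); this mirrors the per-axis definition and
is documented rather than "fixed".

# Few-shot prototypical evaluation

Episodes are N-way K-shot: N classes drawn without replacement from
classes with at least $K + 1$ cells, K support cells per class, and up to
`query_per_class = 50` held-out queries per class (a cap that bounds
episode cost while keeping queries stratified). Episodes serialize to JSON
so that different methods consume byte-identical support/query sets — the
comparability guarantee is enforced by artifact, not convention.
Prototypes are support means; queries are scored by softmax over negative
cosine distances, with argmax ties going to the first class in level
order. With $K = 1$ this reduces exactly to cosine nearest-neighbor
classification, which the tests exploit as an oracle.

# Probe fine-tuning and the HVG+PCA baseline

The probe is layer normalization → dropout (0.1) → hidden affine (width
256) with GELU → output affine, trained with cross-entropy, Adam
(peak learning rate $10^{-3}$), a cosine learning-rate schedule over
`max_epochs` and early stopping with patience 10 on validation loss; the
returned parameters are those of the epoch with the lowest validation
loss. The width/dropout/learning-rate/batch-size defaults are package
decisions tuned to nothing beyond "modest capacity for ≤1024-dim
embeddings"; all are in `probe_config()`. When the split carries no
validation set, a stratified fraction (default 0.2) is carved from train.
Inputs are not standardized outside the model: the probe's own
normalization layer handles scale.

The HVG+PCA baseline selects 2,000 highly variable genes by dispersion
(variance/mean of log-normalized expression, z-scored within 20
equal-frequency mean bins — the classic recipe), then standardizes genes
and projects to 50 PCs. Every statistic — the library-size target, the
HVG set, gene means/s.d.s, and the loadings — is a function of training
cells only; validation and test cells are projected through the frozen
transform. A metamorphic test replaces all test-cell counts with noise and
asserts the train-side output is unchanged.

# Perturbation-response prediction

Observed responses are per-condition means of log-normalized expression
minus the control mean. Counterfactual inputs take a fixed seeded subset
of control cells (default 500) and overwrite only the targeted genes'
values with draws from the perturbed condition; each condition's
counterfactual set is embedded separately and averaged into a
condition-level embedding. Embeddings are standardized and projected to 50
PCs (fitted on training conditions only; the dimension shrinks with a
warning when conditions are few) and ridge regression maps the reduced
embedding to the gene-wise response.

The ridge penalty accepts a fixed value or `"loocv"`, which selects over
the grid $10^{-6} \ldots 10^{2}$ by closed-form leave-one-out PRESS. The
pipeline defaults to `"loocv"`: with a dozen-odd training conditions a
fixed unit penalty measurably over-shrinks (on the bundled additive
fixture it inflates held-out L2 by ~50% relative to the self-tuned
penalty), while LOO-CV costs one SVD. The additive baseline predicts a
double perturbation as the sum of its two observed single responses
(mode `"observed"`; `"predicted"` sums model outputs instead — both exist
because "summing predicted responses from the singles" is ambiguous when
all singles are training conditions with observed responses).

# Synthetic worlds, and what a green test establishes

`make_mixture_embeddings()` draws cell types as unit-variance isotropic
Gaussians at the vertices of a regular simplex with pairwise separation
`type_separation` (in within-class s.d. units) and adds a fixed random
offset of norm `batch_shift` per batch — the simplest geometry in which
label metrics respond monotonically to separation and batch metrics to
shift. `make_spatial_fixture()` lays one spot per grid node with stripe /
checkerboard / block domains and Poisson counts (marker rate 50 inside
the domain vs 0.5 outside, the contrast of a strong marker over sparse
background; at this contrast the noiseless stripes fixture reaches a
median marker Moran's I above 0.8). `make_perturbation_fixture()` builds
log-space expression with additive double effects
$\delta_{g_1} + \delta_{g_2} + \varepsilon$,
$\|\varepsilon\| \propto$ `interaction_scale`, and a seeded linear
pseudo-embedding $E = XW + \text{noise}$.

Two generator choices deserve emphasis. Each perturbation's own-gene
(cis) effect is fixed at +2 while trans effects are drawn
$N(0, \text{effect\_scale}^2)$ and are zeroed on the other *targeted*
genes. Both are identifiability requirements, not conveniences: a
perturbation with a near-zero cis effect is invisible to the
counterfactual encoding (only the targeted columns change), and a trans
effect of one perturbation on another's target gene leaks into that
partner's counterfactual column, making the condition-to-response map
non-linear — in which case no linear model, however regularized, can
recover the additive ground truth.

These fixtures exercise the metrics and protocols; they do not emulate
real scRNA-seq count distributions (no dropout, no overdispersion, no
batch-by-type interactions). A green suite therefore establishes that the
implementations compute their definitions correctly and respond to signal
and nuisance in the right direction — not that any particular embedding
method is good.

# Numerical notes

- Exact kNN is brute force (block-wise distance computation), with ties
  broken toward the lower cell index; no approximate search is used, so
  neighbor sets are reproducible across platforms.
- Silhouettes use `stats::dist` (direct coordinate differences) rather
  than the $x^2 + y^2 - 2xy$ expansion, which loses ~5 digits and fails
  the 1e-10 oracle comparisons.
- All stochastic steps (splits, fold assignment, episode sampling,
  clustering, probe training, counterfactual draws) consume an explicit
  seed and restore the caller's RNG state.
- Report TSVs format numbers with `%.12g` and contain no timestamps, so
  reruns with identical configs are byte-identical.

# Known limitations

- The unified clustering hits the exact target cluster count only when
  some resolution attains it; otherwise the closest partition within the
  bisection budget is returned (recorded in the `Partition`).
- kBET relies on the asymptotic $\chi^2$ distribution; for very small
  neighborhoods or many rare batches the pooled approximation is coarse.
- The h5ad interface shells out to Python's `anndata`; environments
  without it can use the plain-text dataset directory format exclusively.
- Trajectory-inference evaluation is out of scope: the package exports
  embeddings and neighbor graphs for external tools but computes no
  trajectory metrics.
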