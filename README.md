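# scembedeval

Benchmarking toolkit for cell embeddings from single-cell transcriptomics.

Single-cell foundation models (and classical pipelines such as HVG+PCA)
reduce each cell's transcriptome to a d-dimensional vector z ∈ R^d. This
package evaluates such embeddings — it does not compute them. It provides,
as a library plus a `scembed-eval` command line:

- **Zero-shot metrics.** A kNN graph is built from the embedding, Leiden
  community detection is tuned by resolution bisection to the annotated
  cluster count, and the partition is scored against cell-type labels with
  ARI, NMI, homogeneity, completeness and the Fowlkes–Mallows index.
  Embedding-space structure is scored with the average silhouette width
  (ASW), stratified 5-fold kNN classifier accuracy (Acc@kNN), and the local
  inverse Simpson's index over cell types (cLISI, reported as
  1 − normalized so higher = purer neighborhoods). Batch mixing is scored
  with iLISI, BRAS (mean over cell types of 1 − |ASW_batch|), graph
  connectivity (per-label largest connected component fraction) and kBET
  (the fraction of cells whose neighborhood batch composition passes a
  chi-square goodness-of-fit test against the global batch frequencies).
- **Spatial-domain metrics.** Moran's I and Geary's C of domain marker
  genes over a spatial weight graph, CHAOS (mean distance to the nearest
  same-domain spot on standardized coordinates) and PAS (fraction of spots
  whose spatial neighbors mostly disagree with them). Geary, CHAOS and PAS
  are reported as 1 − metric so that higher is always better.
- **Few-shot evaluation.** N-way K-shot episodes with serialized
  support/query sets; prototypes p_c are support means, queries are scored
  by softmax over negative cosine distances
  P(c|z) = exp(−d_c(z)) / Σ exp(−d_c'(z)), d_c(z) = 1 − cos(z, p_c).
- **Probe fine-tuning.** A standardized MLP probe (layer norm → dropout →
  GELU hidden layer → linear output) trained with cross-entropy, Adam, a
  cosine learning-rate schedule and early stopping; the checkpoint with the
  lowest validation loss is kept. Includes the classical HVG+PCA baseline
  (2,000 HVGs, library-size normalization, log1p, scaling, 50 PCs — all
  fitted on the training split only).
- **Perturbation-response prediction.** Counterfactual transcriptomes
  (control background with only the targeted genes' values replaced),
  condition-level embeddings, standardization + PCA to 50 dims, ridge
  regression to gene-wise responses, the additive single-effect baseline
  for double perturbations, and L2 / Pearson evaluation.
- **Reporting.** Direction-aware normalization (each dataset × metric
  column divided by its maximum), unweighted composite scores and method
  ranking, written as byte-reproducible TSV/JSON.
- **Synthetic fixtures.** Seeded generators for Gaussian-mixture embeddings
  with batch shifts, spatial grids with contiguous domains and marker-gene
  count profiles, and additive perturbation screens with a linear
  pseudo-embedding — every metric has an oracle-checkable input without
  downloads.

## Worked example

```r
library(scembedeval)

mix <- make_mixture_embeddings(mixture_spec(
  n_cells = 600, n_types = 3, n_batches = 2, dim = 16,
  type_separation = 8, batch_shift = 1, seed = 1))
res <- zero_shot_metrics(mix$embedding, mix$annotations, seed = 1)
round(unlist(res), 3)
#>         ari         nmi         hom         com         fmi         asw
#>       1.000       1.000       1.000       1.000       1.000       0.396
#>     acc_knn          gc clisi_score ilisi_score        bras        kbet
#>       1.000       1.000       0.999       0.891       0.970       0.677
```

Cell types separated by 8 within-class standard deviations are perfectly
recovered by the unified clustering (agreement metrics 1.0); ASW is
positive but far from 1 because unit-variance clusters at separation 8 in
16 dimensions still have width relative to their spacing. A batch shift of
norm 1 is mild but real: neighborhood mixing stays high (iLISI 0.89,
BRAS 0.97) while kBET — a per-cell significance test and the most
sensitive of the three — already drops to 0.68 from its well-mixed
ceiling of 1 − α = 0.95.

The one-command runner chains everything on fixtures or your own `.h5ad`:

```r
run_benchmark(list(
  seed = 1, tasks = list("zero_shot", "spatial"),
  datasets = list(list(
    name = "grid", methods = list("expression", "hvg_pca"),
    fixture = list(kind = "spatial", grid_rows = 10, grid_cols = 10,
                   domain_layout = "stripes")))),
  out_dir = "bench_out")
```

which writes `report_long.tsv` (raw, transformed and normalized values per
method × dataset × metric), `ranking.tsv` (composite scores) and a JSON
report plus run log.

## Command line

```sh
scembed-eval simulate {mixture|spatial|perturb} --out fix.h5ad --seed 1
scembed-eval zero-shot fix.h5ad --method embedding --seed 1
scembed-eval few-shot fix.h5ad --n-way 5 --k-shot 1 --trials 20 --episodes-file eps.json
scembed-eval finetune fix.h5ad --method hvg_pca --seed 1
scembed-eval perturb perturb_fix.h5ad --seed 0
scembed-eval run --config cfg.yaml
```

The launcher lives at `system.file("exec/scembed-eval", package = "scembedeval")`.

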