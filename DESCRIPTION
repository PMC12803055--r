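Package: scembedeval
Title: Evaluation Toolkit for Single-Cell Embedding Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Metrics and protocols for benchmarking cell embeddings derived
    from single-cell transcriptomics. Provides zero-shot clustering and
    batch-mixing metrics (ARI, NMI, homogeneity, completeness, Fowlkes-Mallows,
    silhouette, kNN accuracy, cLISI/iLISI, BRAS, graph connectivity, kBET),
    spatial-domain coherence metrics (Moran's I, Geary's C, CHAOS, PAS),
    episodic few-shot prototypical classification, a standardized supervised
    probe with an HVG+PCA baseline, counterfactual perturbation-response
    prediction with ridge regression and an additive baseline, and
    direction-aware metric normalization with composite ranking. Includes
    seeded synthetic-data generators with known ground truth so every metric
    can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
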