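# Label- and batch-aware embedding-space metrics: average silhouette width,
# kNN classifier accuracy, cLISI/iLISI, BRAS, graph connectivity and kBET.
# All are computed directly on distances/neighborhoods; the test suite
# re-derives each one with naive per-cell loops as an independent oracle.

#' Configuration for batch/embedding metrics
#'
#' Neighborhood sizes and test level are artifact decisions (the source
#' formulas leave them open); all are common community defaults and every
#' one is overridable here.
#'
#' @param k_lisi neighborhood size for cLISI/iLISI (default 50).
#' @param k_kbet neighborhood size for kBET (default 50).
#' @param alpha_kbet kBET significance threshold (default 0.05).
#' @param k_gc kNN graph size for graph connectivity (default 15).
#' @param k_acc kNN classifier neighborhood (default 5).
#' @param folds_acc stratified CV folds (default 5).
#' @param seed integer seed for fold assignment.
#' @return A `BatchMetricConfig` list.
#' @export
batch_metric_config <- function(k_lisi = 50, k_kbet = 50, alpha_kbet = 0.05,
                                k_gc = 15, k_acc = 5, folds_acc = 5,
                                seed = 0L) {
  assert_that(alpha_kbet > 0 && alpha_kbet < 1, "alpha must be in (0,1)")
  assert_that(min(k_lisi, k_kbet, k_gc, k_acc) >= 1 && folds_acc >= 2,
              "neighborhood sizes must be >= 1 and folds >= 2")
  structure(list(k_lisi = k_lisi, k_kbet = k_kbet, alpha_kbet = alpha_kbet,
                 k_gc = k_gc, k_acc = k_acc, folds_acc = folds_acc,
                 seed = as.integer(seed)),
            class = "BatchMetricConfig")
}

# group-mean distance machinery shared by silhouette variants:
# returns per-cell silhouette s(i) for the given labels (s = 0 for
# singleton classes, and 0 where both a(i) and b(i) are 0).
silhouette_values <- function(X, labels) {
  labels <- as.character(labels)
  n <- nrow(X)
  levs <- sort(unique(labels))
  assert_that(length(levs) >= 2, "silhouette requires >= 2 label levels")
  # stats::dist uses direct coordinate differences, which keeps the
  # pairwise distances accurate to ~1e-15 (the x^2+y^2-2xy expansion is not)
  D <- as.matrix(stats::dist(X))
  grp <- factor(labels, levels = levs)
  sizes <- as.vector(table(grp))
  # sums of distances from every cell to each group: n x L
  S <- t(rowsum(D, grp))           # D is symmetric
  own <- match(labels, levs)
  s <- numeric(n)
  for (i in seq_len(n)) {
    g <- own[i]
    if (sizes[g] == 1L) { s[i] <- 0; next }
    a <- S[i, g] / (sizes[g] - 1)
    b <- min(S[i, -g] / sizes[-g])
    m <- max(a, b)
    s[i] <- if (m == 0) 0 else (b - a) / m
  }
  s
}

#' Average silhouette width over cell-type labels
#'
#' For each cell, `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the
#' mean distance to other cells of the same type and `b(i)` the minimum
#' mean distance to cells of another type; singleton classes contribute 0.
#'
#' @param emb An [embedding_set()] (or a plain numeric matrix).
#' @param labels cell-type label per cell.
#' @return mean silhouette, in `[-1, 1]`.
#' @export
silhouette_label <- function(emb, labels) {
  X <- if (inherits(emb, "EmbeddingSet")) emb$matrix else as.matrix(emb)
  mean(silhouette_values(X, labels))
}

knn_vote <- function(neigh_labels, neigh_order_dist) {
  counts <- table(neigh_labels)
  winners <- names(counts)[counts == max(counts)]
  if (length(winners) == 1L) return(winners)
  # tie: the tied label whose nearest representative is closest
  for (lab in neigh_labels[order(neigh_order_dist)]) {
    if (lab %in% winners) return(lab)
  }
  winners[1L]
}

#' kNN classifier accuracy under stratified cross-validation
#'
#' Mean held-out accuracy of a Euclidean k-nearest-neighbor majority-vote
#' classifier over stratified folds with preserved label proportions.
#' Majority ties are resolved by the nearest single neighbor's label.
#'
#' @param emb An [embedding_set()] or matrix.
#' @param labels cell-type label per cell.
#' @param cfg A [batch_metric_config()] (`k_acc`, `folds_acc`, `seed`).
#' @return accuracy in `[0, 1]`; deterministic given `cfg$seed`.
#' @export
knn_accuracy <- function(emb, labels, cfg = batch_metric_config()) {
  X <- if (inherits(emb, "EmbeddingSet")) emb$matrix else as.matrix(emb)
  labels <- as.character(labels)
  n <- nrow(X)
  folds <- cfg$folds_acc
  min_class <- min(table(labels))
  if (min_class < folds) {
    warning(sprintf("smallest class has %d cells < %d folds; reducing folds",
                    min_class, folds))
    folds <- max(2L, min_class)
  }
  fold_id <- integer(n)
  with_seed(cfg$seed, {
    for (lev in unique(labels)) {
      idx <- sample(which(labels == lev))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  accs <- numeric(folds)
  for (f in seq_len(folds)) {
    te <- which(fold_id == f); tr <- which(fold_id != f)
    D <- cross_dist(X[te, , drop = FALSE], X[tr, , drop = FALSE])
    k <- min(cfg$k_acc, length(tr))
    pred <- character(length(te))
    for (r in seq_along(te)) {
      o <- order(D[r, ], seq_along(tr))[seq_len(k)]
      pred[r] <- knn_vote(labels[tr][o], D[r, o])
    }
    accs[f] <- mean(pred == labels[te])
  }
  mean(accs)
}

# raw mean inverse-Simpson over fixed k-nearest neighborhoods,
# normalized to [0,1] by (L - 1) / (C - 1)
lisi_normalized <- function(idx, labels) {
  labels <- as.character(labels)
  levs <- unique(labels)
  C <- length(levs)
  if (C < 2) return(NA_real_)
  per_cell <- apply(idx, 1, function(nb) {
    p <- tabulate(factor(labels[nb], levels = levs), nbins = C) / length(nb)
    1 / sum(p^2)
  })
  L <- mean(per_cell)
  min(max((L - 1) / (C - 1), 0), 1)
}

#' Local inverse Simpson's index scores (cLISI and iLISI)
#'
#' The inverse Simpson's index of the label composition of each cell's
#' `k_lisi` nearest neighbors, averaged over cells and normalized from
#' `[1, C]` to `[0, 1]`. Both reported scores are oriented higher-is-better:
#' `clisi_score = 1 - normalized` (neighborhood purity over cell types),
#' `ilisi_score = normalized` (mixing over batches).
#'
#' @param emb An [embedding_set()] or matrix.
#' @param labels cell-type label per cell.
#' @param batch batch label per cell, or NULL (then `ilisi_score` is NA).
#' @param cfg A [batch_metric_config()].
#' @param graph optional precomputed `NeighborGraph` (with `k >= k_lisi`).
#' @return list with `clisi_score`, `ilisi_score`, both in `[0, 1]`.
#' @export
lisi_scores <- function(emb, labels, batch = NULL,
                        cfg = batch_metric_config(), graph = NULL) {
  if (is.null(graph)) {
    emb <- if (inherits(emb, "EmbeddingSet")) emb else
      embedding_set(sprintf("c%d", seq_len(nrow(emb))), emb)
    graph <- build_neighbor_graph(emb, k = min(cfg$k_lisi, length(emb$cell_ids) - 1L))
  }
  idx <- graph$idx[, seq_len(min(cfg$k_lisi, graph$k)), drop = FALSE]
  clisi <- 1 - lisi_normalized(idx, labels)
  ilisi <- NA_real_
  if (!is.null(batch)) {
    if (length(unique(batch)) < 2) {
      warning("single batch level: ilisi_score reported as 1")
      ilisi <- 1
    } else {
      ilisi <- lisi_normalized(idx, batch)
    }
  }
  list(clisi_score = clisi, ilisi_score = ilisi)
}

#' Batch removal adapted silhouette (BRAS)
#'
#' Within each cell type, the silhouette score is computed with respect to
#' batch labels; the type contributes `1 - |ASW_batch|` (types containing a
#' single batch contribute 1) and BRAS is the mean over cell types.
#' The absolute value keeps the score in the claimed `[0, 1]` range.
#'
#' @param emb An [embedding_set()] or matrix.
#' @param cell_labels cell-type label per cell.
#' @param batch batch label per cell.
#' @return BRAS in `[0, 1]`.
#' @export
bras <- function(emb, cell_labels, batch) {
  X <- if (inherits(emb, "EmbeddingSet")) emb$matrix else as.matrix(emb)
  cell_labels <- as.character(cell_labels)
  batch <- as.character(batch)
  types <- sort(unique(cell_labels))
  vals <- numeric(length(types))
  any_multi <- FALSE
  for (t in seq_along(types)) {
    sel <- cell_labels == types[t]
    if (length(unique(batch[sel])) < 2 || sum(sel) < 3) {
      vals[t] <- 1
      next
    }
    any_multi <- TRUE
    asw_b <- mean(silhouette_values(X[sel, , drop = FALSE], batch[sel]))
    vals[t] <- 1 - abs(asw_b)
  }
  if (!any_multi) warning("no cell type contains >= 2 batches; BRAS = 1")
  mean(vals)
}

#' Graph connectivity of biological labels
#'
#' For each label, the fraction of its cells inside the largest connected
#' component of the symmetrized kNN subgraph induced by that label; GC is
#' the mean over labels.
#'
#' @param emb An [embedding_set()] or matrix.
#' @param labels cell-type label per cell.
#' @param cfg A [batch_metric_config()] (`k_gc`).
#' @return GC in `(0, 1]`.
#' @export
graph_connectivity <- function(emb, labels, cfg = batch_metric_config()) {
  emb <- if (inherits(emb, "EmbeddingSet")) emb else
    embedding_set(sprintf("c%d", seq_len(nrow(emb))), emb)
  labels <- as.character(labels)
  vals <- vapply(sort(unique(labels)), function(lev) {
    sel <- which(labels == lev)
    if (length(sel) == 1L) return(1)
    sub <- subset_embedding(emb, emb$cell_ids[sel])
    k <- min(cfg$k_gc, length(sel) - 1L)
    g <- symmetrize_graph(build_neighbor_graph(sub, k))
    comp <- igraph::components(g)
    max(comp$csize) / length(sel)
  }, numeric(1))
  mean(vals)
}

#' k-nearest-neighbor batch effect test (kBET)
#'
#' Per cell, a chi-square goodness-of-fit test compares the batch
#' composition of its `k_kbet` nearest neighbors against the global batch
#' frequencies; the score is the fraction of cells whose test is *not*
#' rejected at `alpha_kbet`. Batches whose expected neighborhood count is
#' below 1 are pooled into the smallest-expectation category.
#'
#' @param emb An [embedding_set()] or matrix.
#' @param batch batch label per cell.
#' @param cfg A [batch_metric_config()].
#' @param graph optional precomputed `NeighborGraph`.
#' @return kBET acceptance rate in `[0, 1]`.
#' @export
kbet <- function(emb, batch, cfg = batch_metric_config(), graph = NULL) {
  batch <- as.character(batch)
  levs <- sort(unique(batch))
  if (length(levs) < 2) return(1)  # df = 0: never rejected
  if (is.null(graph)) {
    emb <- if (inherits(emb, "EmbeddingSet")) emb else
      embedding_set(sprintf("c%d", seq_len(nrow(emb))), emb)
    graph <- build_neighbor_graph(emb, k = min(cfg$k_kbet, length(emb$cell_ids) - 1L))
  }
  idx <- graph$idx[, seq_len(min(cfg$k_kbet, graph$k)), drop = FALSE]
  k <- ncol(idx)
  p_global <- as.vector(table(factor(batch, levels = levs))) / length(batch)
  expected <- k * p_global
  if (any(expected < 1)) {
    warning("batch with expected neighborhood count < 1: pooling categories")
    map <- stats::setNames(levs, levs)
    # pool all under-expected batches together; if the pool is still under-
    # expected, absorb the smallest adequately-sized batch as well
    small <- levs[expected < 1]
    if (sum(expected[levs %in% small]) < 1 && length(small) < length(levs)) {
      big <- levs[!levs %in% small]
      small <- c(small, big[which.min(expected[levs %in% big])])
    }
    map[small] <- "(pooled)"
    batch <- unname(map[batch])
    levs <- sort(unique(batch))
    if (length(levs) < 2) return(1)
    p_global <- as.vector(table(factor(batch, levels = levs))) / length(batch)
    expected <- k * p_global
  }
  df <- length(levs) - 1L
  pvals <- apply(idx, 1, function(nb) {
    obs <- tabulate(factor(batch[nb], levels = levs), nbins = length(levs))
    stat <- sum((obs - expected)^2 / expected)
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  })
  mean(pvals > cfg$alpha_kbet)
}
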