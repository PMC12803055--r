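# Spatial-domain evaluation: Moran's I and Geary's C on domain marker genes,
# CHAOS (within-domain compactness) and PAS (abnormal-spot fraction), with
# the direction transforms applied so every reported score is
# higher-is-better (1 - C, 1 - CHAOS, 1 - PAS).

#' Configuration for spatial metrics
#'
#' @param k_spatial spatial-neighbor count for the weight graph and PAS
#'   (default 6, the hex-like Visium convention).
#' @param markers_per_domain marker genes selected per predicted domain for
#'   the autocorrelation score (default 10).
#' @param seed integer.
#' @return A `SpatialConfig` list.
#' @export
spatial_config <- function(k_spatial = 6, markers_per_domain = 10, seed = 0L) {
  assert_that(k_spatial >= 1, "k_spatial must be >= 1")
  structure(list(k_spatial = k_spatial,
                 markers_per_domain = markers_per_domain,
                 seed = as.integer(seed)),
            class = "SpatialConfig")
}

# k nearest spatial neighbors (self excluded, ties toward lower index),
# as a list of integer vectors
spatial_knn <- function(coords, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  assert_that(k < n, "k_spatial must be < number of spots")
  g <- build_neighbor_graph(
    embedding_set(sprintf("s%d", seq_len(n)), coords), k = k)
  lapply(seq_len(n), function(i) g$idx[i, ])
}

# symmetric binary weight pairs (i, j) from a neighbor list
neighbor_pairs <- function(neighbors) {
  i <- rep(seq_along(neighbors), lengths(neighbors))
  j <- unlist(neighbors, use.names = FALSE)
  # symmetrize: union of (i,j) and (j,i), deduplicated
  key <- paste(pmin(i, j), pmax(i, j))
  und <- !duplicated(key) & i != j
  cbind(i = c(i[und], j[und]), j = c(j[und], i[und]))
}

#' Rank one-vs-rest marker genes per predicted domain
#'
#' Wilcoxon rank-sum ranking on log-normalized counts: genes are ordered by
#' the in-domain rank-sum AUC (probability that an in-domain spot exceeds an
#' out-domain spot).
#'
#' @param logexpr spots x genes matrix of log-normalized expression.
#' @param domains character vector of predicted domain labels.
#' @param top genes kept per domain.
#' @return named list of character vectors (per domain), plus a deduplicated
#'   union as attribute `"union"`.
#' @export
rank_domain_markers <- function(logexpr, domains, top = 10) {
  domains <- as.character(domains)
  ranks <- apply(logexpr, 2, rank)
  out <- list()
  for (d in sort(unique(domains))) {
    sel <- domains == d
    n1 <- sum(sel); n0 <- sum(!sel)
    auc <- (colSums(ranks[sel, , drop = FALSE]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    out[[d]] <- colnames(logexpr)[order(-auc)][seq_len(min(top, ncol(logexpr)))]
  }
  attr(out, "union") <- unique(unlist(out, use.names = FALSE))
  out
}

# Moran's I and Geary's C for one variable over symmetric binary weights
moran_geary_one <- function(x, pairs) {
  xc <- x - mean(x)
  ss <- sum(xc^2)
  if (ss == 0) return(c(moran = NA_real_, geary = NA_real_))
  n <- length(x)
  W <- nrow(pairs)
  num_i <- sum(xc[pairs[, 1]] * xc[pairs[, 2]])
  num_c <- sum((x[pairs[, 1]] - x[pairs[, 2]])^2)
  c(moran = n / W * num_i / ss,
    geary = (n - 1) / (2 * W) * num_c / ss)
}

#' Spatial autocorrelation of domain marker genes
#'
#' Counts are library-normalized and log-transformed; the top
#' `markers_per_domain` one-vs-rest markers of each predicted domain are
#' selected (union, deduplicated); Moran's I and Geary's C are computed per
#' marker gene on a binary symmetric k-nearest-neighbor spatial weight
#' graph. Reported: `moran_score` = median I (higher is better),
#' `geary_score` = 1 - median C.
#'
#' @param counts A [count_matrix()] (raw counts, or `assay = "logexpr"`
#'   which is used as-is).
#' @param domains predicted domain labels ([as_partition()] accepted).
#' @param coords spots x 2 coordinate matrix (defaults to
#'   `ann$spatial_xy` passed directly).
#' @param cfg A [spatial_config()].
#' @param neighbors optional spatial neighbor list (e.g.
#'   [grid_rook_neighbors()]); default Euclidean kNN with `k_spatial`.
#' @return list with `moran_score`, `geary_score`, and `per_gene` (matrix of
#'   per-marker I and C). Constant genes are skipped with a warning.
#' @export
spatial_autocorrelation <- function(counts, domains, coords,
                                    cfg = spatial_config(),
                                    neighbors = NULL) {
  stopifnot(inherits(counts, "CountMatrix"))
  domains <- as_partition(domains)$labels
  assert_that(length(unique(domains)) >= 2, "need >= 2 predicted domains")
  X <- if (counts$assay == "logexpr") counts$counts else lognorm(counts$counts)
  if (is.null(neighbors)) neighbors <- spatial_knn(coords, cfg$k_spatial)
  pairs <- neighbor_pairs(neighbors)
  markers <- rank_domain_markers(X, domains, top = cfg$markers_per_domain)
  sel <- attr(markers, "union")
  vals <- t(vapply(sel, function(g) moran_geary_one(X[, g], pairs),
                   c(moran = 0, geary = 0)))
  if (anyNA(vals)) {
    warning("constant marker gene(s) skipped in autocorrelation")
    vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  }
  list(moran_score = stats::median(vals[, "moran"]),
       geary_score = 1 - stats::median(vals[, "geary"]),
       per_gene = vals)
}

#' CHAOS spatial-continuity score
#'
#' Coordinates are standardized per axis (population variance); raw CHAOS is
#' the mean over spots of the distance to the nearest spot of the same
#' cluster. Reported score is `1 - CHAOS`, floored at 0 (the raw value is
#' kept in attribute `"raw"`). Singleton clusters contribute 0 with a
#' warning.
#'
#' @param coords spots x 2 coordinate matrix.
#' @param labels cluster/domain label per spot.
#' @return reported score in `[0, 1]` with attribute `raw`.
#' @export
chaos_score <- function(coords, labels) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  n <- nrow(coords)
  assert_that(n >= 2, "need at least 2 spots")
  S <- scale(coords, center = TRUE, scale = FALSE)
  sds <- sqrt(colMeans(S^2))          # population variance
  sds[sds == 0] <- 1
  S <- sweep(S, 2, sds, "/")
  total <- 0
  for (lev in unique(labels)) {
    sel <- which(labels == lev)
    if (length(sel) == 1L) {
      warning(sprintf("singleton cluster '%s' contributes 0 to CHAOS", lev))
      next
    }
    D <- cross_dist(S[sel, , drop = FALSE])
    diag(D) <- Inf
    total <- total + sum(apply(D, 1, min))
  }
  raw <- total / n
  structure(max(0, 1 - raw), raw = raw)
}

#' PAS (percentage of abnormal spots) score
#'
#' A spot is abnormal if more than half of its spatial neighbors carry a
#' different label (self excluded). Reported score is `1 - PAS` (raw
#' fraction kept in attribute `"raw"`).
#'
#' @param coords spots x 2 coordinate matrix.
#' @param labels domain label per spot.
#' @param cfg A [spatial_config()] (`k_spatial` for the default kNN rule).
#' @param neighbors optional explicit neighbor list (e.g. the rook lattice
#'   from [grid_rook_neighbors()]); the abnormality threshold then uses each
#'   spot's own neighbor count.
#' @return reported score in `[0, 1]` with attribute `raw`.
#' @export
pas_score <- function(coords, labels, cfg = spatial_config(),
                      neighbors = NULL) {
  labels <- as.character(labels)
  if (is.null(neighbors)) neighbors <- spatial_knn(coords, cfg$k_spatial)
  abnormal <- vapply(seq_along(labels), function(i) {
    nb <- neighbors[[i]]
    sum(labels[nb] != labels[i]) > length(nb) / 2
  }, logical(1))
  raw <- mean(abnormal)
  structure(1 - raw, raw = raw)
}
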