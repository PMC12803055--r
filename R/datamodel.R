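# Shared domain types. These are deliberately lightweight validated lists
# (the style of limma's EList) so that every downstream stage can rely on a
# fixed contract: cell_ids are unique, ordered, and canonical for all
# row-aligned matrices.

#' Construct an EmbeddingSet
#'
#' An `EmbeddingSet` holds a cells x d numeric matrix of per-cell embedding
#' vectors together with the aligned, unique cell identifiers. The row order
#' of `matrix` follows `cell_ids` and is canonical for all downstream
#' computations.
#'
#' @param cell_ids character vector of unique cell identifiers.
#' @param matrix numeric matrix, one row per cell, d columns.
#' @return An object of class `EmbeddingSet` with fields `cell_ids`,
#'   `matrix`, `dim`.
#' @export
embedding_set <- function(cell_ids, matrix) {
  cell_ids <- as.character(cell_ids)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  assert_that(nrow(matrix) == length(cell_ids),
              "embedding row count must equal number of cell_ids")
  assert_that(!anyDuplicated(cell_ids), "cell_ids must be unique")
  assert_that(all(is.finite(matrix)), "embedding contains non-finite values")
  assert_that(ncol(matrix) >= 1L, "embedding must have at least one dimension")
  rownames(matrix) <- cell_ids
  structure(list(cell_ids = cell_ids, matrix = matrix, dim = ncol(matrix)),
            class = "EmbeddingSet")
}

#' @export
print.EmbeddingSet <- function(x, ...) {
  cat(sprintf("EmbeddingSet: %d cells x %d dims\n", length(x$cell_ids), x$dim))
  invisible(x)
}

#' Construct CellAnnotations
#'
#' Per-cell metadata aligned 1:1 with `cell_ids`: the cell-type label,
#' optional batch and perturbation-condition labels (the level `"control"`
#' is reserved for unperturbed cells), and optional 2-D spatial coordinates.
#'
#' @param cell_ids character vector of unique cell identifiers.
#' @param cell_type character/factor vector of cell-type labels.
#' @param batch optional character/factor vector of batch labels.
#' @param condition optional character/factor vector of condition labels.
#' @param spatial_xy optional numeric matrix with 2 columns (x, y).
#' @return An object of class `CellAnnotations`.
#' @export
cell_annotations <- function(cell_ids, cell_type, batch = NULL,
                             condition = NULL, spatial_xy = NULL) {
  cell_ids <- as.character(cell_ids)
  n <- length(cell_ids)
  assert_that(!anyDuplicated(cell_ids), "cell_ids must be unique")
  chk <- function(v, what) {
    v <- as.character(v)
    assert_that(length(v) == n, sprintf("%s must align with cell_ids", what))
    assert_that(all(!is.na(v) & nzchar(v)),
                sprintf("%s levels must be non-empty strings", what))
    v
  }
  cell_type <- chk(cell_type, "cell_type")
  if (!is.null(batch)) batch <- chk(batch, "batch")
  if (!is.null(condition)) condition <- chk(condition, "condition")
  if (!is.null(spatial_xy)) {
    spatial_xy <- as.matrix(spatial_xy)
    storage.mode(spatial_xy) <- "double"
    assert_that(nrow(spatial_xy) == n && ncol(spatial_xy) == 2L,
                "spatial_xy must be an n x 2 matrix")
    assert_that(all(is.finite(spatial_xy)), "spatial_xy must be finite")
    rownames(spatial_xy) <- cell_ids
  }
  structure(list(cell_ids = cell_ids, cell_type = cell_type, batch = batch,
                 condition = condition, spatial_xy = spatial_xy),
            class = "CellAnnotations")
}

#' @export
print.CellAnnotations <- function(x, ...) {
  cat(sprintf(
    "CellAnnotations: %d cells, %d cell types%s%s%s\n",
    length(x$cell_ids), length(unique(x$cell_type)),
    if (!is.null(x$batch)) sprintf(", %d batches", length(unique(x$batch))) else "",
    if (!is.null(x$condition)) sprintf(", %d conditions", length(unique(x$condition))) else "",
    if (!is.null(x$spatial_xy)) ", spatial" else ""))
  invisible(x)
}

#' Construct a CountMatrix
#'
#' Cells x genes non-negative expression values with aligned cell and gene
#' identifiers. Values need not be integers (log-normalized tables are
#' accepted wherever a CountMatrix is, and are flagged by `assay`).
#'
#' @param cell_ids unique cell identifiers (rows).
#' @param gene_ids unique gene identifiers (columns).
#' @param counts numeric matrix, cells x genes, values >= 0 for raw counts.
#' @param assay `"counts"` (non-negative enforced) or `"logexpr"`.
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(cell_ids, gene_ids, counts, assay = c("counts", "logexpr")) {
  assay <- match.arg(assay)
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  assert_that(!anyDuplicated(cell_ids), "cell_ids must be unique")
  assert_that(!anyDuplicated(gene_ids), "gene_ids must be unique")
  assert_that(nrow(counts) == length(cell_ids) && ncol(counts) == length(gene_ids),
              "counts dimensions must match cell_ids x gene_ids")
  assert_that(all(is.finite(counts)), "counts contain non-finite values")
  if (assay == "counts") {
    assert_that(all(counts >= 0), "raw counts must be non-negative")
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(cell_ids = cell_ids, gene_ids = gene_ids, counts = counts,
                 assay = assay),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix (%s): %d cells x %d genes\n",
              x$assay, length(x$cell_ids), length(x$gene_ids)))
  invisible(x)
}

#' Construct a SplitAssignment
#'
#' Pairwise-disjoint train / validation / test cell-id sets plus the seed
#' that produced them.
#'
#' @param train_ids,val_ids,test_ids character vectors of cell ids.
#' @param seed integer seed recorded for provenance.
#' @return An object of class `SplitAssignment`.
#' @export
split_assignment <- function(train_ids, val_ids = character(), test_ids, seed = NA_integer_) {
  train_ids <- as.character(train_ids)
  val_ids <- as.character(val_ids)
  test_ids <- as.character(test_ids)
  all_ids <- c(train_ids, val_ids, test_ids)
  assert_that(!anyDuplicated(all_ids),
              "train/val/test sets must be pairwise disjoint")
  structure(list(train_ids = train_ids, val_ids = val_ids,
                 test_ids = test_ids, seed = as.integer(seed)),
            class = "SplitAssignment")
}

#' @export
print.SplitAssignment <- function(x, ...) {
  cat(sprintf("SplitAssignment: %d train / %d val / %d test (seed %s)\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids),
              x$seed))
  invisible(x)
}

#' Subset annotations to a set of cell ids (order of `ids` preserved)
#' @param ann A [cell_annotations()] object.
#' @param ids Cell ids to keep, in the desired order.
#' @return A `CellAnnotations` restricted to `ids`.
#' @export
subset_annotations <- function(ann, ids) {
  idx <- match(ids, ann$cell_ids)
  assert_that(!anyNA(idx), "unknown cell ids in subset")
  cell_annotations(
    cell_ids = ann$cell_ids[idx],
    cell_type = ann$cell_type[idx],
    batch = ann$batch[idx],
    condition = ann$condition[idx],
    spatial_xy = if (!is.null(ann$spatial_xy)) ann$spatial_xy[idx, , drop = FALSE]
  )
}

#' Subset an EmbeddingSet by cell ids (order of `ids` preserved)
#' @param emb An [embedding_set()].
#' @param ids Cell ids to keep.
#' @return An `EmbeddingSet` restricted to `ids`.
#' @export
subset_embedding <- function(emb, ids) {
  idx <- match(ids, emb$cell_ids)
  assert_that(!anyNA(idx), "unknown cell ids in subset")
  embedding_set(emb$cell_ids[idx], emb$matrix[idx, , drop = FALSE])
}
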