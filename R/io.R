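# Dataset container I/O. The native on-disk format is a plain-text directory
# (TSV matrices + a JSON manifest) that round-trips bit-exactly for
# identifiers and to full double precision for values. Annotated-matrix
# h5ad containers are supported through a bundled Python bridge that uses
# the anndata library (observation metadata keys "cell_type", "batch",
# "condition"; embeddings under obsm key "X_emb" by default; counts in X or
# layer "counts"; spatial coordinates under obsm "spatial").

DATASET_MANIFEST <- "manifest.json"

#' Assemble a dataset container
#'
#' @param annotations A [cell_annotations()] (required).
#' @param embedding optional [embedding_set()] sharing the same cell order.
#' @param counts optional [count_matrix()] sharing the same cell order.
#' @return A `Dataset` list.
#' @export
dataset <- function(annotations, embedding = NULL, counts = NULL) {
  stopifnot(inherits(annotations, "CellAnnotations"))
  assert_that(!is.null(embedding) || !is.null(counts),
              "at least one of embedding or counts must be present")
  if (!is.null(embedding)) {
    stopifnot(inherits(embedding, "EmbeddingSet"))
    assert_that(identical(embedding$cell_ids, annotations$cell_ids),
                "embedding and annotations must share cell_id order")
  }
  if (!is.null(counts)) {
    stopifnot(inherits(counts, "CountMatrix"))
    assert_that(identical(counts$cell_ids, annotations$cell_ids),
                "counts and annotations must share cell_id order")
  }
  structure(list(annotations = annotations, embedding = embedding,
                 counts = counts),
            class = "Dataset")
}

write_num_tsv <- function(M, path) {
  df <- data.frame(cell_id = rownames(M),
                   format(M, digits = 17, scientific = TRUE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_num_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- df[[1]]
  M
}

#' Write a dataset container
#'
#' `path` ending in `.h5ad` writes an annotated-matrix container through the
#' Python bridge; any other path is treated as a directory in the native
#' plain-text format.
#'
#' @param d A [dataset()].
#' @param path output directory or `.h5ad` file.
#' @param emb_key obsm key for the embedding in h5ad output (default
#'   `"X_emb"`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(d, path, emb_key = "X_emb") {
  stopifnot(inherits(d, "Dataset"))
  if (grepl("\\.h5ad$", path)) {
    tmp <- tempfile("scembed_ds_")
    on.exit(unlink(tmp, recursive = TRUE))
    write_dataset_dir(d, tmp)
    h5ad_bridge("import", tmp, path, emb_key)
    return(invisible(path))
  }
  write_dataset_dir(d, path)
}

write_dataset_dir <- function(d, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ann <- d$annotations
  obs <- data.frame(cell_id = ann$cell_ids, cell_type = ann$cell_type,
                    stringsAsFactors = FALSE)
  if (!is.null(ann$batch)) obs$batch <- ann$batch
  if (!is.null(ann$condition)) obs$condition <- ann$condition
  if (!is.null(ann$spatial_xy)) {
    obs$spatial_x <- format(ann$spatial_xy[, 1], digits = 17, trim = TRUE)
    obs$spatial_y <- format(ann$spatial_xy[, 2], digits = 17, trim = TRUE)
  }
  utils::write.table(obs, file.path(path, "obs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(format = "scembedeval-dataset", version = 1,
                   n_cells = length(ann$cell_ids),
                   has_embedding = !is.null(d$embedding),
                   has_counts = !is.null(d$counts))
  if (!is.null(d$embedding)) {
    write_num_tsv(d$embedding$matrix, file.path(path, "embedding.tsv"))
  }
  if (!is.null(d$counts)) {
    write_num_tsv(d$counts$counts, file.path(path, "counts.tsv"))
    manifest$counts_assay <- d$counts$assay
  }
  jsonlite::write_json(manifest, file.path(path, DATASET_MANIFEST),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Load a dataset container
#'
#' Reads the native plain-text directory format, or a `.h5ad` container via
#' the Python bridge. All returned objects share identical cell-id order;
#' missing optional fields are absent (NULL), never fabricated. Duplicated
#' cell identifiers raise a format error; non-finite embedding values raise
#' a validation error.
#'
#' @param path dataset directory or `.h5ad` file.
#' @param emb_key obsm key holding the embedding in h5ad input.
#' @return A [dataset()] with fields `annotations`, `embedding` (or NULL),
#'   `counts` (or NULL).
#' @export
load_dataset <- function(path, emb_key = "X_emb") {
  if (grepl("\\.h5ad$", path)) {
    tmp <- tempfile("scembed_ds_")
    on.exit(unlink(tmp, recursive = TRUE))
    h5ad_bridge("export", path, tmp, emb_key)
    path <- tmp
  }
  mf_path <- file.path(path, DATASET_MANIFEST)
  assert_that(file.exists(mf_path),
              sprintf("'%s' is not a dataset container (missing manifest)", path))
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  obs <- utils::read.table(file.path(path, "obs.tsv"), sep = "\t",
                           header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (anyDuplicated(obs$cell_id)) {
    stop("format error: duplicated cell identifiers", call. = FALSE)
  }
  spatial <- NULL
  if (all(c("spatial_x", "spatial_y") %in% names(obs))) {
    spatial <- cbind(as.numeric(obs$spatial_x), as.numeric(obs$spatial_y))
  }
  ann <- cell_annotations(obs$cell_id, obs$cell_type,
                          batch = obs[["batch"]],
                          condition = obs[["condition"]],
                          spatial_xy = spatial)
  emb <- NULL
  if (isTRUE(manifest$has_embedding)) {
    M <- read_num_tsv(file.path(path, "embedding.tsv"))
    assert_that(identical(rownames(M), ann$cell_ids),
                "embedding rows must match obs cell order")
    emb <- embedding_set(rownames(M), M)
  }
  cm <- NULL
  if (isTRUE(manifest$has_counts)) {
    M <- read_num_tsv(file.path(path, "counts.tsv"))
    assert_that(identical(rownames(M), ann$cell_ids),
                "counts rows must match obs cell order")
    cm <- count_matrix(rownames(M), colnames(M), M,
                       assay = manifest$counts_assay %||% "counts")
  }
  dataset(ann, embedding = emb, counts = cm)
}

h5ad_bridge <- function(verb, from, to, emb_key = "X_emb") {
  script <- system.file("python", "h5ad_bridge.py", package = "scembedeval")
  assert_that(nzchar(script), "bundled h5ad bridge script not found")
  python <- Sys.getenv("SCEMBEDEVAL_PYTHON", "python")
  out <- suppressWarnings(
    system2(python, c(shQuote(script), verb, shQuote(from), shQuote(to),
                      shQuote(emb_key)),
            stdout = TRUE, stderr = TRUE)
  )
  status <- attr(out, "status") %||% 0L
  if (status != 0) {
    stop("h5ad bridge failed: ", paste(out, collapse = "\n"), call. = FALSE)
  }
  invisible(NULL)
}
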