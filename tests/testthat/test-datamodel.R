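# Domain types, container I/O and split protocols.

test_that("constructors enforce their invariants", {
  expect_error(embedding_set(c("a", "a"), matrix(0, 2, 2)), "unique")
  expect_error(embedding_set(c("a", "b"), matrix(c(0, NA), 2, 1)),
               "non-finite")
  expect_error(embedding_set(c("a", "b"), matrix(0, 3, 1)), "row count")
  expect_error(cell_annotations(c("a", "b"), c("t", "")), "non-empty")
  expect_error(count_matrix("a", c("g1", "g2"), matrix(-1, 1, 2)),
               "non-negative")
  expect_error(split_assignment(c("a", "b"), test_ids = c("b")), "disjoint")
  expect_error(dataset(cell_annotations("a", "t")), "at least one")
})

test_that("text-directory round trip preserves all fields", {
  mix <- make_mixture_embeddings(mixture_spec(
    n_cells = 30, n_types = 2, n_batches = 2, dim = 4,
    type_separation = 5, batch_shift = 1, seed = 1))
  cm <- count_matrix(mix$annotations$cell_ids, paste0("g", 1:5),
                     matrix(rpois(150, 3), 30, 5))
  d <- dataset(mix$annotations, embedding = mix$embedding, counts = cm)
  path <- withr::local_tempdir()
  write_dataset(d, path)
  d2 <- load_dataset(path)
  expect_identical(d2$annotations$cell_ids, d$annotations$cell_ids)
  expect_identical(d2$annotations$cell_type, d$annotations$cell_type)
  expect_identical(d2$annotations$batch, d$annotations$batch)
  expect_lt(max(abs(d2$embedding$matrix - d$embedding$matrix)), 1e-12)
  expect_lt(max(abs(d2$counts$counts - cm$counts)), 1e-12)
  expect_identical(d2$counts$gene_ids, cm$gene_ids)
})

test_that("h5ad round trip via the python bridge preserves the dataset", {
  mix <- make_mixture_embeddings(mixture_spec(
    n_cells = 25, n_types = 2, n_batches = 2, dim = 3,
    type_separation = 4, batch_shift = 0.5, seed = 2))
  sp_xy <- cbind(runif(25), runif(25))
  ann <- cell_annotations(mix$annotations$cell_ids, mix$annotations$cell_type,
                          batch = mix$annotations$batch, spatial_xy = sp_xy)
  d <- dataset(ann, embedding = mix$embedding)
  f <- withr::local_tempfile(fileext = ".h5ad")
  write_dataset(d, f)
  d2 <- load_dataset(f)
  expect_identical(d2$annotations$cell_ids, d$annotations$cell_ids)
  expect_identical(d2$annotations$batch, d$annotations$batch)
  expect_lt(max(abs(d2$embedding$matrix - d$embedding$matrix)), 1e-12)
  expect_lt(max(abs(d2$annotations$spatial_xy - sp_xy)), 1e-12)
  expect_null(d2$counts)
})

test_that("counts-only container loads without fabricating an embedding", {
  ann <- cell_annotations(c("c1", "c2"), c("a", "b"))
  cm <- count_matrix(c("c1", "c2"), c("g1", "g2"), matrix(1:4, 2, 2))
  path <- withr::local_tempdir()
  write_dataset(dataset(ann, counts = cm), path)
  d <- load_dataset(path)
  expect_null(d$embedding)
  expect_s3_class(d$counts, "CountMatrix")
})

test_that("duplicated cell identifiers raise a format error", {
  path <- withr::local_tempdir()
  ann <- cell_annotations(c("c1", "c2"), c("a", "b"))
  cm <- count_matrix(c("c1", "c2"), "g1", matrix(1:2, 2, 1))
  write_dataset(dataset(ann, counts = cm), path)
  obs <- readLines(file.path(path, "obs.tsv"))
  writeLines(c(obs, obs[2]), file.path(path, "obs.tsv"))
  expect_error(load_dataset(path), "format error")
})

test_that("stratified_split respects fractions, coverage and determinism", {
  ann <- cell_annotations(sprintf("c%03d", 1:100),
                          rep(c("A", "B"), each = 50))
  sp <- stratified_split(ann, test_fraction = 0.2, seed = 1)
  expect_length(sp$train_ids, 80)
  expect_length(sp$test_ids, 20)
  types <- ann$cell_type[match(sp$test_ids, ann$cell_ids)]
  expect_equal(as.vector(table(types)), c(10, 10))
  sp2 <- stratified_split(ann, test_fraction = 0.2, seed = 1)
  expect_identical(sp, sp2)

  # per-class rounding: {A:50, B:10} at 0.2 -> 10 A + 2 B in test
  ann2 <- cell_annotations(sprintf("d%02d", 1:60),
                           rep(c("A", "B"), c(50, 10)))
  sp3 <- stratified_split(ann2, test_fraction = 0.2, seed = 3)
  t3 <- table(ann2$cell_type[match(sp3$test_ids, ann2$cell_ids)])
  expect_equal(as.vector(t3), c(10, 2))
})

test_that("stratified_split properties hold over random cases", {
  withr::local_seed(99)
  for (rep in 1:10) {
    n <- sample(30:80, 1)
    ann <- cell_annotations(sprintf("c%03d", seq_len(n)),
                            sample(c("A", "B", "C"), n, replace = TRUE,
                                   prob = c(.5, .3, .2)))
    sp <- stratified_split(ann, test_fraction = 0.25, val_fraction = 0.2,
                           seed = rep)
    all_ids <- c(sp$train_ids, sp$val_ids, sp$test_ids)
    expect_setequal(all_ids, ann$cell_ids)
    tr_types <- unique(ann$cell_type[match(sp$train_ids, ann$cell_ids)])
    te_types <- unique(ann$cell_type[match(sp$test_ids, ann$cell_ids)])
    va_types <- unique(ann$cell_type[match(sp$val_ids, ann$cell_ids)])
    expect_true(all(te_types %in% tr_types))
    expect_true(all(va_types %in% tr_types))
  }
})

test_that("a singleton class stays in train with a warning", {
  ann <- cell_annotations(c("c1", "c2", "c3", "c4", "c5"),
                          c("A", "A", "A", "A", "B"))
  expect_warning(sp <- stratified_split(ann, 0.25, seed = 1), "single cell")
  expect_true("c5" %in% sp$train_ids)
})

test_that("perturbation_split follows the doubles/singles rules", {
  singles <- sprintf("G%d", 1:8)
  doubles <- apply(combn(singles, 2)[, 1:12], 2, paste, collapse = "+")
  sp <- perturbation_split(c("control", singles, doubles), seed = 0)
  expect_setequal(intersect(sp$train_ids, singles), singles)
  expect_length(setdiff(sp$train_ids, singles), 6)   # floor(12/2)
  expect_length(sp$test_ids, 6)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_false("control" %in% c(sp$train_ids, sp$test_ids))
  sp2 <- perturbation_split(c("control", singles, doubles), seed = 0)
  expect_identical(sp, sp2)

  # singles only: 75% / 25%
  sp3 <- perturbation_split(c("control", singles), seed = 1)
  expect_length(sp3$train_ids, 6)
  expect_length(sp3$test_ids, 2)
  expect_error(perturbation_split(c("control")), "no perturbation")
})

test_that("perturbation_split halving is exact for odd double counts", {
  withr::local_seed(5)
  singles <- sprintf("G%d", 1:6)
  for (nd in c(3, 5, 9)) {
    doubles <- apply(combn(singles, 2)[, seq_len(nd)], 2, paste,
                     collapse = "+")
    sp <- perturbation_split(c(singles, doubles), seed = nd)
    expect_length(setdiff(sp$train_ids, singles), floor(nd / 2))
    expect_setequal(c(setdiff(sp$train_ids, singles), sp$test_ids), doubles)
  }
})
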