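# Train/validation/test split protocols. Splits are stratified by cell type
# so every label present in test (and val) is also represented in train, and
# are fully determined by the seed.

#' Stratified train/validation/test split by cell type
#'
#' Cells are partitioned per cell-type level: round(test_fraction * n_c)
#' cells go to test (clipped so at least one train cell remains per class),
#' then round(val_fraction * remaining) to validation, the rest to train.
#' A class with a single cell is kept entirely in train with a warning.
#'
#' @param ann A [cell_annotations()] object; every cell must have a cell type.
#' @param test_fraction real in (0,1).
#' @param val_fraction real in `[0,1)`; validation cells are drawn stratified
#'   from the non-test remainder.
#' @param seed integer; the split is deterministic given the seed.
#' @return A [split_assignment()].
#' @export
stratified_split <- function(ann, test_fraction, val_fraction = 0, seed = 0L) {
  assert_that(test_fraction > 0 && test_fraction < 1,
              "test_fraction must be in (0,1)")
  assert_that(val_fraction >= 0 && val_fraction < 1,
              "val_fraction must be in [0,1)")
  ids <- ann$cell_ids
  type <- ann$cell_type
  train <- val <- test <- character()
  with_seed(seed, {
    for (lev in sort(unique(type))) {
      cls <- ids[type == lev]
      n_c <- length(cls)
      if (n_c == 1L) {
        warning(sprintf("class '%s' has a single cell; kept entirely in train", lev))
        train <- c(train, cls)
        next
      }
      n_test <- round(test_fraction * n_c)
      n_test <- min(n_test, n_c - 1L)        # >= 1 train cell per class
      perm <- sample(cls)
      test <- c(test, perm[seq_len(n_test)])
      rest <- perm[setdiff(seq_len(n_c), seq_len(n_test))]
      n_val <- round(val_fraction * length(rest))
      n_val <- min(n_val, length(rest) - 1L) # keep the class in train
      if (n_val > 0) {
        val <- c(val, rest[seq_len(n_val)])
        rest <- rest[-seq_len(n_val)]
      }
      train <- c(train, rest)
    }
  })
  keep_order <- function(v) ids[ids %in% v]
  split_assignment(keep_order(train), keep_order(val), keep_order(test),
                   seed = seed)
}

#' Parse a perturbation condition label
#'
#' Conditions follow the `"control"` / `"GENE"` / `"GENE1+GENE2"` dialect.
#'
#' @param x character vector of condition labels.
#' @return data.frame with columns `condition`, `kind`
#'   (control/single/double), `gene1`, `gene2`.
#' @export
parse_conditions <- function(x) {
  x <- as.character(x)
  parts <- strsplit(x, "+", fixed = TRUE)
  n_genes <- lengths(parts)
  assert_that(all(n_genes <= 2L),
              "conditions with more than two target genes are not supported")
  kind <- ifelse(x == "control", "control",
                 ifelse(n_genes == 2L, "double", "single"))
  data.frame(
    condition = x,
    kind = kind,
    gene1 = ifelse(kind == "control", NA_character_,
                   vapply(parts, `[`, character(1), 1L)),
    gene2 = ifelse(kind == "double",
                   vapply(parts, function(p) p[2L], character(1)),
                   NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Train/test split for perturbation-response prediction
#'
#' When double perturbations are present, training uses all single-gene
#' perturbations plus a seeded random floor(n/2) of the double perturbations;
#' the remaining doubles form the test set. With singles only, 75% of
#' perturbed samples are selected for training and 25% for testing. Control
#' cells are not assigned to either set: they remain available to both
#' phases (as the counterfactual background).
#'
#' @param conditions character vector: one condition label per sample, or the
#'   unique condition names themselves.
#' @param seed integer seed for the random half / 75% selection.
#' @return A [split_assignment()] over condition labels (train_ids/test_ids
#'   are condition names when `conditions` are condition-level, otherwise
#'   sample indices are grouped by their condition's assignment).
#' @export
perturbation_split <- function(conditions, seed = 0L) {
  info <- parse_conditions(unique(as.character(conditions)))
  pert <- info[info$kind != "control", , drop = FALSE]
  assert_that(nrow(pert) > 0, "no perturbation conditions present")
  singles <- pert$condition[pert$kind == "single"]
  doubles <- pert$condition[pert$kind == "double"]
  if (length(doubles) > 0) {
    n_train_d <- floor(length(doubles) / 2)
    train_d <- with_seed(seed, sample(doubles, n_train_d))
    train <- c(singles, sort(train_d))
    test <- setdiff(doubles, train_d)
  } else {
    n_train <- round(0.75 * length(singles))
    train <- sort(with_seed(seed, sample(singles, n_train)))
    test <- setdiff(singles, train)
  }
  split_assignment(train_ids = train, test_ids = test, seed = seed)
}
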