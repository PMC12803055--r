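# Counterfactual construction, ridge response model, additive baseline,
# response metrics.

pert_fixture <- function(seed = 0, ...) {
  make_perturbation_fixture(perturb_fixture_spec(seed = seed, ...))
}

test_that("counterfactuals differ from control only in target columns", {
  px <- pert_fixture(n_genes = 30, single_genes = sprintf("G%02d", 1:4))
  cf <- construct_counterfactuals(px$expr, px$annotations, n_control = 20,
                                  seed = 1)
  single <- cf$counterfactuals[["G01"]]
  diffs <- which(colSums(abs(single - cf$control)) > 0)
  expect_identical(colnames(cf$control)[diffs], "G01")
  dbl_name <- names(cf$counterfactuals)[grepl("\\+", names(cf$counterfactuals))][1]
  pair <- strsplit(dbl_name, "+", fixed = TRUE)[[1]]
  dbl <- cf$counterfactuals[[dbl_name]]
  diffs2 <- which(colSums(abs(dbl - cf$control)) > 0)
  expect_setequal(colnames(cf$control)[diffs2], pair)
  # determinism
  cf2 <- construct_counterfactuals(px$expr, px$annotations, n_control = 20,
                                   seed = 1)
  expect_identical(cf, cf2)
})

test_that("missing target genes are reported by name", {
  px <- pert_fixture(n_genes = 20, single_genes = sprintf("G%02d", 1:3))
  ann <- px$annotations
  ann$condition[ann$condition == "G01"] <- "NOPE"
  ann$cell_type[ann$cell_type == "G01"] <- "NOPE"
  expect_error(construct_counterfactuals(px$expr, ann, seed = 1), "NOPE")
})

test_that("additive baseline is a symmetric vector sum", {
  px <- pert_fixture(n_genes = 25, single_genes = sprintf("G%02d", 1:4))
  split <- perturbation_split(px$annotations$condition, seed = 0)
  tab <- condition_table(px$expr, px$annotations, split = split)
  pair <- c("G01", "G02")
  a <- additive_baseline(tab, pair)
  b <- additive_baseline(tab, rev(pair))
  expect_equal(a, b, tolerance = 1e-12)
  r1 <- tab$y[match("G01", tab$conditions$condition), ]
  r2 <- tab$y[match("G02", tab$conditions$condition), ]
  expect_equal(a, r1 + r2, tolerance = 1e-12)
  expect_error(additive_baseline(tab, c("G01", "ZZZ")), "ZZZ")
})

test_that("response metric identities hold", {
  expect_equal(response_metrics(1:5, 1:5), list(l2 = 0, pearson = 1))
  y <- c(0, 0, 0, 0)
  yh <- c(3, 4, 0, 0)
  expect_equal(response_metrics(yh, y + 1e-9 * seq_along(y))$l2, 5,
               tolerance = 1e-6)
  y2 <- rnorm(10)
  expect_equal(response_metrics(2 * y2 + 1, y2)$pearson, 1,
               tolerance = 1e-12)
  expect_warning(m <- response_metrics(1:3, c(2, 2, 2)), "constant")
  expect_true(is.na(m$pearson))
})

test_that("ridge with vanishing penalty matches the least-squares oracle", {
  withr::local_seed(51)
  px <- pert_fixture(n_genes = 40, single_genes = sprintf("G%02d", 1:6),
                     embed_dim = 10)
  split <- perturbation_split(px$annotations$condition, seed = 0)
  tab <- condition_table(px$expr, px$annotations, split = split)
  cf <- construct_counterfactuals(px$expr, px$annotations, seed = 0)
  W <- px$embedding_map
  cond_emb <- t(sapply(names(cf$counterfactuals), function(cn) {
    colMeans(cf$counterfactuals[[cn]] %*% W)
  }))
  fit <- suppressWarnings(
    fit_predict_responses(cond_emb, tab, n_pc = 6, ridge_alpha = 1e-10))
  # oracle: lm on the same reduced features
  m <- fit$model
  Z <- sweep(sweep(cond_emb, 2, m$center, "-"), 2, m$scale, "/") %*% m$rotation
  train_cn <- tab$conditions$condition[tab$conditions$split == "train"]
  test_cn <- rownames(fit$predictions)
  ols <- lm(tab$y[match(train_cn, tab$conditions$condition), ] ~
              Z[train_cn, ])
  pred_oracle <- cbind(1, Z[test_cn, ]) %*% coef(ols)
  expect_equal(unname(fit$predictions), unname(pred_oracle),
               tolerance = 1e-6)
})

test_that("infinite shrinkage collapses predictions to the train mean", {
  px <- pert_fixture(n_genes = 30, single_genes = sprintf("G%02d", 1:5))
  split <- perturbation_split(px$annotations$condition, seed = 0)
  tab <- condition_table(px$expr, px$annotations, split = split)
  cf <- construct_counterfactuals(px$expr, px$annotations, seed = 0)
  W <- px$embedding_map
  cond_emb <- t(sapply(names(cf$counterfactuals), function(cn) {
    colMeans(cf$counterfactuals[[cn]] %*% W)
  }))
  fit <- suppressWarnings(
    fit_predict_responses(cond_emb, tab, n_pc = 5, ridge_alpha = 1e9))
  train_cn <- tab$conditions$condition[tab$conditions$split == "train"]
  ybar <- colMeans(tab$y[match(train_cn, tab$conditions$condition), ])
  for (cn in rownames(fit$predictions)) {
    expect_equal(unname(fit$predictions[cn, ]), unname(ybar),
                 tolerance = 1e-4)
  }
})

test_that("end-to-end recovery on the additive fixture", {
  px <- pert_fixture()   # 100 genes, 8 singles, 12 doubles, interaction 0
  W <- px$embedding_map
  res <- suppressWarnings(perturbation_pipeline(
    px$expr, px$annotations, function(M) M %*% W, seed = 0))
  expect_gte(res$mean_pearson, 0.99)
  expect_lte(res$mean_l2, 1.1 * res$mean_additive_l2)
})

test_that("large interaction scale degrades the additive baseline", {
  small <- pert_fixture(interaction_scale = 0)
  large <- pert_fixture(interaction_scale = 2)
  W <- small$embedding_map
  r_small <- suppressWarnings(perturbation_pipeline(
    small$expr, small$annotations, function(M) M %*% W, seed = 0))
  W2 <- large$embedding_map
  r_large <- suppressWarnings(perturbation_pipeline(
    large$expr, large$annotations, function(M) M %*% W2, seed = 0))
  expect_gt(r_large$mean_additive_l2, r_small$mean_additive_l2)
  expect_true(all(is.finite(r_large$per_condition$l2)))
})

test_that("condition row order does not change per-condition predictions", {
  px <- pert_fixture(n_genes = 30, single_genes = sprintf("G%02d", 1:5))
  W <- px$embedding_map
  split <- perturbation_split(px$annotations$condition, seed = 0)
  tab <- condition_table(px$expr, px$annotations, split = split)
  cf <- construct_counterfactuals(px$expr, px$annotations, seed = 0)
  cond_emb <- t(sapply(names(cf$counterfactuals), function(cn) {
    colMeans(cf$counterfactuals[[cn]] %*% W)
  }))
  f1 <- suppressWarnings(fit_predict_responses(cond_emb, tab))
  f2 <- suppressWarnings(
    fit_predict_responses(cond_emb[rev(seq_len(nrow(cond_emb))), ], tab))
  cns <- rownames(f1$predictions)
  expect_equal(f1$predictions[cns, ], f2$predictions[cns, ],
               tolerance = 1e-10)
})
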