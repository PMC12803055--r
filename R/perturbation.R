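# Counterfactual perturbation-response prediction: observed per-condition
# responses vs control, counterfactual transcriptome construction, ridge
# regression from reduced condition embeddings to gene-wise responses, the
# additive baseline for double perturbations, and L2/Pearson evaluation.

#' Build a ConditionTable of observed responses vs control
#'
#' The response space is the per-condition mean of log1p library-normalized
#' expression minus the control mean (tables with `assay = "logexpr"` are
#' used as-is). Control is excluded from the condition rows.
#'
#' @param expr A [count_matrix()].
#' @param ann A [cell_annotations()] with a `condition` field
#'   (`"control"` reserved).
#' @param split optional [perturbation_split()] over condition names; when
#'   given, per-condition split flags are recorded.
#' @return A `ConditionTable`: list with `conditions` (data.frame:
#'   condition, kind, gene1, gene2, split), `y` (conditions x genes matrix
#'   of observed mean responses), `control_mean`, `gene_ids`.
#' @export
condition_table <- function(expr, ann, split = NULL) {
  stopifnot(inherits(expr, "CountMatrix"))
  assert_that(!is.null(ann$condition), "annotations lack a condition field")
  X <- if (expr$assay == "logexpr") expr$counts else lognorm(expr$counts)
  cond <- ann$condition[match(expr$cell_ids, ann$cell_ids)]
  assert_that(any(cond == "control"), "no control cells present")
  ctrl_mean <- colMeans(X[cond == "control", , drop = FALSE])
  info <- parse_conditions(setdiff(unique(cond), "control"))
  y <- t(vapply(info$condition, function(cn) {
    colMeans(X[cond == cn, , drop = FALSE]) - ctrl_mean
  }, numeric(ncol(X))))
  info$split <- if (is.null(split)) NA_character_ else
    ifelse(info$condition %in% split$train_ids, "train",
           ifelse(info$condition %in% split$test_ids, "test", "none"))
  structure(list(conditions = info, y = y, control_mean = ctrl_mean,
                 gene_ids = expr$gene_ids),
            class = "ConditionTable")
}

#' Construct counterfactual transcriptomes per condition
#'
#' A fixed seeded subset of control cells serves as the shared background;
#' for each condition, only the targeted genes' values are overwritten with
#' values drawn (seeded) from that condition's observed cells, while all
#' other genes stay bit-identical to the control background.
#'
#' @param expr A [count_matrix()] (raw counts are log-normalized first).
#' @param ann A [cell_annotations()] with `condition`.
#' @param n_control background size (default 500; capped at the number of
#'   control cells).
#' @param seed integer.
#' @return list with `control` (background matrix) and `counterfactuals`
#'   (named list of matrices, one per non-control condition).
#' @export
construct_counterfactuals <- function(expr, ann, n_control = 500, seed = 0L) {
  stopifnot(inherits(expr, "CountMatrix"))
  X <- if (expr$assay == "logexpr") expr$counts else lognorm(expr$counts)
  cond <- ann$condition[match(expr$cell_ids, ann$cell_ids)]
  ctrl_rows <- which(cond == "control")
  assert_that(length(ctrl_rows) > 0, "no control cells present")
  n_bg <- min(n_control, length(ctrl_rows))
  bg_rows <- with_seed(seed, sample(ctrl_rows, n_bg))
  bg <- X[bg_rows, , drop = FALSE]
  info <- parse_conditions(setdiff(unique(cond), "control"))
  cf <- list()
  for (r in seq_len(nrow(info))) {
    cn <- info$condition[r]
    targets <- stats::na.omit(c(info$gene1[r], info$gene2[r]))
    missing <- setdiff(targets, expr$gene_ids)
    assert_that(length(missing) == 0,
                sprintf("target gene '%s' of condition '%s' absent from panel",
                        paste(missing, collapse = ","), cn))
    src <- X[cond == cn, targets, drop = FALSE]
    M <- bg
    draw <- with_seed(sub_seed(seed, r), {
      src[sample(nrow(src), n_bg, replace = nrow(src) < n_bg), , drop = FALSE]
    })
    M[, targets] <- draw
    cf[[cn]] <- M
  }
  list(control = bg, counterfactuals = cf)
}

#' Fit ridge regression from condition embeddings and predict responses
#'
#' Condition embeddings (mean embedding over each condition's counterfactual
#' cells) are standardized and projected to `n_pc` principal components,
#' both fitted on training conditions only; a ridge-regularized linear model
#' then maps the reduced embeddings to the observed responses. Predictions
#' are returned for the test conditions.
#'
#' @param cond_emb conditions x d matrix of condition-level embeddings with
#'   rownames = condition names.
#' @param table A [condition_table()] carrying observed responses and split
#'   flags (its `conditions$split` must mark train/test).
#' @param n_pc reduced dimensionality (default 50; reduced with a warning
#'   when training conditions are too few).
#' @param ridge_alpha ridge penalty: a non-negative number, or `"loocv"` to
#'   select the penalty over the log grid `10^(-6..2)` by closed-form
#'   leave-one-out cross-validation on the training conditions (the robust
#'   choice in the few-training-conditions regime).
#' @return list with `predictions` (test conditions x genes), `fitted`
#'   (train conditions x genes), `model` (a `ResponseModel`:
#'   standardization parameters, loadings, coefficients, `ridge_alpha`).
#' @export
fit_predict_responses <- function(cond_emb, table, n_pc = 50,
                                  ridge_alpha = 1.0) {
  stopifnot(inherits(table, "ConditionTable"))
  flags <- table$conditions$split
  train_cn <- table$conditions$condition[flags == "train"]
  test_cn <- table$conditions$condition[flags == "test"]
  assert_that(length(train_cn) >= 2, "need at least 2 training conditions")
  E <- as.matrix(cond_emb)
  assert_that(all(c(train_cn, test_cn) %in% rownames(E)),
              "cond_emb must cover every train/test condition")
  Etr <- E[train_cn, , drop = FALSE]
  mu <- colMeans(Etr)
  sd_ <- apply(Etr, 2, stats::sd); sd_[sd_ == 0 | is.na(sd_)] <- 1
  Z <- sweep(sweep(E, 2, mu, "-"), 2, sd_, "/")
  d_eff <- min(n_pc, length(train_cn) - 1L, ncol(E))
  if (d_eff < n_pc) {
    warning(sprintf("n_pc reduced to %d (limited training conditions)", d_eff))
  }
  pc <- stats::prcomp(Z[train_cn, , drop = FALSE], center = FALSE)
  rot <- pc$rotation[, seq_len(d_eff), drop = FALSE]
  R <- Z %*% rot
  Y <- table$y[match(train_cn, table$conditions$condition), , drop = FALSE]
  r_mu <- colMeans(R[train_cn, , drop = FALSE])
  y_mu <- colMeans(Y)
  Rc <- sweep(R[train_cn, , drop = FALSE], 2, r_mu, "-")
  Yc <- sweep(Y, 2, y_mu, "-")
  if (identical(ridge_alpha, "loocv")) {
    ridge_alpha <- select_ridge_loocv(Rc, Yc)
  }
  B <- solve(crossprod(Rc) + ridge_alpha * diag(d_eff), crossprod(Rc, Yc))
  predict_for <- function(cn) {
    Rt <- sweep(R[cn, , drop = FALSE], 2, r_mu, "-")
    sweep(Rt %*% B, 2, y_mu, "+")
  }
  preds <- predict_for(test_cn)
  rownames(preds) <- test_cn
  colnames(preds) <- table$gene_ids
  fitted <- predict_for(train_cn)
  rownames(fitted) <- train_cn
  model <- structure(list(center = mu, scale = sd_, rotation = rot,
                          reduced_center = r_mu, response_center = y_mu,
                          coefficients = B, ridge_alpha = ridge_alpha),
                     class = "ResponseModel")
  list(predictions = preds, fitted = fitted, model = model)
}

# closed-form leave-one-out PRESS for ridge on centered data; the hat
# diagonal gets +1/n for the (unpenalized) intercept absorbed by centering
select_ridge_loocv <- function(Rc, Yc, grid = 10^seq(-6, 2)) {
  n <- nrow(Rc)
  sv <- svd(Rc)
  press <- vapply(grid, function(a) {
    shr <- sv$d^2 / (sv$d^2 + a)
    H <- sv$u %*% (t(sv$u) * shr)
    E <- Yc - H %*% Yc
    h <- pmin(diag(H) + 1 / n, 1 - 1e-8)
    sum((E / (1 - h))^2)
  }, numeric(1))
  grid[which.min(press)]
}

#' Additive baseline for a double perturbation
#'
#' Predicts the response of `g1+g2` as `r(g1) + r(g2)`, where `r` is the
#' observed training single response (mode `"observed"`, the classical
#' additive baseline) or the model's prediction for the single
#' (mode `"predicted"`, supply `predictions`).
#'
#' @param table A [condition_table()].
#' @param pair character vector of the two single genes.
#' @param mode `"observed"` or `"predicted"`.
#' @param predictions matrix of model predictions with single-condition
#'   rownames (required for mode `"predicted"`).
#' @return numeric gene-wise additive prediction.
#' @export
additive_baseline <- function(table, pair, mode = c("observed", "predicted"),
                              predictions = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "ConditionTable"))
  assert_that(length(pair) == 2, "pair must name two single genes")
  singles <- table$conditions$condition[table$conditions$kind == "single"]
  missing <- setdiff(pair, singles)
  assert_that(length(missing) == 0,
              sprintf("single perturbation '%s' not available",
                      paste(missing, collapse = ",")))
  r <- if (mode == "observed") {
    function(g) table$y[match(g, table$conditions$condition), ]
  } else {
    assert_that(!is.null(predictions) && all(pair %in% rownames(predictions)),
                "mode 'predicted' requires predictions covering both singles")
    function(g) predictions[g, ]
  }
  r(pair[1]) + r(pair[2])
}

#' L2 error and Pearson correlation between responses
#'
#' @param yhat,y numeric vectors of equal length (gene-wise responses).
#' @return list with `l2` (Euclidean norm of the error) and `pearson`
#'   (NA with a warning when `y` is constant).
#' @export
response_metrics <- function(yhat, y) {
  assert_that(length(yhat) == length(y) && length(y) >= 2,
              "responses must have equal length >= 2")
  l2 <- sqrt(sum((yhat - y)^2))
  pearson <- if (stats::sd(y) == 0) {
    warning("observed response is constant: Pearson undefined")
    NA_real_
  } else if (stats::sd(yhat) == 0) {
    NA_real_
  } else {
    stats::cor(yhat, y)
  }
  list(l2 = l2, pearson = pearson)
}

#' End-to-end perturbation-response evaluation
#'
#' Chains the split protocol, observed-response table, counterfactual
#' construction, per-condition embedding (mean over counterfactual cells),
#' ridge regression and per-test-condition metrics, plus the additive
#' baseline for double-perturbation test conditions.
#'
#' @param expr A [count_matrix()].
#' @param ann A [cell_annotations()] with `condition`.
#' @param embed_fun function mapping a cells x genes matrix to a cells x d
#'   embedding matrix (e.g. `function(X) X %*% W`; the identity for the
#'   expression baseline).
#' @param n_control,n_pc,ridge_alpha see the stage functions; the pipeline
#'   defaults to `ridge_alpha = "loocv"` (self-tuned penalty).
#' @param seed integer driving split and counterfactual sampling.
#' @return list with `per_condition` (data.frame: condition, l2, pearson,
#'   additive_l2 for doubles), `mean_l2`, `mean_pearson`,
#'   `mean_additive_l2`, plus the intermediate `table`, `fit`, `split`.
#' @export
perturbation_pipeline <- function(expr, ann, embed_fun, n_control = 500,
                                  n_pc = 50, ridge_alpha = "loocv",
                                  seed = 0L) {
  split <- perturbation_split(ann$condition, seed = seed)
  tab <- condition_table(expr, ann, split = split)
  cf <- construct_counterfactuals(expr, ann, n_control = n_control,
                                  seed = seed)
  cond_emb <- t(vapply(names(cf$counterfactuals), function(cn) {
    colMeans(embed_fun(cf$counterfactuals[[cn]]))
  }, numeric(ncol(embed_fun(cf$control[1, , drop = FALSE])))))
  fit <- fit_predict_responses(cond_emb, tab, n_pc = n_pc,
                               ridge_alpha = ridge_alpha)
  test_cn <- rownames(fit$predictions)
  info <- tab$conditions
  rows <- lapply(test_cn, function(cn) {
    y <- tab$y[match(cn, info$condition), ]
    m <- response_metrics(fit$predictions[cn, ], y)
    add_l2 <- NA_real_
    if (info$kind[match(cn, info$condition)] == "double") {
      pair <- c(info$gene1[match(cn, info$condition)],
                info$gene2[match(cn, info$condition)])
      if (all(pair %in% info$condition[info$split == "train"])) {
        add_l2 <- response_metrics(additive_baseline(tab, pair), y)$l2
      }
    }
    data.frame(condition = cn, l2 = m$l2, pearson = m$pearson,
               additive_l2 = add_l2)
  })
  per_condition <- do.call(rbind, rows)
  list(per_condition = per_condition,
       mean_l2 = mean(per_condition$l2),
       mean_pearson = mean(per_condition$pearson, na.rm = TRUE),
       mean_additive_l2 = mean(per_condition$additive_l2, na.rm = TRUE),
       table = tab, fit = fit, split = split)
}
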