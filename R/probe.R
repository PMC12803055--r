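# The standardized supervised probe used for fine-tuning evaluation, and the
# classical HVG+PCA baseline embedding. The probe is a small multilayer
# perceptron (layer normalization -> dropout -> hidden affine + GELU ->
# output affine) trained with cross-entropy, an adaptive-moment optimizer,
# a cosine learning-rate schedule and early stopping on validation loss;
# the checkpoint with the lowest validation loss is returned. Implemented on
# base matrix algebra so training is deterministic given the seed.

#' Probe hyper-parameters
#'
#' The architecture is fixed; the numeric defaults are artifact decisions
#' (modest capacity suited to <= 1024-dim embeddings), all overridable.
#'
#' @param hidden_width hidden layer width (default 256).
#' @param dropout dropout rate on the normalized input (default 0.1).
#' @param learning_rate peak Adam learning rate (default 1e-3).
#' @param max_epochs cosine-schedule horizon (default 100).
#' @param patience early-stopping patience in epochs (default 10).
#' @param batch_size minibatch size (default 128).
#' @param val_fraction stratified validation fraction carved from train when
#'   the split has no validation set (default 0.2).
#' @param seed integer.
#' @return A `ProbeConfig` list.
#' @export
probe_config <- function(hidden_width = 256, dropout = 0.1,
                         learning_rate = 1e-3, max_epochs = 100,
                         patience = 10, batch_size = 128,
                         val_fraction = 0.2, seed = 0L) {
  assert_that(hidden_width >= 1 && learning_rate > 0 && max_epochs >= 1 &&
                patience >= 1 && batch_size >= 1,
              "probe hyper-parameters must be positive")
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0,1)")
  assert_that(val_fraction > 0 && val_fraction < 1,
              "val_fraction must be in (0,1)")
  structure(list(hidden_width = hidden_width, dropout = dropout,
                 learning_rate = learning_rate, max_epochs = max_epochs,
                 patience = patience, batch_size = batch_size,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "ProbeConfig")
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# layer norm forward; returns normalized input and cached moments
ln_forward <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+"),
       xhat = xhat, inv = inv)
}

probe_forward <- function(par, X, dropout_mask = NULL) {
  ln <- ln_forward(X, par$gamma, par$beta)
  y <- ln$out
  if (!is.null(dropout_mask)) y <- y * dropout_mask
  h <- sweep(y %*% par$W1, 2, par$b1, "+")
  a <- gelu(h)
  logits <- sweep(a %*% par$W2, 2, par$b2, "+")
  list(logits = logits, a = a, h = h, y = y, ln = ln)
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

ce_loss <- function(logits, y_idx) {
  P <- softmax_rows(logits)
  -mean(log(pmax(P[cbind(seq_len(nrow(P)), y_idx)], 1e-300)))
}

probe_init <- function(d, h, C) {
  # He-style fan-in scaling for the hidden layer
  list(gamma = rep(1, d), beta = rep(0, d),
       W1 = matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h),
       b1 = rep(0, h),
       W2 = matrix(stats::rnorm(h * C, sd = sqrt(1 / h)), h, C),
       b2 = rep(0, C))
}

probe_grads <- function(par, X, y_idx, dropout) {
  B <- nrow(X)
  mask <- if (dropout > 0) {
    matrix(stats::rbinom(B * ncol(X), 1, 1 - dropout), B, ncol(X)) /
      (1 - dropout)
  } else NULL
  fw <- probe_forward(par, X, mask)
  P <- softmax_rows(fw$logits)
  loss <- -mean(log(pmax(P[cbind(seq_len(B), y_idx)], 1e-300)))
  dlog <- P
  dlog[cbind(seq_len(B), y_idx)] <- dlog[cbind(seq_len(B), y_idx)] - 1
  dlog <- dlog / B
  gW2 <- crossprod(fw$a, dlog)
  gb2 <- colSums(dlog)
  da <- tcrossprod(dlog, par$W2)
  dh <- da * gelu_grad(fw$h)
  gW1 <- crossprod(fw$y, dh)
  gb1 <- colSums(dh)
  dy <- tcrossprod(dh, par$W1)
  if (!is.null(mask)) dy <- dy * mask
  xhat <- fw$ln$xhat
  ggamma <- colSums(dy * xhat)
  gbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, par$gamma, "*")
  # layer-norm backward (per-row means over features)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * fw$ln$inv
  list(loss = loss,
       grads = list(gamma = ggamma, beta = gbeta, W1 = gW1, b1 = gb1,
                    W2 = gW2, b2 = gb2, X = dX))
}

#' Train the standardized probe on fixed embeddings
#'
#' @param emb An [embedding_set()] covering at least the split's cells.
#' @param labels class label per cell of `emb` (aligned with
#'   `emb$cell_ids`).
#' @param split A [split_assignment()]; when `val_ids` is empty a stratified
#'   validation subset (`cfg$val_fraction`) is carved out of train.
#' @param cfg A [probe_config()].
#' @return A `ProbeModel`: fitted parameters, `classes`, `history`
#'   (per-epoch train/val loss), `best_epoch`, `config`.
#' @export
train_probe <- function(emb, labels, split, cfg = probe_config()) {
  stopifnot(inherits(emb, "EmbeddingSet"), inherits(split, "SplitAssignment"))
  labels <- as.character(labels)
  assert_that(length(labels) == length(emb$cell_ids),
              "labels must align with emb$cell_ids")
  lab_of <- stats::setNames(labels, emb$cell_ids)
  train_ids <- split$train_ids
  val_ids <- split$val_ids
  if (length(val_ids) == 0) {
    ann_tr <- cell_annotations(train_ids, lab_of[train_ids])
    inner <- stratified_split(ann_tr, test_fraction = cfg$val_fraction,
                              seed = sub_seed(cfg$seed, 1L))
    val_ids <- inner$test_ids
    train_ids <- inner$train_ids
  }
  Xtr <- emb$matrix[match(train_ids, emb$cell_ids), , drop = FALSE]
  Xva <- emb$matrix[match(val_ids, emb$cell_ids), , drop = FALSE]
  classes <- sort(unique(lab_of[train_ids]))
  assert_that(length(classes) >= 2, "need >= 2 classes in train")
  ytr <- match(lab_of[train_ids], classes)
  yva <- match(lab_of[val_ids], classes)
  assert_that(!anyNA(yva), "validation contains a class absent from train")

  d <- ncol(Xtr); h <- cfg$hidden_width; C <- length(classes)
  with_seed(cfg$seed, {
    par <- probe_init(d, h, C)
    mstate <- lapply(par, function(p) p * 0)
    vstate <- lapply(par, function(p) p * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    best <- list(par = par, val = Inf, epoch = 0L)
    stall <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      lr <- cfg$learning_rate * 0.5 *
        (1 + cos(pi * (epoch - 1) / cfg$max_epochs))
      ord <- sample(nrow(Xtr))
      ep_loss <- 0; nb <- 0
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        rows <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
        g <- probe_grads(par, Xtr[rows, , drop = FALSE], ytr[rows],
                         cfg$dropout)
        if (!is.finite(g$loss)) {
          stop("probe training diverged (non-finite loss) at epoch ", epoch)
        }
        ep_loss <- ep_loss + g$loss; nb <- nb + 1
        step <- step + 1
        for (nm in names(par)) {
          gr <- g$grads[[nm]]
          mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gr
          vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gr^2
          mhat <- mstate[[nm]] / (1 - b1^step)
          vhat <- vstate[[nm]] / (1 - b2^step)
          par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      val_loss <- ce_loss(probe_forward(par, Xva)$logits, yva)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = ep_loss / nb, val_loss = val_loss))
      if (val_loss < best$val) {
        best <- list(par = par, val = val_loss, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
    structure(list(parameters = best$par, classes = classes,
                   history = history, best_epoch = best$epoch,
                   best_val_loss = best$val, config = cfg,
                   input_dim = d),
              class = "ProbeModel")
  })
}

#' @export
print.ProbeModel <- function(x, ...) {
  cat(sprintf("ProbeModel: %d -> %d -> %d classes; best epoch %d (val loss %.4f)\n",
              x$input_dim, x$config$hidden_width, length(x$classes),
              x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Predict class probabilities with a trained probe
#'
#' @param model A `ProbeModel` from [train_probe()].
#' @param emb An [embedding_set()] with the model's input dimension.
#' @param truth optional ground-truth labels per cell; when omitted the
#'   `truth` field of the returned set is filled with the predictions (shape
#'   validity only) and should not be scored.
#' @return A [prediction_set()] with probability rows summing to 1 and
#'   predicted label = argmax.
#' @export
probe_predict <- function(model, emb, truth = NULL) {
  stopifnot(inherits(model, "ProbeModel"))
  X <- if (inherits(emb, "EmbeddingSet")) emb$matrix else as.matrix(emb)
  assert_that(ncol(X) == model$input_dim,
              "embedding dimension does not match the probe input")
  probs <- softmax_rows(probe_forward(model$parameters, X)$logits)
  colnames(probs) <- model$classes
  pred <- model$classes[apply(probs, 1, which.max)]
  ids <- if (inherits(emb, "EmbeddingSet")) emb$cell_ids else
    sprintf("c%d", seq_len(nrow(X)))
  prediction_set(ids, truth %||% pred, pred, probs)
}

#' HVG + PCA baseline embedding
#'
#' The classical pipeline: 2,000 highly variable genes selected on the
#' training split (dispersion-based ranking on log-normalized data),
#' library-size normalization, log1p, per-gene standardization, and PCA to
#' 50 dimensions - every statistic fitted on train cells only, with
#' validation/test cells projected through the fitted transform.
#'
#' @param counts A [count_matrix()].
#' @param split A [split_assignment()]; HVGs, scaling and loadings are
#'   functions of `train_ids` only.
#' @param n_hvg number of highly variable genes (default 2000; capped at the
#'   gene panel size with a warning).
#' @param n_pc output dimensionality (default 50; effective dimension is
#'   `min(n_pc, n_hvg, n_train - 1)`).
#' @return An [embedding_set()] over all cells of `counts`, in input order.
#' @export
hvg_pca_embed <- function(counts, split, n_hvg = 2000, n_pc = 50) {
  stopifnot(inherits(counts, "CountMatrix"))
  tr_idx <- match(split$train_ids, counts$cell_ids)
  assert_that(!anyNA(tr_idx) && length(tr_idx) > 1,
              "train split must be a non-empty subset of the counts cells")
  if (n_hvg > length(counts$gene_ids)) {
    warning("n_hvg exceeds the gene panel; using all genes")
    n_hvg <- length(counts$gene_ids)
  }
  raw <- counts$counts
  # per-cell library normalization; the scale target is a train statistic
  tot_tr <- rowSums(raw[tr_idx, , drop = FALSE])
  scale_to <- stats::median(tot_tr[tot_tr > 0])
  X <- lognorm(raw, scale_to = scale_to)
  hvg <- select_hvg(X[tr_idx, , drop = FALSE], n_hvg)
  Xh <- X[, hvg, drop = FALSE]
  mu <- colMeans(Xh[tr_idx, , drop = FALSE])
  sd_ <- apply(Xh[tr_idx, , drop = FALSE], 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Z <- sweep(sweep(Xh, 2, mu, "-"), 2, sd_, "/")
  d_eff <- min(n_pc, n_hvg, length(tr_idx) - 1L)
  pc <- stats::prcomp(Z[tr_idx, , drop = FALSE], center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(d_eff), drop = FALSE]
  embedding_set(counts$cell_ids, Z %*% rot)
}

# dispersion-based HVG ranking (classic recipe): dispersion = var/mean on
# log-normalized data, z-scored within 20 equal-frequency mean bins
select_hvg <- function(X, n_hvg) {
  m <- colMeans(X)
  v <- apply(X, 2, stats::var)
  disp <- ifelse(m > 0, v / m, 0)
  bins <- cut(rank(m, ties.method = "first"),
              breaks = min(20, ncol(X)), labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    sel <- bins == b
    mu <- mean(disp[sel]); sd_ <- stats::sd(disp[sel])
    z[sel] <- if (is.na(sd_) || sd_ == 0) 0 else (disp[sel] - mu) / sd_
  }
  colnames(X)[order(-z, seq_len(ncol(X)))][seq_len(n_hvg)]
}
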