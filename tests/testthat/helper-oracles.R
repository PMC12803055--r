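# Independent oracle implementations used throughout the suite. These are
# deliberately naive (explicit loops over cells, pairs, neighborhoods) and
# share no code with the package internals they check.

# ---- partition metrics by exhaustive pair counting / plug-in entropies ----

oracle_pair_counts <- function(u, v) {
  n <- length(u)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_u <- u[i] == u[j]
      same_v <- v[i] == v[j]
      if (same_u && same_v) tp <- tp + 1
      else if (!same_u && same_v) fp <- fp + 1
      else if (same_u && !same_v) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_ari <- function(u, v) {
  pc <- oracle_pair_counts(u, v)
  n2 <- sum(pc)
  sum_nij <- pc["tp"]
  sum_a <- pc["tp"] + pc["fn"]   # pairs together in u
  sum_b <- pc["tp"] + pc["fp"]   # pairs together in v
  exp_idx <- sum_a * sum_b / n2
  denom <- (sum_a + sum_b) / 2 - exp_idx
  if (denom == 0) return(1)
  unname((sum_nij - exp_idx) / denom)
}

oracle_fmi <- function(u, v) {
  pc <- oracle_pair_counts(u, v)
  denom <- sqrt((pc["tp"] + pc["fp"]) * (pc["tp"] + pc["fn"]))
  if (denom == 0) return(0)
  unname(pc["tp"] / denom)
}

oracle_entropies <- function(u, v) {
  n <- length(u)
  hu <- 0
  for (lev in unique(u)) { p <- sum(u == lev) / n; hu <- hu - p * log(p) }
  hv <- 0
  for (lev in unique(v)) { p <- sum(v == lev) / n; hv <- hv - p * log(p) }
  # H(U|V) by conditioning on each v-cluster
  huv <- 0
  for (lev in unique(v)) {
    sel <- v == lev
    pv <- sum(sel) / n
    hcond <- 0
    for (lu in unique(u[sel])) {
      p <- sum(u[sel] == lu) / sum(sel)
      hcond <- hcond - p * log(p)
    }
    huv <- huv + pv * hcond
  }
  hvu <- 0
  for (lev in unique(u)) {
    sel <- u == lev
    pu <- sum(sel) / n
    hcond <- 0
    for (lv in unique(v[sel])) {
      p <- sum(v[sel] == lv) / sum(sel)
      hcond <- hcond - p * log(p)
    }
    hvu <- hvu + pu * hcond
  }
  list(hu = hu, hv = hv, huv = huv, hvu = hvu, mi = hu - huv)
}

oracle_nmi <- function(u, v) {
  e <- oracle_entropies(u, v)
  if (e$hu + e$hv == 0) return(1)
  2 * e$mi / (e$hu + e$hv)
}

oracle_hom <- function(u, v) {
  e <- oracle_entropies(u, v)
  if (e$hu == 0) return(1)
  1 - e$huv / e$hu
}

oracle_com <- function(u, v) {
  e <- oracle_entropies(u, v)
  if (e$hv == 0) return(1)
  1 - e$hvu / e$hv
}

# ---- embedding metrics, loop-based ----

oracle_silhouette <- function(X, labels) {
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(X) - X[i, ])^2))
    same <- which(labels == labels[i] & seq_len(n) != i)
    if (length(same) == 0) { s[i] <- 0; next }
    a <- mean(di[same])
    b <- Inf
    for (lev in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(di[labels == lev]))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

oracle_knn_indices <- function(X, i, k) {
  di <- sqrt(colSums((t(X) - X[i, ])^2))
  di[i] <- Inf
  order(di, seq_len(nrow(X)))[seq_len(k)]
}

oracle_lisi_norm <- function(X, labels, k) {
  n <- nrow(X)
  levs <- unique(labels)
  C <- length(levs)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- labels[oracle_knn_indices(X, i, k)]
    p <- sapply(levs, function(l) mean(nb == l))
    vals[i] <- 1 / sum(p^2)
  }
  (mean(vals) - 1) / (C - 1)
}

oracle_kbet <- function(X, batch, k, alpha) {
  n <- nrow(X)
  levs <- sort(unique(batch))
  p_global <- sapply(levs, function(l) mean(batch == l))
  ok <- 0
  for (i in seq_len(n)) {
    nb <- batch[oracle_knn_indices(X, i, k)]
    obs <- sapply(levs, function(l) sum(nb == l))
    stat <- sum((obs - k * p_global)^2 / (k * p_global))
    p <- pchisq(stat, df = length(levs) - 1, lower.tail = FALSE)
    if (p > alpha) ok <- ok + 1
  }
  ok / n
}

# BFS connected components over an adjacency list
oracle_components <- function(adj) {
  n <- length(adj)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  comp
}

oracle_graph_connectivity <- function(X, labels, k) {
  vals <- c()
  for (lev in sort(unique(labels))) {
    sel <- which(labels == lev)
    if (length(sel) == 1) { vals <- c(vals, 1); next }
    Xs <- X[sel, , drop = FALSE]
    kk <- min(k, length(sel) - 1)
    adj <- vector("list", length(sel))
    for (i in seq_along(sel)) {
      nb <- oracle_knn_indices(Xs, i, kk)
      for (j in nb) {
        adj[[i]] <- union(adj[[i]], j)
        adj[[j]] <- union(adj[[j]], i)
      }
    }
    comp <- oracle_components(adj)
    vals <- c(vals, max(table(comp)) / length(sel))
  }
  mean(vals)
}

# ---- misc helpers ----

random_partition <- function(n, kmax = 4) {
  sample(letters[seq_len(sample(kmax, 1))], n, replace = TRUE)
}

random_simplex_rows <- function(n, k) {
  M <- matrix(rexp(n * k), n, k)
  M / rowSums(M)
}

rotation_matrix <- function(d) {
  qr.Q(qr(matrix(rnorm(d * d), d, d)))
}
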