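# Embedding-space metrics vs direct loop-based oracles, anchors, null and
# separated-batch behavior, and geometric invariances.

test_that("silhouette anchor and structural cases", {
  # 1-D points {0,1} vs {10,11}
  X <- matrix(c(0, 1, 10, 11), 4, 1)
  expect_equal(silhouette_label(X, c("A", "A", "B", "B")),
               (8.5 / 9.5 + 9.5 / 10.5) / 2, tolerance = 1e-12)
  # random labels on one Gaussian cloud: |ASW| small
  withr::local_seed(3)
  X2 <- matrix(rnorm(1000 * 4), 1000, 4)
  lab <- sample(c("A", "B"), 1000, replace = TRUE)
  expect_lt(abs(silhouette_label(X2, lab)), 0.05)
  # two coincident clusters: a(i) >= b(i)
  X3 <- matrix(rnorm(100 * 2), 100, 2)
  expect_lte(silhouette_label(rbind(X3, X3),
                              rep(c("A", "B"), each = 100)), 0)
  expect_error(silhouette_label(X, rep("A", 4)), ">= 2 label")
})

test_that("loop-based oracles agree with the vectorized metrics (n <= 300)", {
  withr::local_seed(11)
  n <- 180
  X <- matrix(rnorm(n * 6), n, 6)
  lab <- sample(c("A", "B", "C"), n, replace = TRUE)
  bat <- sample(c("b1", "b2"), n, replace = TRUE)
  cfg <- batch_metric_config(k_lisi = 20, k_kbet = 20, k_gc = 5)
  expect_equal(silhouette_label(X, lab), oracle_silhouette(X, lab),
               tolerance = 1e-10)
  l <- lisi_scores(X, lab, batch = bat, cfg = cfg)
  expect_equal(l$clisi_score, 1 - oracle_lisi_norm(X, lab, 20),
               tolerance = 1e-10)
  expect_equal(l$ilisi_score, oracle_lisi_norm(X, bat, 20),
               tolerance = 1e-10)
  expect_equal(kbet(X, bat, cfg), oracle_kbet(X, bat, 20, 0.05),
               tolerance = 1e-10)
  expect_equal(graph_connectivity(X, lab, cfg),
               oracle_graph_connectivity(X, lab, 5), tolerance = 1e-10)
})

test_that("knn accuracy on separated and label-free data", {
  mix <- make_mixture_embeddings(mixture_spec(
    n_cells = 200, n_types = 3, dim = 6, type_separation = 12, seed = 4))
  cfg1 <- batch_metric_config(k_acc = 1)
  expect_equal(knn_accuracy(mix$embedding, mix$annotations$cell_type, cfg1), 1)
  withr::local_seed(5)
  X <- matrix(rnorm(1000 * 3), 1000, 3)
  lab <- rep(c("A", "B"), each = 500)[sample(1000)]
  acc <- knn_accuracy(X, lab, batch_metric_config(seed = 1))
  expect_lt(abs(acc - 0.5), 0.05)
  expect_identical(acc, knn_accuracy(X, lab, batch_metric_config(seed = 1)))
  expect_warning(
    knn_accuracy(X[1:20, ], c(rep("A", 17), rep("B", 3)),
                 batch_metric_config(folds_acc = 5)), "reducing folds")
})

test_that("lisi scores take their boundary values on constructed neighborhoods", {
  # pure neighborhoods: clisi_score = 1
  mix <- make_mixture_embeddings(mixture_spec(
    n_cells = 120, n_types = 2, dim = 4, type_separation = 40, seed = 8))
  l <- lisi_scores(mix$embedding, mix$annotations$cell_type,
                   cfg = batch_metric_config(k_lisi = 10))
  expect_equal(l$clisi_score, 1)
  # constructed neighbor list with exactly 50/50 batch composition
  batch <- rep(c("b1", "b2"), 20)
  idx <- t(vapply(1:40, function(i) {
    others <- setdiff(1:40, i)
    c(others[batch[others] == "b1"][1:5], others[batch[others] == "b2"][1:5])
  }, integer(10)))
  graph <- structure(list(n_nodes = 40, k = 10, idx = idx,
                          dist = idx * 0, cell_ids = as.character(1:40),
                          symmetric = FALSE), class = "NeighborGraph")
  l2 <- lisi_scores(NULL, rep("t", 40), batch = batch,
                    cfg = batch_metric_config(k_lisi = 10), graph = graph)
  expect_equal(l2$ilisi_score, 1)
  # fully separated batches: ilisi_score = 0
  sep <- make_mixture_embeddings(mixture_spec(
    n_cells = 200, n_types = 1, n_batches = 2, dim = 2,
    type_separation = 0, batch_shift = 100, seed = 9))
  l3 <- lisi_scores(sep$embedding, sep$annotations$cell_type,
                    batch = sep$annotations$batch,
                    cfg = batch_metric_config(k_lisi = 20))
  expect_equal(l3$ilisi_score, 0)
  expect_warning(
    l4 <- lisi_scores(sep$embedding, sep$annotations$cell_type,
                      batch = rep("b1", 200),
                      cfg = batch_metric_config(k_lisi = 20)),
    "single batch")
  expect_equal(l4$ilisi_score, 1)
})

test_that("BRAS behaves at its limits", {
  # batches coincident within every type
  mix <- make_mixture_embeddings(mixture_spec(
    n_cells = 1000, n_types = 2, n_batches = 2, dim = 4,
    type_separation = 8, batch_shift = 0, seed = 10))
  expect_gt(bras(mix$embedding, mix$annotations$cell_type,
                 mix$annotations$batch), 0.95)
  # batches fully separated within a type
  sep <- make_mixture_embeddings(mixture_spec(
    n_cells = 400, n_types = 1, n_batches = 2, dim = 4,
    type_separation = 0, batch_shift = 200, seed = 11))
  expect_lt(bras(sep$embedding, sep$annotations$cell_type,
                 sep$annotations$batch), 0.05)
  # single batch: 1 with warning
  expect_warning(
    b <- bras(mix$embedding, mix$annotations$cell_type, rep("b", 1000)),
    "BRAS = 1")
  expect_equal(b, 1)
})

test_that("graph connectivity formula on a constructed split label", {
  # label A forms two far pairs (components 2 + 2), label B one pair
  X <- rbind(c(0, 0), c(0, 0.1), c(100, 0), c(100, 0.1),
             c(50, 50), c(50, 50.1))
  lab <- c("A", "A", "A", "A", "B", "B")
  gc <- graph_connectivity(X, lab, batch_metric_config(k_gc = 1))
  expect_equal(gc, (0.5 + 1) / 2)
  # invariant to label renaming
  lab2 <- c("Z", "Z", "Z", "Z", "Q", "Q")
  expect_equal(graph_connectivity(X, lab2, batch_metric_config(k_gc = 1)), gc)
})

test_that("kbet conventions: single batch and pooling", {
  withr::local_seed(12)
  X <- matrix(rnorm(300 * 3), 300, 3)
  expect_equal(kbet(X, rep("b1", 300)), 1)
  rare <- c(rep("b1", 296), rep("b2", 4))  # expected ~0.67 < 1 at k = 50
  expect_warning(k <- kbet(X, rare, batch_metric_config(k_kbet = 50)),
                 "pooling")
  expect_equal(k, 1)  # pooled down to a single category
})

test_that("metrics are invariant to rigid rotation and translation", {
  withr::local_seed(13)
  n <- 150
  X <- matrix(rnorm(n * 5), n, 5)
  lab <- sample(c("A", "B", "C"), n, replace = TRUE)
  bat <- sample(c("b1", "b2"), n, replace = TRUE)
  R <- rotation_matrix(5)
  X2 <- sweep(X %*% R, 2, rnorm(5), "+")
  # tolerance 1e-8: the rotated coordinates themselves carry float error
  cfg <- batch_metric_config(k_lisi = 15, k_kbet = 15, k_gc = 4, seed = 1)
  expect_equal(silhouette_label(X2, lab), silhouette_label(X, lab),
               tolerance = 1e-8)
  expect_equal(knn_accuracy(X2, lab, cfg), knn_accuracy(X, lab, cfg),
               tolerance = 1e-8)
  expect_equal(lisi_scores(X2, lab, bat, cfg)$ilisi_score,
               lisi_scores(X, lab, bat, cfg)$ilisi_score, tolerance = 1e-8)
  expect_equal(kbet(X2, bat, cfg), kbet(X, bat, cfg), tolerance = 1e-8)
  expect_equal(bras(X2, lab, bat), bras(X, lab, bat), tolerance = 1e-8)
})

test_that("batch metrics respond monotonically to batch shift", {
  shifts <- c(0, 2, 5, 12)
  vals <- sapply(shifts, function(s) {
    mix <- make_mixture_embeddings(mixture_spec(
      n_cells = 800, n_types = 2, n_batches = 2, dim = 6,
      type_separation = 8, batch_shift = s, seed = 20))
    cfg <- batch_metric_config()
    c(ilisi = lisi_scores(mix$embedding, mix$annotations$cell_type,
                          mix$annotations$batch, cfg)$ilisi_score,
      bras = bras(mix$embedding, mix$annotations$cell_type,
                  mix$annotations$batch),
      kbet = kbet(mix$embedding, mix$annotations$batch, cfg))
  })
  for (m in rownames(vals)) {
    expect_true(all(diff(vals[m, ]) <= 0.05),
                info = paste("non-monotone:", m))
  }
})

test_that("label metrics respond monotonically to type separation", {
  seps <- c(0, 3, 8)
  vals <- sapply(seps, function(s) {
    mix <- make_mixture_embeddings(mixture_spec(
      n_cells = 600, n_types = 3, dim = 6, type_separation = s, seed = 21))
    cfg <- batch_metric_config()
    c(asw = silhouette_label(mix$embedding, mix$annotations$cell_type),
      acc = knn_accuracy(mix$embedding, mix$annotations$cell_type, cfg),
      clisi = lisi_scores(mix$embedding, mix$annotations$cell_type,
                          cfg = cfg)$clisi_score)
  })
  for (m in rownames(vals)) {
    expect_true(all(diff(vals[m, ]) >= -0.05),
                info = paste("non-monotone:", m))
  }
})
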