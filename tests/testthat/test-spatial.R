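# Spatial metrics: hand anchors, brute-force oracles, direction transforms,
# geometric invariances.

test_that("Moran/Geary anchor: 4-node path with x = (1,1,-1,-1)", {
  nb <- list(2L, c(1L, 3L), c(2L, 4L), 3L)
  pairs <- scembedeval:::neighbor_pairs(nb)
  mg <- scembedeval:::moran_geary_one(c(1, 1, -1, -1), pairs)
  expect_equal(unname(mg["moran"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(1 - mg["geary"]), 0.5, tolerance = 1e-12)
})

test_that("Moran's I is near 0 for spatially random values", {
  withr::local_seed(31)
  coords <- expand.grid(row = 1:20, col = 1:20)
  nb <- grid_rook_neighbors(as.matrix(coords))
  pairs <- scembedeval:::neighbor_pairs(nb)
  vals <- replicate(20, {
    mg <- scembedeval:::moran_geary_one(rnorm(400), pairs)
    mg["moran"]
  })
  # permutation simulation: the null I is centered at -1/(n-1) with
  # s.d. ~ 1/sqrt(#edges); the mean is near 0, single draws fluctuate
  expect_lte(abs(mean(vals)), 0.05)
  expect_true(all(abs(vals) <= 0.2))
})

test_that("stripes fixture at noise 0 yields strong autocorrelation", {
  sp <- make_spatial_fixture(10, 10, "stripes", n_domains = 2, noise = 0,
                             seed = 1)
  ac <- spatial_autocorrelation(sp$counts, sp$annotations$cell_type,
                                sp$annotations$spatial_xy,
                                neighbors = sp$rook_neighbors)
  expect_gte(ac$moran_score, 0.8)
  # direction transform: reported geary + median C = 1
  expect_equal(ac$geary_score + median(ac$per_gene[, "geary"]), 1,
               tolerance = 1e-12)
})

test_that("constant genes are skipped with a warning", {
  cm <- count_matrix(sprintf("s%d", 1:9), c("g1", "g2"),
                     cbind(c(rep(5, 4), rep(0, 5)), rep(1, 9)),
                     assay = "logexpr")
  coords <- as.matrix(expand.grid(1:3, 1:3))
  dom <- c(rep("a", 4), rep("b", 5))
  expect_warning(
    ac <- spatial_autocorrelation(cm, dom, coords,
                                  spatial_config(k_spatial = 2,
                                                 markers_per_domain = 2)),
    "constant")
  expect_true(is.finite(ac$moran_score))
})

test_that("CHAOS: coincident clusters, brute-force oracle, interleaving", {
  ch <- chaos_score(rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5)),
                    c("a", "a", "b", "b"))
  expect_equal(as.numeric(ch), 1)
  expect_equal(attr(ch, "raw"), 0)

  withr::local_seed(32)
  coords <- matrix(runif(400), 200, 2)
  labels <- sample(c("a", "b", "c"), 200, replace = TRUE)
  S <- scale(coords, center = TRUE, scale = FALSE)
  S <- sweep(S, 2, sqrt(colMeans(S^2)), "/")
  total <- 0
  for (i in 1:200) {
    same <- which(labels == labels[i] & seq_len(200) != i)
    total <- total + min(sqrt(rowSums((S[same, , drop = FALSE] -
                                         rep(S[i, ], each = length(same)))^2)))
  }
  raw_oracle <- total / 200
  got <- chaos_score(coords, labels)
  expect_equal(attr(got, "raw"), raw_oracle, tolerance = 1e-10)
  expect_equal(as.numeric(got), max(0, 1 - raw_oracle), tolerance = 1e-10)

  # interleaving a contiguous stripe into two labels never decreases raw
  sp <- make_spatial_fixture(10, 10, "stripes", n_domains = 2, seed = 3)
  lab <- sp$annotations$cell_type
  raw0 <- attr(chaos_score(sp$annotations$spatial_xy, lab), "raw")
  lab2 <- lab
  in1 <- which(lab == "domain1")
  lab2[in1[seq_along(in1) %% 2 == 0]] <- "domain1b"
  raw1 <- attr(chaos_score(sp$annotations$spatial_xy, lab2), "raw")
  expect_gte(raw1, raw0)
  # both clusters are singletons: one warning each
  expect_warning(expect_warning(
    chaos_score(rbind(c(0, 0), c(1, 1)), c("a", "b")), "singleton"),
    "singleton")
})

test_that("PAS: single-label, checkerboard, stripes brute force", {
  sp <- make_spatial_fixture(10, 10, "stripes", seed = 1)
  expect_equal(as.numeric(pas_score(sp$annotations$spatial_xy,
                                    rep("x", 100))), 1)
  cb <- make_spatial_fixture(8, 8, "checkerboard", seed = 1)
  p <- pas_score(cb$annotations$spatial_xy, cb$annotations$cell_type,
                 neighbors = cb$rook_neighbors)
  expect_equal(as.numeric(p), 0)
  expect_equal(attr(p, "raw"), 1)
  # stripes with k = 4 euclidean neighbors: brute-force abnormal count
  lab <- sp$annotations$cell_type
  coords <- sp$annotations$spatial_xy
  cfg <- spatial_config(k_spatial = 4)
  abn <- sapply(1:100, function(i) {
    nb <- oracle_knn_indices(coords, i, 4)
    sum(lab[nb] != lab[i]) > 2
  })
  expect_equal(attr(pas_score(coords, lab, cfg), "raw"), mean(abn))
})

test_that("reported scores respect the direction transforms exactly", {
  sp <- make_spatial_fixture(8, 8, "blocks", seed = 5)
  lab <- sp$annotations$cell_type
  coords <- sp$annotations$spatial_xy
  p <- pas_score(coords, lab)
  expect_equal(as.numeric(p) + attr(p, "raw"), 1, tolerance = 1e-12)
  ch <- chaos_score(coords, lab)
  if (attr(ch, "raw") <= 1) {
    expect_equal(as.numeric(ch) + attr(ch, "raw"), 1, tolerance = 1e-12)
  }
})

test_that("spatial scores are invariant to the expected rigid transforms", {
  sp <- make_spatial_fixture(9, 9, "stripes", n_domains = 3, seed = 6)
  lab <- sp$annotations$cell_type
  coords <- sp$annotations$spatial_xy
  # translation + uniform scaling for all three
  coords2 <- coords * 3.7 + 11
  cfg <- spatial_config(k_spatial = 4)
  expect_equal(as.numeric(pas_score(coords2, lab, cfg)),
               as.numeric(pas_score(coords, lab, cfg)))
  expect_equal(as.numeric(chaos_score(coords2, lab)),
               as.numeric(chaos_score(coords, lab)), tolerance = 1e-10)
  # rotation for the rank-based neighbor rules (PAS, autocorrelation graph);
  # lattice coordinates are jittered first: exact distance ties on the grid
  # are broken by index, and rotation reshuffles tied float comparisons
  withr::local_seed(34)
  coordsj <- coords + matrix(runif(length(coords), -0.05, 0.05),
                             nrow(coords), 2)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  coords3 <- coordsj %*% R
  expect_equal(as.numeric(pas_score(coords3, lab, cfg)),
               as.numeric(pas_score(coordsj, lab, cfg)))
  ac1 <- spatial_autocorrelation(sp$counts, lab, coordsj, cfg)
  ac3 <- spatial_autocorrelation(sp$counts, lab, coords3, cfg)
  expect_equal(ac3$moran_score, ac1$moran_score, tolerance = 1e-10)
})

test_that("true stripes labeling dominates random relabelings", {
  sp <- make_spatial_fixture(10, 10, "stripes", n_domains = 2, seed = 7)
  lab <- sp$annotations$cell_type
  coords <- sp$annotations$spatial_xy
  cfg <- spatial_config(k_spatial = 4)
  pas_true <- as.numeric(pas_score(coords, lab, cfg))
  chaos_true <- as.numeric(chaos_score(coords, lab))
  withr::local_seed(33)
  for (perm in 1:20) {
    shuf <- sample(lab)
    expect_gte(pas_true, as.numeric(pas_score(coords, shuf, cfg)))
    expect_gte(chaos_true, as.numeric(chaos_score(coords, shuf)))
  }
})
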