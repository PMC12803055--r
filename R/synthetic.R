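# Seeded synthetic-data generators. Every generator is a pure function of
# its spec (seed included) and produces ground truth that downstream metrics
# can be checked against. The fixtures exercise metrics; they make no attempt
# to reproduce real scRNA-seq count distributions (no dropout or
# overdispersion realism).

#' Specification for a Gaussian-mixture embedding fixture
#'
#' Cell types are isotropic unit-variance Gaussians whose means sit at the
#' vertices of a regular simplex with pairwise distance
#' `type_separation` (in units of the within-class standard deviation).
#' Each batch adds a fixed random offset of norm `batch_shift` to all its
#' cells, the simplest structure that makes batch-mixing metrics respond
#' monotonically to the shift.
#'
#' @param n_cells,n_types,n_batches,dim positive integers; `dim >= n_types`.
#' @param type_separation,batch_shift non-negative reals.
#' @param seed integer.
#' @return A `MixtureSpec` list.
#' @export
mixture_spec <- function(n_cells = 1000, n_types = 3, n_batches = 1, dim = 16,
                         type_separation = 8, batch_shift = 0, seed = 0L) {
  assert_that(n_cells >= n_types && n_types >= 1 && n_batches >= 1 && dim >= 1,
              "all counts must be positive and n_cells >= n_types")
  assert_that(dim >= n_types,
              "dim must be >= n_types for the simplex mean construction")
  assert_that(type_separation >= 0 && batch_shift >= 0,
              "separation and shift must be >= 0")
  structure(list(n_cells = n_cells, n_types = n_types, n_batches = n_batches,
                 dim = dim, type_separation = type_separation,
                 batch_shift = batch_shift, seed = as.integer(seed)),
            class = "MixtureSpec")
}

# Regular simplex vertices in R^dim with pairwise distance `sep`,
# centered at the origin. Uses the e_i construction (pairwise sqrt(2)).
simplex_means <- function(n_types, dim, sep) {
  M <- matrix(0, n_types, dim)
  if (n_types == 1 || sep == 0) return(M)
  M[, seq_len(n_types)] <- diag(n_types) * (sep / sqrt(2))
  sweep(M, 2, colMeans(M), "-")
}

#' Generate a Gaussian-mixture embedding fixture
#'
#' @param spec A [mixture_spec()].
#' @return list with `embedding` ([embedding_set()]) and `annotations`
#'   ([cell_annotations()]); cell types `type1..typeK`, batches
#'   `batch1..batchB`.
#' @export
make_mixture_embeddings <- function(spec) {
  stopifnot(inherits(spec, "MixtureSpec"))
  with_seed(spec$seed, {
    n <- spec$n_cells
    means <- simplex_means(spec$n_types, spec$dim, spec$type_separation)
    # near-balanced deterministic type assignment, then shuffled
    type_idx <- sample(rep_len(seq_len(spec$n_types), n))
    batch_idx <- sample(rep_len(seq_len(spec$n_batches), n))
    X <- means[type_idx, , drop = FALSE] +
      matrix(stats::rnorm(n * spec$dim), n, spec$dim)
    if (spec$n_batches > 1 && spec$batch_shift > 0) {
      offs <- matrix(stats::rnorm(spec$n_batches * spec$dim),
                     spec$n_batches, spec$dim)
      offs <- offs / sqrt(rowSums(offs^2)) * spec$batch_shift
      X <- X + offs[batch_idx, , drop = FALSE]
    }
    ids <- sprintf("cell%05d", seq_len(n))
    list(
      embedding = embedding_set(ids, X),
      annotations = cell_annotations(
        ids,
        cell_type = paste0("type", type_idx),
        batch = if (spec$n_batches > 1) paste0("batch", batch_idx)
      )
    )
  })
}

#' Rook-adjacency neighbor lists for integer grid coordinates
#'
#' @param coords n x 2 matrix of integer grid coordinates.
#' @return list of integer vectors; element i holds the indices of the spots
#'   at Manhattan distance 1 from spot i.
#' @export
grid_rook_neighbors <- function(coords) {
  coords <- as.matrix(coords)
  key <- paste(coords[, 1], coords[, 2], sep = "_")
  lookup <- stats::setNames(seq_len(nrow(coords)), key)
  lapply(seq_len(nrow(coords)), function(i) {
    r <- coords[i, 1]; c <- coords[i, 2]
    cand <- paste(c(r - 1, r + 1, r, r), c(c, c, c - 1, c + 1), sep = "_")
    unname(lookup[cand[cand %in% key]])
  })
}

#' Generate a spatial-grid fixture with contiguous domains
#'
#' One spot per grid node at integer coordinates. Domain labels follow the
#' requested layout; each domain has `n_marker_genes_per_domain` marker genes
#' whose Poisson rate is elevated inside the domain (50 vs baseline 0.5, the
#' contrast of a strong domain marker over sparse background expression).
#' `noise` is the s.d. of a log-normal perturbation of each spot x gene rate
#' (0 = exact construction).
#'
#' @param grid_rows,grid_cols grid dimensions (>= 2 each).
#' @param domain_layout `"stripes"`, `"checkerboard"` or `"blocks"`.
#' @param n_domains number of domains for `"stripes"` (column bands);
#'   checkerboard always has 2, blocks 4 (quadrants).
#' @param n_marker_genes_per_domain markers per domain.
#' @param noise non-negative real.
#' @param seed integer.
#' @return list with `counts` ([count_matrix()]), `annotations`
#'   ([cell_annotations()] with `spatial_xy` and domain labels as
#'   `cell_type`), `rook_neighbors` (lattice adjacency, see
#'   [grid_rook_neighbors()]), and `marker_genes` (named list).
#' @export
make_spatial_fixture <- function(grid_rows, grid_cols,
                                 domain_layout = c("stripes", "checkerboard", "blocks"),
                                 n_domains = 2,
                                 n_marker_genes_per_domain = 10,
                                 noise = 0, seed = 0L) {
  domain_layout <- match.arg(domain_layout)
  assert_that(grid_rows >= 2 && grid_cols >= 2, "grid must be at least 2x2")
  coords <- cbind(row = rep(seq_len(grid_rows), each = grid_cols),
                  col = rep(seq_len(grid_cols), times = grid_rows))
  n <- nrow(coords)
  domain <- switch(domain_layout,
    stripes = {
      band <- ceiling(coords[, "col"] / (grid_cols / n_domains))
      pmin(band, n_domains)
    },
    checkerboard = (coords[, "row"] + coords[, "col"]) %% 2 + 1,
    blocks = 1L + (coords[, "row"] > grid_rows / 2) * 2L +
      (coords[, "col"] > grid_cols / 2)
  )
  k_dom <- length(unique(domain))
  genes <- sprintf("gene%03d", seq_len(k_dom * n_marker_genes_per_domain))
  marker_of <- rep(seq_len(k_dom), each = n_marker_genes_per_domain)
  base_rate <- 0.5; marker_rate <- 50
  with_seed(seed, {
    rate <- matrix(base_rate, n, length(genes))
    for (d in seq_len(k_dom)) {
      rate[domain == d, marker_of == d] <- marker_rate
    }
    if (noise > 0) {
      rate <- rate * exp(matrix(stats::rnorm(length(rate), sd = noise),
                                nrow(rate), ncol(rate)))
    }
    counts <- matrix(stats::rpois(length(rate), rate), nrow(rate), ncol(rate))
    ids <- sprintf("spot%04d", seq_len(n))
    list(
      counts = count_matrix(ids, genes, counts),
      annotations = cell_annotations(ids, cell_type = paste0("domain", domain),
                                     spatial_xy = coords),
      rook_neighbors = grid_rook_neighbors(coords),
      marker_genes = split(genes, paste0("domain", marker_of))
    )
  })
}

#' Specification for an additive perturbation fixture
#'
#' Emulates a CRISPR-style single/double perturbation screen in log-space:
#' the control profile is `mu0`; each single perturbation g has a gene-wise
#' effect vector `delta_g` with trans effects drawn N(0, effect_scale^2) and
#' a fixed strong cis effect (+2 on g's own expression, without which the
#' counterfactual encoding would be uninformative); double effects are
#' `delta_g1 + delta_g2 + eps` with `eps ~ N(0, interaction_scale^2)`.
#'
#' @param n_genes number of genes in the panel.
#' @param single_genes character vector of perturbed genes (subset of panel).
#' @param double_pairs list of 2-vectors (pairs of `single_genes`).
#' @param effect_scale,interaction_scale non-negative reals.
#' @param n_cells_per_condition cells per condition (incl. control).
#' @param embed_dim width of the linear pseudo-embedding.
#' @param cell_noise per-cell expression noise s.d. (log-space).
#' @param seed integer.
#' @return A `PerturbFixtureSpec` list.
#' @export
perturb_fixture_spec <- function(n_genes = 100,
                                 single_genes = sprintf("G%02d", 1:8),
                                 double_pairs = NULL,
                                 effect_scale = 0.5,
                                 interaction_scale = 0,
                                 n_cells_per_condition = 50,
                                 embed_dim = 32,
                                 cell_noise = 0.1,
                                 seed = 0L) {
  if (is.null(double_pairs)) {
    cmb <- utils::combn(single_genes, 2)
    double_pairs <- lapply(seq_len(min(12L, ncol(cmb))), function(j) cmb[, j])
  }
  assert_that(all(unlist(double_pairs) %in% single_genes),
              "double_pairs must pair genes from single_genes")
  assert_that(effect_scale >= 0 && interaction_scale >= 0 && cell_noise >= 0,
              "scales must be >= 0")
  assert_that(length(single_genes) <= n_genes, "more singles than genes")
  structure(list(n_genes = n_genes, single_genes = single_genes,
                 double_pairs = double_pairs, effect_scale = effect_scale,
                 interaction_scale = interaction_scale,
                 n_cells_per_condition = n_cells_per_condition,
                 embed_dim = embed_dim, cell_noise = cell_noise,
                 seed = as.integer(seed)),
            class = "PerturbFixtureSpec")
}

#' Generate an additive perturbation fixture
#'
#' Expression is generated directly in log-normalized space (the evaluation
#' pipeline is agnostic to the upstream transform). Besides the expression
#' table and annotations, the generator emits a seeded linear
#' pseudo-embedding map `W` (`expr %*% W + noise`) so the downstream
#' regression stage is identifiable, plus the ground-truth per-condition
#' effect vectors.
#'
#' @param spec A [perturb_fixture_spec()].
#' @return list with `expr` (cells x genes [count_matrix()], assay
#'   `"logexpr"`), `annotations` (condition labels, `"control"` reserved),
#'   `embedding_map` (`W`, genes x embed_dim), `embed` (pseudo-embedding of
#'   the generated cells), and `ground_truth` (list: `mu0`, `effects` - a
#'   conditions x genes matrix of true mean changes vs control).
#' @export
make_perturbation_fixture <- function(spec) {
  stopifnot(inherits(spec, "PerturbFixtureSpec"))
  genes <- sprintf("G%02d", seq_len(spec$n_genes))
  assert_that(all(spec$single_genes %in% genes),
              "single_genes must use the G01.. panel naming")
  with_seed(spec$seed, {
    G <- spec$n_genes
    mu0 <- stats::rnorm(G, mean = 2, sd = 0.5)
    names(mu0) <- genes
    # single effects: dense trans effects + strong fixed cis effect
    delta <- matrix(stats::rnorm(length(spec$single_genes) * G,
                                 sd = spec$effect_scale),
                    length(spec$single_genes), G,
                    dimnames = list(spec$single_genes, genes))
    # targeted genes are clean cis reporters: each perturbation shifts its
    # own gene by a fixed +2 and has no trans effect on other *targeted*
    # genes, so the counterfactual encoding identifies the condition
    delta[, spec$single_genes] <- 0
    for (g in spec$single_genes) delta[g, g] <- 2
    dbl_names <- vapply(spec$double_pairs, paste, character(1), collapse = "+")
    eff_dbl <- matrix(0, length(dbl_names), G,
                      dimnames = list(dbl_names, genes))
    for (j in seq_along(spec$double_pairs)) {
      p <- spec$double_pairs[[j]]
      eps <- stats::rnorm(G, sd = spec$interaction_scale)
      eff_dbl[j, ] <- delta[p[1], ] + delta[p[2], ] + eps
    }
    effects <- rbind(delta, eff_dbl)
    conditions <- c("control", rownames(effects))
    n_per <- spec$n_cells_per_condition
    cond_vec <- rep(conditions, each = n_per)
    mean_mat <- rbind(rep(0, G), effects)[rep(seq_along(conditions), each = n_per), ]
    expr <- sweep(mean_mat, 2, mu0, "+") +
      matrix(stats::rnorm(length(cond_vec) * G, sd = spec$cell_noise),
             length(cond_vec), G)
    ids <- sprintf("cell%05d", seq_along(cond_vec))
    W <- matrix(stats::rnorm(G * spec$embed_dim, sd = 1 / sqrt(G)),
                G, spec$embed_dim)
    E <- expr %*% W +
      matrix(stats::rnorm(length(cond_vec) * spec$embed_dim, sd = 0.01),
             length(cond_vec), spec$embed_dim)
    list(
      expr = count_matrix(ids, genes, expr, assay = "logexpr"),
      annotations = cell_annotations(ids, cell_type = cond_vec,
                                     condition = cond_vec),
      embedding_map = W,
      embed = embedding_set(ids, E),
      ground_truth = list(mu0 = mu0, effects = effects)
    )
  })
}
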