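# Partition-agreement metrics computed from the contingency table:
# adjusted Rand index, normalized mutual information, homogeneity,
# completeness and the Fowlkes-Mallows index. These are implemented directly
# (pair counts and plug-in entropies, natural log) rather than delegated to a
# library: the exact definitions are part of this package's contract and are
# cross-checked against brute-force oracles in the test suite.

choose2 <- function(x) x * (x - 1) / 2

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Agreement metrics between two partitions of the same cells
#'
#' @param U,V `Partition` objects (see [as_partition()]) or label vectors of
#'   equal length over the same cells in the same order. Conventionally `U`
#'   is the reference annotation and `V` the predicted clustering; ARI, NMI
#'   and FMI are symmetric, homogeneity/completeness are not.
#' @return named list: `ari` (in `[-1,1]`), `nmi`, `hom`, `com`, `fmi`
#'   (each in `[0,1]`).
#' @details Degenerate cases follow the limit behavior of agreement: if both
#'   partitions are constant, NMI/HOM/COM are 1; if exactly one is constant,
#'   NMI is 0 while HOM/COM use the convention that a zero conditional
#'   entropy against a zero marginal entropy scores 1. ARI returns 1 when
#'   its chance-correction denominator vanishes and the partitions agree.
#' @export
partition_agreement <- function(U, V) {
  u <- as_partition(U)$labels
  v <- as_partition(V)$labels
  assert_that(length(u) == length(v), "partitions must cover the same cells")
  n <- length(u)
  tab <- table(u, v)
  a <- rowSums(tab)
  b <- colSums(tab)
  sum_nij <- sum(choose2(tab))
  sum_a <- sum(choose2(a))
  sum_b <- sum(choose2(b))
  n2 <- choose2(n)

  # ARI (pair-counting with chance correction)
  exp_idx <- sum_a * sum_b / n2
  denom <- 0.5 * (sum_a + sum_b) - exp_idx
  ari <- if (denom == 0) 1 else (sum_nij - exp_idx) / denom

  # entropies (natural log; base cancels in all ratios)
  pu <- a / n; pv <- b / n; pj <- tab / n
  hu <- entropy_nat(pu); hv <- entropy_nat(pv)
  # mutual information
  mi <- 0
  nz <- which(pj > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    i <- nz[r, 1]; j <- nz[r, 2]
    mi <- mi + pj[i, j] * log(pj[i, j] / (pu[i] * pv[j]))
  }
  mi <- max(mi, 0)
  nmi <- if (hu + hv == 0) 1 else 2 * mi / (hu + hv)

  h_u_given_v <- hu - mi   # H(U|V) = H(U) - I(U;V)
  h_v_given_u <- hv - mi
  hom <- if (hu == 0) 1 else 1 - h_u_given_v / hu
  com <- if (hv == 0) 1 else 1 - h_v_given_u / hv

  # Fowlkes-Mallows: TP / sqrt((TP+FP)(TP+FN))
  fmi <- if (sum_a == 0 || sum_b == 0) 0 else sum_nij / sqrt(sum_a * sum_b)

  list(ari = ari, nmi = min(nmi, 1), hom = min(max(hom, 0), 1),
       com = min(max(com, 0), 1), fmi = fmi)
}
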