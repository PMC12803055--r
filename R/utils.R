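# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so seeded operations do not
#' perturb the global RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Pairwise Euclidean distances between rows of A and rows of B
#' @return length(nrow(A)) x nrow(B) matrix
#' @noRd
cross_dist <- function(A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Library-size normalize and log1p a count matrix (cells x genes)
#'
#' Counts are scaled per cell to `scale_to` total (default: median library
#' size) then log1p-transformed. Cells with zero totals are left at zero.
#' @noRd
lognorm <- function(counts, scale_to = NULL) {
  counts <- as.matrix(counts)
  tot <- rowSums(counts)
  if (is.null(scale_to)) scale_to <- stats::median(tot[tot > 0])
  fac <- ifelse(tot > 0, scale_to / tot, 0)
  log1p(counts * fac)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic integer sub-seed derived from a base seed and a tag
#' @noRd
sub_seed <- function(seed, offset) {
  (as.integer(seed) * 10007L + as.integer(offset)) %% 2147483629L
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
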