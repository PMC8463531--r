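#' Morisita overlap between two count vectors
#'
#' Classic Morisita index with the unbiased within-community aggregation
#' term: `C = 2 * sum(x * y) / ((lambda_x + lambda_y) * X * Y)` where
#' `X = sum(x)`, `lambda_x = sum(x * (x - 1)) / (X * (X - 1))`.  `C` is 0
#' for communities with disjoint support and can exceed 1 when the
#' between-community overlap is larger than the within-community
#' aggregation, in which case the dissimilarity `1 - C` is negative.
#'
#' @param x,y Non-negative integer count vectors of equal length, each
#'   with total at least 2.
#' @return The overlap `C` (a single number).
#' @seealso [morisita_dissimilarity()]
#' @export
morisita_overlap <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) abort("counts must be non-negative")
  X <- sum(x); Y <- sum(y)
  if (X < 2 || Y < 2) {
    abort("each community needs a total count of at least 2")
  }
  lam_x <- sum(x * (x - 1)) / (X * (X - 1))
  lam_y <- sum(y * (y - 1)) / (Y * (Y - 1))
  if (lam_x + lam_y == 0) {
    abort("both communities are maximally even singleton collections; the Morisita denominator is zero")
  }
  2 * sum(x * y) / ((lam_x + lam_y) * X * Y)
}

#' @describeIn morisita_overlap Morisita dissimilarity `1 - C` (negative
#'   when overlap exceeds within-community aggregation).
#' @export
morisita_dissimilarity <- function(x, y) 1 - morisita_overlap(x, y)

#' Randomly pair replicate ids, each used once
#'
#' A uniformly random perfect matching of an even number of replicate
#' ids: 450 replicates yield 225 disjoint pairs.
#'
#' @param replicate_ids Vector of an even number of ids.
#' @param seed Optional integer seed.
#' @return A tibble with columns `id_a`, `id_b` (`length(replicate_ids)/2`
#'   rows; every id appears exactly once).
#' @export
pair_replicates <- function(replicate_ids, seed = NULL) {
  n <- length(replicate_ids)
  if (n %% 2 != 0) abort("need an even number of replicates to pair")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample(replicate_ids)
  tibble::tibble(id_a = perm[seq(1, n, by = 2)],
                 id_b = perm[seq(2, n, by = 2)])
}
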