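#' Jensen-Shannon divergence matrix between samples
#'
#' Computes pairwise Jensen-Shannon divergence between the rows of a
#' community table.  Rows are renormalised to compositions first, so the
#' input may hold counts.  The divergence between compositions p and q is
#' `H(m) - (H(p) + H(q)) / 2` with `m = (p + q) / 2` and Shannon entropy
#' `H` in bits (log base 2, with `0 * log 0 = 0`), which bounds the
#' divergence in `[0, 1]`.
#'
#' @param table A community-table tibble (see [read_abundance_table()]).
#' @return A symmetric numeric matrix of class `community_dist` with zero
#'   diagonal and sample ids as dimnames.
#' @examples
#' tab <- as_community_table(matrix(c(1, 0, 0, 1), 2, 2,
#'   dimnames = list(c("a", "b"), c("f1", "f2"))))
#' jsd_matrix(tab) # divergence 1 between disjoint compositions
#' @export
jsd_matrix <- function(table) {
  p <- community_matrix(to_relative_abundance(table))
  n <- nrow(p)
  hrow <- apply(p, 1, shannon_bits)
  D <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m <- (p[i, ] + p[j, ]) / 2
        d <- shannon_bits(m) - (hrow[i] + hrow[j]) / 2
        D[i, j] <- D[j, i] <- max(d, 0) # guard tiny negative round-off
      }
    }
  }
  structure(D, class = c("community_dist", "matrix"))
}

# Shannon entropy in bits with the 0 log 0 = 0 convention
shannon_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' @export
print.community_dist <- function(x, ...) {
  cat("<community_dist> ", nrow(x), " samples, Jensen-Shannon divergence\n",
      sep = "")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE], ...)
  invisible(x)
}

#' @describeIn jsd_matrix Long-format tibble of pairwise divergences
#'   (one row per unordered sample pair).
#' @param x A `community_dist` matrix.
#' @param ... Unused.
#' @export
tidy.community_dist <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(sample_a = ids[idx[, 1]], sample_b = ids[idx[, 2]],
                 distance = x[idx])
}

validate_dist <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (is.null(rownames(D))) stop("distance matrix needs sample ids as dimnames")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  if (any(D < 0)) stop("distances must be non-negative")
  invisible(D)
}
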