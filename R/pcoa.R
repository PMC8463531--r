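#' Principal coordinate analysis of a dissimilarity matrix
#'
#' Classical metric scaling: double-centre `-D^2 / 2`, eigendecompose, and
#' scale eigenvectors by the square roots of the positive eigenvalues.
#' Axes whose eigenvalue is at most `1e-10 * max(eigenvalue)` are dropped;
#' relative eigenvalues are each eigenvalue divided by the sum of all
#' positive eigenvalues (the "variance explained" of each principal
#' coordinate).
#'
#' @param dist A `community_dist` matrix (or any symmetric zero-diagonal
#'   dissimilarity matrix with sample ids as dimnames), e.g. from
#'   [jsd_matrix()].
#' @return An object of class `community_pcoa`: a list with `coordinates`
#'   (samples x axes matrix, columns `PCo1`, `PCo2`, ...), `eigenvalues`
#'   (retained, descending) and `relative_eigenvalues`.
#' @seealso [eigenvalue_table()], [mapper()]
#' @export
pcoa <- function(dist) {
  validate_dist(dist)
  n <- nrow(dist)
  if (n < 2) stop("need at least two samples")
  if (all(dist == 0)) stop("degenerate configuration: all distances zero")
  sc <- suppressWarnings(cmdscale(as.dist(dist), k = n - 1, eig = TRUE))
  eig <- sc$eig
  pos <- eig[eig > 0]
  keep <- which(eig > 1e-10 * max(eig))
  coords <- sc$points[, seq_along(keep), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(keep))
  rownames(coords) <- rownames(dist)
  structure(
    list(coordinates = coords,
         eigenvalues = eig[keep],
         relative_eigenvalues = eig[keep] / sum(pos)),
    class = "community_pcoa"
  )
}

#' @export
print.community_pcoa <- function(x, ...) {
  cat("<community_pcoa> ", nrow(x$coordinates), " samples, ",
      ncol(x$coordinates), " axes\n", sep = "")
  cat("relative eigenvalues:",
      paste0(sprintf("%.1f", 100 * head(x$relative_eigenvalues, 5)), "%"),
      if (length(x$relative_eigenvalues) > 5) "...", "\n")
  invisible(x)
}

#' @describeIn pcoa Per-sample coordinates as a tibble.
#' @param x A `community_pcoa` object.
#' @param ... Unused.
#' @export
tidy.community_pcoa <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(x$coordinates)),
                   tibble::as_tibble(x$coordinates))
}

#' @describeIn pcoa One-row summary: number of samples, retained axes and
#'   variance explained by the first two axes.
#' @export
glance.community_pcoa <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$coordinates),
    n_axes = ncol(x$coordinates),
    pco1_pct = 100 * x$relative_eigenvalues[1],
    pco2_pct = if (length(x$relative_eigenvalues) >= 2)
      100 * x$relative_eigenvalues[2] else NA_real_
  )
}

#' Relative-eigenvalue table for the leading principal coordinates
#'
#' Percent variance explained by the first `n_axes` principal coordinates
#' plus their total, the layout used to report how much of a functional
#' landscape the Mapper filter captures.
#'
#' @param ordination A `community_pcoa` object.
#' @param n_axes Number of leading axes to report (default 10).
#' @return A tibble with columns `PCo` (axis number, plus a final
#'   `"Total"` row) and `relative_eigenvalue_pct`.
#' @export
eigenvalue_table <- function(ordination, n_axes = 10) {
  rel <- 100 * ordination$relative_eigenvalues
  k <- min(n_axes, length(rel))
  tibble::tibble(
    PCo = c(as.character(seq_len(k)), "Total"),
    relative_eigenvalue_pct = c(rel[seq_len(k)], sum(rel[seq_len(k)]))
  )
}

#' @describeIn pcoa Scatter plot of the first two principal coordinates.
#' @param object A `community_pcoa` object.
#' @export
autoplot.community_pcoa <- function(object, ...) {
  dat <- tidy(object)
  rel <- 100 * object$relative_eigenvalues
  ggplot2::ggplot(dat, ggplot2::aes(.data$PCo1, .data$PCo2)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", rel[1]),
      y = if (length(rel) >= 2) sprintf("PCo2 (%.1f%%)", rel[2]) else "PCo2"
    ) +
    ggplot2::theme_minimal()
}
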