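# Shared fixtures and independent oracles used across test files.

# independent literal-formula Jensen-Shannon divergence (bits)
jsd_ref <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  h <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  h(m) - (h(p) + h(q)) / 2
}

# small community tibble from a matrix literal
ct <- function(values, sample_ids = NULL, feature_ids = NULL) {
  m <- as.matrix(values)
  rownames(m) <- sample_ids %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- feature_ids %||% paste0("f", seq_len(ncol(m)))
  as_community_table(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built mapper graph with explicit nodes/edges (for attractor tests)
manual_graph <- function(clusters, edges, samples = NULL) {
  nodes <- tibble::tibble(
    node = seq_along(clusters),
    size = vapply(clusters, length, integer(1)),
    samples = clusters
  )
  structure(list(nodes = nodes,
                 edges = tibble::tibble(from = edges$from, to = edges$to,
                                        shared = edges$shared %||%
                                          rep(1L, length(edges$from))),
                 samples = samples %||% unlist(clusters)),
            class = "mapper_graph")
}

# distance matrix in which each node's samples form a tight pair at a
# chosen scale, so that with knn_k = 1 the node potential equals the scale
paired_dist <- function(pair_scales, far = 10) {
  n_nodes <- length(pair_scales)
  ids <- as.vector(vapply(seq_len(n_nodes),
                          function(i) paste0("n", i, c("a", "b")),
                          character(2)))
  n <- 2 * n_nodes
  D <- matrix(far, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  for (i in seq_len(n_nodes)) {
    a <- 2 * i - 1; b <- 2 * i
    D[a, b] <- D[b, a] <- pair_scales[i]
  }
  structure(D, class = c("community_dist", "matrix"))
}

# grid design of the simulation study (9 combinations x 225 pairs)
study_design <- function() {
  grid <- expand.grid(Con = c(0, 0.01, 0.1), Fix = c(0, 100, 200))
  grid[rep(seq_len(nrow(grid)), each = 225), ]
}

# gamma responses with mean 1 / (b0 + b1 * Con + b2 * Fix + b3 * Con * Fix)
gamma_design <- function(dat, b0, b1 = 0, b2 = 0, b3 = 0, shape = 2) {
  eta <- b0 + b1 * dat$Con + b2 * dat$Fix + b3 * dat$Con * dat$Fix
  stopifnot(all(eta > 0))
  dat$response <- rgamma(nrow(dat), shape = shape, scale = 1 / (eta * shape))
  dat
}
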