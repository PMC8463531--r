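#' Cover specification for the Mapper algorithm
#'
#' A 2-D rectangular cover over the first two filter axes.  Defaults are
#' the hyperparameters used throughout the landscape analysis: 15
#' intervals per axis, 70% overlap, 10 histogram bins for the preimage
#' clustering heuristic.
#'
#' @param intervals_per_axis Positive integer, number of overlapping
#'   windows per filter axis.
#' @param overlap_fraction Fraction in `[0, 1)` of each window shared with
#'   its successor.
#' @param histogram_bins Positive integer, bins of the single-linkage
#'   merge-height histogram used to pick the cluster cut.
#' @return A list of class `cover_spec`.
#' @export
cover_spec <- function(intervals_per_axis = 15, overlap_fraction = 0.70,
                       histogram_bins = 10) {
  stopifnot(intervals_per_axis >= 1, overlap_fraction >= 0,
            overlap_fraction < 1, histogram_bins >= 1)
  structure(list(intervals_per_axis = as.integer(intervals_per_axis),
                 overlap_fraction = overlap_fraction,
                 histogram_bins = as.integer(histogram_bins)),
            class = "cover_spec")
}

# Overlapping closed windows along one axis, anchored at the data range.
# With k windows of length L = range / (k - (k - 1) * overlap), consecutive
# windows share overlap * L and the first/last edges coincide with min/max.
axis_windows <- function(x, k, overlap) {
  lo <- min(x); hi <- max(x)
  if (hi == lo || k == 1) {
    return(matrix(c(lo, hi), ncol = 2,
                  dimnames = list(NULL, c("lo", "hi")))[rep(1, k), ,
                                                        drop = FALSE])
  }
  L <- (hi - lo) / (k - (k - 1) * overlap)
  step <- L * (1 - overlap)
  lo_i <- lo + (seq_len(k) - 1) * step
  hi_i <- lo_i + L
  hi_i[k] <- hi # guard float drift at the anchored right edge
  cbind(lo = lo_i, hi = hi_i)
}

#' Cluster a cover-cell preimage with the single-linkage gap heuristic
#'
#' Single-linkage merge heights among the member samples are histogrammed
#' (together with the preimage diameter) over `[0, d_max]` in
#' `histogram_bins` equal-width bins; the cut threshold is the left edge
#' of the first empty bin above the smallest merge height, and clusters
#' are the single-linkage components at that threshold.  If no such gap
#' exists the preimage is one cluster.
#'
#' @param members Character vector of sample ids in the preimage.
#' @param dist A `community_dist` matrix covering at least these samples.
#' @param histogram_bins Number of histogram bins.
#' @return A list of character vectors (the clusters).
#' @export
preimage_clusters <- function(members, dist, histogram_bins = 10) {
  stopifnot(length(members) >= 1)
  if (length(members) == 1) return(list(members))
  sub <- dist[members, members, drop = FALSE]
  d_max <- max(sub)
  if (d_max == 0) return(list(members))
  hc <- hclust(as.dist(sub), method = "single")
  heights <- hc$height
  breaks <- seq(0, d_max, length.out = histogram_bins + 1)
  counts <- graphics::hist(c(heights, d_max), breaks = breaks, plot = FALSE,
                           right = FALSE, include.lowest = TRUE)$counts
  eligible <- which(counts == 0 & breaks[-length(breaks)] > min(heights))
  if (length(eligible) == 0) return(list(members))
  threshold <- breaks[eligible[1]]
  grp <- cutree(hc, h = threshold)
  unname(split(members, grp))
}

#' Build a Mapper graph over the first two ordination axes
#'
#' Covers the plane of the first two principal coordinates with
#' overlapping rectangular windows, clusters each window's preimage with
#' [preimage_clusters()] (in the original dissimilarity, not in
#' ordination space), and connects clusters that share at least one
#' sample.
#'
#' @param ordination A `community_pcoa` object with at least two retained
#'   axes.
#' @param dist The `community_dist` matrix the ordination came from.
#' @param cover A [cover_spec()].
#' @return An object of class `mapper_graph`: list with `nodes` (tibble:
#'   `node`, `size`, `samples` list-column), `edges` (tibble: `from`,
#'   `to`, `shared`) and `samples` (all sample ids).
#' @export
mapper <- function(ordination, dist, cover = cover_spec()) {
  coords <- ordination$coordinates
  if (nrow(coords) == 0) stop("empty ordination")
  if (ncol(coords) < 2) stop("the Mapper filter needs two retained axes")
  validate_dist(dist)
  x <- coords[, 1]; y <- coords[, 2]
  wx <- axis_windows(x, cover$intervals_per_axis, cover$overlap_fraction)
  wy <- axis_windows(y, cover$intervals_per_axis, cover$overlap_fraction)
  ids <- rownames(coords)

  clusters <- list()
  for (iy in seq_len(nrow(wy))) {
    in_y <- y >= wy[iy, "lo"] & y <= wy[iy, "hi"]
    for (ix in seq_len(nrow(wx))) {
      keep <- in_y & x >= wx[ix, "lo"] & x <= wx[ix, "hi"]
      if (!any(keep)) next
      clusters <- c(clusters,
                    preimage_clusters(ids[keep], dist, cover$histogram_bins))
    }
  }
  new_mapper_graph(clusters, ids)
}

# Assemble nodes/edges from a list of sample-id clusters.
new_mapper_graph <- function(clusters, all_samples) {
  n_nodes <- length(clusters)
  nodes <- tibble::tibble(
    node = seq_len(n_nodes),
    size = vapply(clusters, length, integer(1)),
    samples = clusters
  )
  edges <- tibble::tibble(from = integer(), to = integer(), shared = integer())
  if (n_nodes >= 2) {
    # incidence: sample -> nodes containing it
    inc <- tibble::tibble(
      node = rep(seq_len(n_nodes), nodes$size),
      sample_id = unlist(clusters)
    )
    pairs <- dplyr::inner_join(inc, inc, by = "sample_id",
                               relationship = "many-to-many") %>%
      dplyr::filter(.data$node.x < .data$node.y) %>%
      dplyr::count(from = .data$node.x, to = .data$node.y, name = "shared")
    edges <- pairs
  }
  structure(list(nodes = nodes, edges = edges, samples = all_samples),
            class = "mapper_graph")
}

#' Remove singleton nodes from a Mapper graph
#'
#' Nodes holding a single sample are dropped together with their incident
#' edges; samples that then belong to no node become unassigned in the
#' downstream basin partition.  Idempotent.
#'
#' @param graph A `mapper_graph`.
#' @return A `mapper_graph` without singleton nodes.
#' @export
prune_singletons <- function(graph) {
  keep <- graph$nodes$node[graph$nodes$size > 1]
  nodes <- graph$nodes %>% dplyr::filter(.data$node %in% keep)
  edges <- graph$edges %>%
    dplyr::filter(.data$from %in% keep, .data$to %in% keep)
  structure(list(nodes = nodes, edges = edges, samples = graph$samples),
            class = "mapper_graph")
}

#' @export
print.mapper_graph <- function(x, ...) {
  cat("<mapper_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges over ", length(x$samples), " samples\n", sep = "")
  invisible(x)
}

#' @describeIn mapper Node table (one row per node, with membership size
#'   and potential when attractors were computed).
#' @param x A `mapper_graph`.
#' @param ... Unused.
#' @export
tidy.mapper_graph <- function(x, ...) {
  x$nodes %>% dplyr::select(-"samples") %>%
    dplyr::mutate(samples = vapply(x$nodes$samples, paste, character(1),
                                   collapse = ","))
}

# igraph view of a mapper graph (isolated nodes preserved)
as_igraph <- function(graph, partition = NULL) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(graph$edges$from),
                   to = as.character(graph$edges$to),
                   shared = graph$edges$shared),
    directed = FALSE,
    vertices = data.frame(name = as.character(graph$nodes$node),
                          size = graph$nodes$size)
  )
  if (!is.null(partition)) {
    key <- igraph::V(g)$name
    igraph::V(g)$potential <- unname(partition$node_potential[key])
    igraph::V(g)$attractor <- unname(partition$basin_of_node[key])
  }
  g
}

#' Export a Mapper graph as GraphML
#'
#' Node attributes: `size`, and `potential` / `attractor` when a basin
#' partition is supplied; edge attribute: `shared` (shared-sample count).
#'
#' @param graph A `mapper_graph`.
#' @param path Output file.
#' @param partition Optional `attractor_partition` whose node attributes
#'   are attached.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path, partition = NULL) {
  igraph::write_graph(as_igraph(graph, partition), path, format = "graphml")
  invisible(path)
}

#' @describeIn mapper Force-directed plot of the Mapper graph; node size
#'   is membership size, colour is the kNN potential (or attractor index)
#'   when a partition is given via `partition=`.
#' @param object A `mapper_graph`.
#' @param partition Optional `attractor_partition` used for colouring.
#' @export
autoplot.mapper_graph <- function(object, partition = NULL, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }
  g <- as_igraph(object, partition)
  # fixed layout seed, restoring the caller's RNG state afterwards
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(1L)
  xy <- igraph::layout_with_fr(g)
  nd <- tibble::tibble(node = as.integer(igraph::V(g)$name),
                       x = xy[, 1], y = xy[, 2],
                       size = igraph::V(g)$size)
  if (!is.null(partition)) {
    nd$attractor <- factor(partition$basin_of_node[as.character(nd$node)])
  }
  ed <- object$edges %>%
    dplyr::left_join(nd %>% dplyr::select("node", xa = "x", ya = "y"),
                     by = c(from = "node")) %>%
    dplyr::left_join(nd %>% dplyr::select("node", xb = "x", yb = "y"),
                     by = c(to = "node"))
  p <- ggplot2::ggplot(nd, ggplot2::aes(.data$x, .data$y))
  if (nrow(ed) > 0) {
    p <- p + ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb),
      colour = "grey60", inherit.aes = FALSE)
  }
  if (!is.null(partition)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(size = .data$size,
                                              colour = .data$attractor))
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(size = .data$size))
  }
  p + ggplot2::theme_void() + ggplot2::labs(size = "samples")
}
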