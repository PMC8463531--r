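#' Detect attractors and basins on a Mapper graph
#'
#' Each sample gets a k-nearest-neighbour (kNN) value: the distance to its
#' `knn_k`-th nearest neighbour over all samples, which is inversely
#' proportional to the local density of sampled community states.  A
#' node's potential is the mean kNN value of its member samples, so dense
#' regions of the landscape have low potential.  Edges are conceptually
#' directed from higher to lower potential; an attractor is a maximal
#' connected set of equal-potential nodes none of whose members has a
#' neighbour with strictly lower potential, and a node's basin is found
#' by steepest descent (repeatedly stepping to the adjacent node of
#' minimal potential, ties broken by smallest node id) until an attractor
#' is reached.  A sample's basin is that of the lowest-potential node
#' containing it; samples in no node (e.g. pruned singletons) are
#' unassigned.
#'
#' @param graph A (typically singleton-pruned) `mapper_graph`.
#' @param dist The `community_dist` matrix over all samples.
#' @param knn_k Neighbour rank used for the density estimate; default
#'   `ceiling(sqrt(n_samples))`.
#' @param smooth If `TRUE` (default), the raw mean-kNN node values are
#'   regularised by `smooth_rounds` rounds of size-weighted averaging
#'   over each node and its graph neighbours before basin detection.
#'   The raw per-node density estimate rests on few samples and its
#'   sampling noise manufactures spurious shallow basins; the weighted
#'   diffusion removes those while leaving the potential ordering of
#'   separated density peaks intact (disconnected regions of the graph
#'   never exchange potential).  Set `smooth = FALSE` to use the raw
#'   mean-kNN potential.
#' @param smooth_rounds Number of smoothing iterations (default 5).
#' @return An object of class `attractor_partition`: list with
#'   `attractors` (list of integer node-id vectors), `basin_of_node`
#'   (named integer vector), `basin_of_sample` (named integer vector, `NA`
#'   = unassigned), `node_potential` and `knn_k`.
#' @export
find_attractors <- function(graph, dist, knn_k = NULL, smooth = TRUE,
                            smooth_rounds = 5L) {
  validate_dist(dist)
  n_samp <- nrow(dist)
  if (is.null(knn_k)) knn_k <- ceiling(sqrt(n_samp))
  stopifnot(knn_k >= 1, knn_k < n_samp)

  nodes <- graph$nodes$node
  empty_partition <- function() {
    structure(list(attractors = list(),
                   basin_of_node = setNames(integer(0), character(0)),
                   basin_of_sample = setNames(rep(NA_integer_,
                                                  length(graph$samples)),
                                              graph$samples),
                   node_potential = setNames(numeric(0), character(0)),
                   knn_k = as.integer(knn_k)),
              class = "attractor_partition")
  }
  if (length(nodes) == 0) return(empty_partition())

  knn_val <- knn_values(dist, knn_k)
  potential <- vapply(graph$nodes$samples,
                      function(s) mean(knn_val[s]), numeric(1))
  names(potential) <- as.character(nodes)

  adj <- adjacency_list(nodes, graph$edges)
  if (smooth) {
    size <- setNames(graph$nodes$size, as.character(nodes))
    for (round in seq_len(smooth_rounds)) {
      potential <- vapply(as.character(nodes), function(v) {
        nb <- c(v, as.character(adj[[v]]))
        sum(size[nb] * potential[nb]) / sum(size[nb])
      }, numeric(1))
    }
  }

  eps <- 1e-9 * max(abs(potential), 1e-300)
  same <- function(a, b) abs(a - b) <= eps

  # plateau components: connected subgraphs of equal potential
  plateau_edges <- graph$edges %>%
    dplyr::filter(same(potential[as.character(.data$from)],
                       potential[as.character(.data$to)]))
  comp_of <- flat_components(nodes, plateau_edges)

  # a component is an attractor iff no member has a strictly lower neighbour
  comp_ids <- unique(comp_of)
  is_attractor <- vapply(comp_ids, function(cid) {
    members <- nodes[comp_of == cid]
    !any(vapply(as.character(members), function(v) {
      nb <- adj[[v]]
      length(nb) > 0 && any(potential[as.character(nb)] <
                              potential[v] - eps)
    }, logical(1)))
  }, logical(1))

  attractor_comps <- comp_ids[is_attractor]
  # deterministic attractor numbering: by smallest member node id
  attractor_members <- lapply(attractor_comps,
                              function(cid) sort(nodes[comp_of == cid]))
  ord <- order(vapply(attractor_members, min, numeric(1)))
  attractor_members <- attractor_members[ord]
  attractor_comps <- attractor_comps[ord]
  attractor_index <- setNames(seq_along(attractor_comps),
                              as.character(attractor_comps))

  # steepest descent at the plateau-component level (memoised)
  basin_of_comp <- setNames(rep(NA_integer_, length(comp_ids)),
                            as.character(comp_ids))
  basin_of_comp[as.character(attractor_comps)] <-
    attractor_index[as.character(attractor_comps)]
  resolve <- function(cid) {
    key <- as.character(cid)
    if (!is.na(basin_of_comp[[key]])) return(basin_of_comp[[key]])
    members <- nodes[comp_of == cid]
    nb <- setdiff(unique(unlist(adj[as.character(members)])), members)
    # a non-attractor plateau always has a strictly lower neighbour
    nb_pot <- potential[as.character(nb)]
    cand <- nb[nb_pot <= min(nb_pot) + eps]
    target <- min(cand) # smallest node id among minimal-potential neighbours
    res <- resolve(comp_of[match(target, nodes)])
    basin_of_comp[[key]] <<- res
    res
  }
  for (cid in comp_ids) resolve(cid)

  basin_of_node <- setNames(basin_of_comp[as.character(comp_of)],
                            as.character(nodes))

  # sample basin: basin of its lowest-potential node (ties: smallest id)
  inc <- tibble::tibble(node = rep(nodes, graph$nodes$size),
                        sample_id = unlist(graph$nodes$samples))
  best <- inc %>%
    dplyr::mutate(potential = potential[as.character(.data$node)]) %>%
    dplyr::arrange(.data$potential, .data$node) %>%
    dplyr::distinct(.data$sample_id, .keep_all = TRUE)
  basin_of_sample <- setNames(rep(NA_integer_, length(graph$samples)),
                              graph$samples)
  basin_of_sample[best$sample_id] <-
    unname(basin_of_node[as.character(best$node)])

  structure(list(attractors = attractor_members,
                 basin_of_node = basin_of_node,
                 basin_of_sample = basin_of_sample,
                 node_potential = potential,
                 knn_k = as.integer(knn_k)),
            class = "attractor_partition")
}

# distance to the k-th nearest neighbour of every sample; the self
# distance (one guaranteed zero per row) is discarded by taking rank k + 1
knn_values <- function(dist, k) {
  apply(dist, 1, function(d) sort(d)[k + 1])
}

# undirected adjacency list keyed by node id (as character)
adjacency_list <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), as.character(nodes))
  for (key in names(adj)) adj[[key]] <- numeric(0)
  if (nrow(edges) > 0) {
    ends <- split(c(edges$to, edges$from),
                  as.character(c(edges$from, edges$to)))
    adj[names(ends)] <- lapply(ends, function(v) sort(unique(v)))
  }
  adj
}

# connected components over an arbitrary node set (possibly with no edges)
flat_components <- function(nodes, edges) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$from),
                   to = as.character(edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes)))
  comp <- igraph::components(g)$membership
  unname(comp[as.character(nodes)])
}

#' @export
print.attractor_partition <- function(x, ...) {
  n_att <- length(x$attractors)
  n_assigned <- sum(!is.na(x$basin_of_sample))
  cat("<attractor_partition> ", n_att, " attractor(s); ",
      n_assigned, "/", length(x$basin_of_sample),
      " samples assigned (knn_k = ", x$knn_k, ")\n", sep = "")
  invisible(x)
}

#' @describeIn find_attractors Per-sample basin assignments as a tibble
#'   (`basin` is `NA` for unassigned samples).
#' @param x An `attractor_partition`.
#' @param ... Unused.
#' @export
tidy.attractor_partition <- function(x, ...) {
  tibble::tibble(sample_id = names(x$basin_of_sample),
                 basin = unname(x$basin_of_sample))
}

#' @describeIn find_attractors One-row summary.
#' @export
glance.attractor_partition <- function(x, ...) {
  tibble::tibble(n_attractors = length(x$attractors),
                 n_assigned = sum(!is.na(x$basin_of_sample)),
                 n_unassigned = sum(is.na(x$basin_of_sample)),
                 knn_k = x$knn_k)
}

#' Export an attractor partition as JSON
#'
#' @param partition An `attractor_partition`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_partition_json <- function(partition, path) {
  obj <- list(
    knn_k = partition$knn_k,
    attractors = lapply(partition$attractors, as.integer),
    basin_of_node = as.list(partition$basin_of_node),
    basin_of_sample = lapply(partition$basin_of_sample, function(b)
      if (is.na(b)) "unassigned" else b)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Occupancy counts per attractor and metadata grouping
#'
#' Long-format table of how many samples fall in each attractor basin
#' (plus `"unassigned"`) for every combination of the requested metadata
#' keys, e.g. counts per generation and tissue, or per timepoint and
#' birth mode.
#'
#' @param partition An `attractor_partition`.
#' @param metadata A metadata tibble with a `sample_id` column (see
#'   [read_metadata()]).
#' @param keys Character vector of metadata column names to group by.
#' @return A tibble with columns `attractor` (`"A1"`, `"A2"`, ...,
#'   `"unassigned"`), the key columns, and `n`.
#' @export
occupancy_summary <- function(partition, metadata, keys) {
  missing_keys <- setdiff(keys, names(metadata))
  if (length(missing_keys) > 0) {
    abort(paste0("unknown metadata key(s): ",
                 paste(missing_keys, collapse = ", ")))
  }
  assign_tbl <- tidy(partition) %>%
    dplyr::mutate(attractor = ifelse(is.na(.data$basin), "unassigned",
                                     paste0("A", .data$basin)))
  joined <- dplyr::inner_join(assign_tbl, metadata, by = "sample_id")
  if (nrow(joined) < nrow(assign_tbl)) {
    warn(sprintf("%d sample(s) missing from metadata were dropped",
                 nrow(assign_tbl) - nrow(joined)))
  }
  joined %>%
    dplyr::count(dplyr::across(dplyr::all_of(c("attractor", keys))),
                 name = "n") %>%
    dplyr::arrange(.data$attractor)
}
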