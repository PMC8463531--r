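#' Landscape analysis workflow
#'
#' Runs the full attractor-landscape chain on an abundance table:
#' Jensen-Shannon divergence, principal coordinate analysis, Mapper on
#' the first two principal coordinates, singleton pruning, kNN-potential
#' attractor detection, and (when metadata are available) occupancy
#' summaries.  All intermediate results are written to `out_dir` along
#' with the resolved configuration, so a run directory is
#' self-describing and exactly reproducible.
#'
#' @param table A community tibble or a path to a TSV abundance table.
#' @param metadata Optional metadata tibble or TSV path; when absent the
#'   occupancy step is skipped with a warning.
#' @param out_dir Output directory (created if needed).
#' @param intervals,overlap,bins Mapper cover hyperparameters (defaults:
#'   15 intervals per axis, 70% overlap, 10 histogram bins).
#' @param knn_k kNN rank for the potential, or `NULL` for
#'   `ceiling(sqrt(n))`.
#' @param keys Metadata columns for the occupancy summaries; defaults to
#'   every non-`sample_id` column.
#' @param orientation Passed to [read_abundance_table()] when `table` is
#'   a path.
#' @param seed Integer seed recorded in the configuration (the chain is
#'   deterministic; the seed pins any future stochastic options).
#' @return (Invisibly) a list with the `dist`, `ordination`, `graph`
#'   (pruned), `partition` and `occupancy` objects; files are written to
#'   `out_dir`.
#' @export
run_landscape_workflow <- function(table, metadata = NULL, out_dir,
                                   intervals = 15, overlap = 0.70,
                                   bins = 10, knn_k = NULL,
                                   keys = NULL,
                                   orientation = "samples_in_rows",
                                   seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  log_line <- function(...) cat(..., "\n", sep = "", file = log_path,
                                append = TRUE)
  cat("", file = log_path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  tab <- stage("read_table", {
    if (is.character(table)) read_abundance_table(table, orientation)
    else table
  })
  md <- stage("read_metadata", {
    if (is.character(metadata)) read_metadata(metadata) else metadata
  })
  log_line("input: ", nrow(tab), " samples x ",
           ncol(tab) - 1, " features")

  D <- stage("jsd", jsd_matrix(tab))
  readr::write_tsv(
    dplyr::bind_cols(tibble::tibble(sample_id = rownames(D)),
                     tibble::as_tibble(unclass(D))),
    file.path(out_dir, "distance.tsv"), progress = FALSE)

  ord <- stage("pcoa", pcoa(D))
  readr::write_tsv(tidy(ord), file.path(out_dir, "pcoa_coordinates.tsv"),
                   progress = FALSE)
  readr::write_tsv(eigenvalue_table(ord),
                   file.path(out_dir, "relative_eigenvalues.tsv"),
                   progress = FALSE)
  log_line("pcoa: ", ncol(ord$coordinates), " retained axes; PCo1+PCo2 = ",
           sprintf("%.1f%%",
                   100 * sum(head(ord$relative_eigenvalues, 2))))

  cover <- cover_spec(intervals, overlap, bins)
  graph <- stage("mapper", mapper(ord, D, cover))
  log_line("mapper: ", nrow(graph$nodes), " nodes, ", nrow(graph$edges),
           " edges")
  pruned <- stage("prune", prune_singletons(graph))
  log_line("prune: ", nrow(graph$nodes) - nrow(pruned$nodes),
           " singleton node(s) removed")

  partition <- stage("attractors", find_attractors(pruned, D, knn_k))
  write_graphml(pruned, file.path(out_dir, "mapper.graphml"), partition)
  write_partition_json(partition, file.path(out_dir, "attractors.json"))
  log_line("attractors: ", length(partition$attractors),
           " attractor(s), ", sum(!is.na(partition$basin_of_sample)),
           " assigned sample(s)")

  occupancy <- NULL
  if (is.null(md)) {
    warn("no metadata supplied; occupancy step skipped")
    log_line("occupancy: skipped (no metadata)")
  } else {
    if (is.null(keys)) keys <- setdiff(names(md), "sample_id")
    occupancy <- stage("occupancy", occupancy_summary(partition, md, keys))
    readr::write_tsv(occupancy, file.path(out_dir, "occupancy.tsv"),
                     progress = FALSE)
    log_line("occupancy: ", nrow(occupancy), " rows over keys ",
             paste(keys, collapse = ", "))
  }

  write_config(file.path(out_dir, "config.txt"), list(
    workflow = "landscape", intervals = intervals, overlap = overlap,
    bins = bins, knn_k = partition$knn_k, seed = seed,
    n_samples = nrow(tab), n_features = ncol(tab) - 1))

  invisible(list(dist = D, ordination = ord, graph = pruned,
                 partition = partition, occupancy = occupancy))
}

#' Simulation and metastability-statistics workflow
#'
#' Runs the simulation experiment over the (connectivity, n_fixed) grid,
#' pairs replicates within each combination, computes Morisita
#' statistics, fits and ranks the five gamma GLMs by AICc and tests the
#' best model against the complete model.  Defaults are the study grid:
#' connectivity 0 / 0.01 / 0.1, fixed individuals 0 / 100 / 200, 450
#' replicates of 600 timesteps with 50 species and 500 individuals.
#'
#' @param out_dir Output directory (created if needed).
#' @param connectivities,n_fixed_values Parameter grid.
#' @param config A [sim_config()].
#' @param seed Master seed; stage seeds are derived from it.
#' @param response Passed to [metastability_analysis()].
#' @return (Invisibly) a list with `results` (replicate abundances) and
#'   `analysis` (the `metastability_analysis`); files are written to
#'   `out_dir`.
#' @export
run_simulation_workflow <- function(out_dir,
                                    connectivities = c(0, 0.01, 0.1),
                                    n_fixed_values = c(0, 100, 200),
                                    config = sim_config(), seed = 1,
                                    response = "auto") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  cat("", file = log_path)
  log_line <- function(...) cat(..., "\n", sep = "", file = log_path,
                                append = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  results <- stage("simulate", run_experiment(connectivities,
                                              n_fixed_values, config,
                                              seed = seed))
  write_experiment(results, file.path(out_dir, "simulation.tsv"))
  log_line("simulate: ", nrow(results), " replicates over ",
           length(connectivities) * length(n_fixed_values),
           " parameter combinations")

  analysis <- stage("metastability",
                    metastability_analysis(results, seed = seed + 1L,
                                           response = response))
  readr::write_tsv(analysis$pairs, file.path(out_dir, "pairs.tsv"),
                   progress = FALSE)
  readr::write_tsv(tibble::as_tibble(analysis$ranking),
                   file.path(out_dir, "ranking.tsv"), progress = FALSE)
  readr::write_tsv(tidy(analysis$dev_test),
                   file.path(out_dir, "deviance_test.tsv"),
                   progress = FALSE)
  log_line("metastability: response = ", analysis$response_used,
           "; best model = ", analysis$ranking$model[1])

  write_config(file.path(out_dir, "config.txt"), list(
    workflow = "simulation", seed = seed,
    connectivities = paste(connectivities, collapse = ","),
    n_fixed = paste(n_fixed_values, collapse = ","),
    species = config$S, individuals = config$I,
    timesteps = config$timesteps, replicates = config$replicates,
    extinction_prob = config$extinction_prob,
    growth_prob = config$growth_prob, response = analysis$response_used))

  invisible(list(results = results, analysis = analysis))
}

# flat key = value configuration file
write_config <- function(path, values) {
  lines <- vapply(names(values), function(k)
    paste0(k, " = ", values[[k]]), character(1))
  writeLines(lines, path)
  invisible(path)
}
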