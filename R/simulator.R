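#' Simulation configuration
#'
#' Holds the shared scales and rates of the individual-based community
#' models.  Defaults are the study conditions of the simulation
#' experiment: 50 metacommunity species, 500 individuals (sites), 600
#' timesteps and 450 replicates per parameter combination; per-species
#' migration probabilities are drawn from a standard uniform distribution
#' once per parameter combination (when `migration_probs` is `NULL`).
#'
#' @param S Metacommunity species count.
#' @param I Number of individuals/sites.
#' @param timesteps Number of timesteps per replicate.
#' @param replicates Replicates per parameter combination.
#' @param migration_probs Optional length-`S` vector of per-species
#'   immigration probabilities in `[0, 1]`; drawn from U(0, 1) per
#'   combination when `NULL`.
#' @param extinction_prob Per-step, per-individual death probability
#'   (also sets the Hubbell deaths-per-step, `round(extinction_prob * I)`).
#' @param growth_prob Probability that a reproduction event into an empty
#'   site succeeds (SOI model).
#' @param n_fixed Number of initial individuals shared by all replicates
#'   of a combination (0, 100 or 200 in the study grid).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(S = 50, I = 500, timesteps = 600, replicates = 450,
                       migration_probs = NULL, extinction_prob = 0.1,
                       growth_prob = 0.5, n_fixed = 0) {
  stopifnot(S >= 1, I >= 1, timesteps >= 0, replicates >= 1,
            extinction_prob >= 0, extinction_prob <= 1,
            growth_prob >= 0, growth_prob <= 1,
            n_fixed >= 0, n_fixed <= I)
  if (!is.null(migration_probs)) {
    stopifnot(length(migration_probs) == S,
              all(migration_probs >= 0), all(migration_probs <= 1))
  }
  structure(list(S = as.integer(S), I = as.integer(I),
                 timesteps = as.integer(timesteps),
                 replicates = as.integer(replicates),
                 migration_probs = migration_probs,
                 extinction_prob = extinction_prob,
                 growth_prob = growth_prob,
                 n_fixed = as.integer(n_fixed)),
            class = "sim_config")
}

#' Random pairwise interaction matrix
#'
#' Exactly `round(connectivity * S * (S - 1))` off-diagonal entries are
#' non-zero, at positions chosen uniformly without replacement, with
#' values drawn from U(-`value_range`, `value_range`) (zero excluded).
#' While the positive edge fraction exceeds `max_pep`, signs of uniformly
#' chosen positive entries are switched, so at most `max_pep` of the
#' non-zero entries are positive.  The diagonal is the self-limitation
#' constant.
#'
#' @param S Species count.
#' @param connectivity Fraction of possible pairwise interactions that
#'   are non-zero, in `[0, 1]`.
#' @param max_pep Maximum positive edge fraction (default 0.3).
#' @param value_range Half-width of the uniform value distribution.
#' @param diag_value Self-limitation diagonal constant (default -0.5).
#' @param seed Optional integer seed.
#' @return An `S x S` matrix of class `interaction_matrix` with
#'   attributes `connectivity` and `positive_edge_fraction`.
#' @export
random_interaction_matrix <- function(S, connectivity, max_pep = 0.3,
                                      value_range = 1, diag_value = -0.5,
                                      seed = NULL) {
  if (connectivity < 0 || connectivity > 1) {
    abort("connectivity must be in [0, 1]")
  }
  stopifnot(max_pep >= 0, max_pep <= 1, S >= 1)
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(0, S, S)
  n_off <- S * (S - 1)
  nnz <- round(connectivity * n_off)
  if (nnz > 0) {
    off <- which(row(A) != col(A))
    pos <- sample(off, nnz)
    vals <- runif(nnz, -value_range, value_range)
    while (any(vals == 0)) {
      vals[vals == 0] <- runif(sum(vals == 0), -value_range, value_range)
    }
    A[pos] <- vals
    while (mean(A[pos] > 0) > max_pep) {
      flip <- pos[A[pos] > 0]
      pick <- if (length(flip) == 1) flip else sample(flip, 1)
      A[pick] <- -A[pick]
    }
  }
  diag(A) <- diag_value
  pep <- if (nnz > 0) mean(A[pos] > 0) else NA_real_
  structure(A, class = c("interaction_matrix", "matrix"),
            connectivity = connectivity, positive_edge_fraction = pep)
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("<interaction_matrix> ", nrow(x), " species, connectivity ",
      attr(x, "connectivity"), ", positive edge fraction ",
      signif(attr(x, "positive_edge_fraction"), 3), "\n", sep = "")
  invisible(x)
}

#' Initial community state
#'
#' All `I` sites are occupied at t = 0: the first `n_fixed` sites carry
#' the shared fixed individuals (identical across replicates of a
#' parameter combination) and the rest are drawn uniformly over species.
#'
#' @param config A [sim_config()].
#' @param fixed_individuals Integer vector of length `config$n_fixed`
#'   with species ids in `1..S`.
#' @param seed Optional integer seed for the random remainder.
#' @return Integer vector of length `I` of species ids.
#' @export
initial_state <- function(config, fixed_individuals = integer(0),
                          seed = NULL) {
  if (length(fixed_individuals) != config$n_fixed) {
    abort("length(fixed_individuals) must equal config$n_fixed")
  }
  if (config$n_fixed > config$I) abort("n_fixed exceeds the number of sites")
  if (!is.null(seed)) set.seed(seed)
  random_part <- sample.int(config$S, config$I - config$n_fixed,
                            replace = TRUE)
  as.integer(c(fixed_individuals, random_part))
}

#' Simulate the self-organized instability (SOI) model
#'
#' One replicate of the individual-based SOI dynamics: per timestep,
#' immigration of each species into an empty site with its migration
#' probability, `I` pairwise interaction/growth events driven by the net
#' effect `A[i, j] - A[j, i]`, and independent per-site extinction.
#'
#' @param config A [sim_config()] (must carry `migration_probs`).
#' @param A An `interaction_matrix`.
#' @param init Initial state from [initial_state()].
#' @param seed Optional integer seed.
#' @param trajectory If `TRUE`, also return the timesteps x S abundance
#'   trajectory.
#' @return List of class `simulation_result`: `abundance` (length-S
#'   integer vector), `sites` (final state), and optionally `trajectory`.
#' @export
simulate_soi <- function(config, A, init, seed = NULL, trajectory = FALSE) {
  stopifnot(nrow(A) == config$S, length(init) == config$I)
  mig <- config$migration_probs
  if (is.null(mig)) abort("config$migration_probs must be set for a single run")
  if (!is.null(seed)) set.seed(seed)
  out <- soi_dynamics_cpp(as.integer(init), unclass(A), mig,
                          config$growth_prob, config$extinction_prob,
                          config$timesteps, trajectory)
  structure(c(out, list(model = "soi")), class = "simulation_result")
}

#' Simulate the Hubbell neutral model
#'
#' Zero-sum neutral dynamics: per timestep,
#' `max(1, round(extinction_prob * I))` uniformly chosen individuals die
#' and are immediately replaced, by an immigrant with probability
#' `mean(migration_probs)` (species proportional to the migration
#' probabilities) or by the offspring of a uniformly chosen other local
#' individual.
#'
#' @inheritParams simulate_soi
#' @param init Fully occupied initial state (no empty sites).
#' @return List of class `simulation_result` as in [simulate_soi()].
#' @export
simulate_hubbell <- function(config, init, seed = NULL, trajectory = FALSE) {
  stopifnot(length(init) == config$I)
  if (any(init == 0)) abort("Hubbell dynamics need a fully occupied start")
  mig <- config$migration_probs
  if (is.null(mig)) abort("config$migration_probs must be set for a single run")
  if (!is.null(seed)) set.seed(seed)
  d <- max(1L, as.integer(round(config$extinction_prob * config$I)))
  out <- hubbell_dynamics_cpp(as.integer(init), mig, d, config$timesteps,
                              trajectory)
  structure(c(out, list(model = "hubbell")), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> model ", x$model, ", richness ",
      sum(x$abundance > 0), ", individuals ", sum(x$abundance), "\n",
      sep = "")
  invisible(x)
}

#' Run the full simulation experiment over a parameter grid
#'
#' For every (connectivity, n_fixed) combination: one interaction matrix,
#' one shared fixed-individual list and one migration-probability vector
#' are drawn, then `config$replicates` replicates are simulated with
#' per-replicate seeds derived deterministically (and disjointly across
#' combinations) from the experiment seed.  Connectivity 0 dispatches to
#' the neutral Hubbell dynamics.
#'
#' @param connectivities Numeric vector of connectivity values (study
#'   grid: 0, 0.01, 0.1).
#' @param n_fixed_values Integer vector of fixed-individual counts (study
#'   grid: 0, 100, 200).
#' @param config A [sim_config()]; its `n_fixed` and `migration_probs`
#'   are overridden per combination.
#' @param seed Experiment seed (integer).
#' @param max_pep,value_range,diag_value Interaction-matrix parameters,
#'   see [random_interaction_matrix()].
#' @return A tibble with one row per replicate: `connectivity`, `n_fixed`,
#'   `replicate`, `seed`, `model`, then `sp1..spS` final abundances.
#' @export
run_experiment <- function(connectivities = c(0, 0.01, 0.1),
                           n_fixed_values = c(0, 100, 200),
                           config = sim_config(), seed = 1,
                           max_pep = 0.3, value_range = 1,
                           diag_value = -0.5) {
  grid <- tidyr::expand_grid(connectivity = connectivities,
                             n_fixed = n_fixed_values)
  n_combo <- nrow(grid)
  R <- config$replicates
  set.seed(seed)
  # disjoint deterministic seed streams: one block per combination plus
  # one setup seed per combination, all distinct
  all_seeds <- matrix(sample.int(2147483646L, n_combo * (R + 1)),
                      nrow = n_combo)

  purrr::pmap_dfr(
    list(grid$connectivity, grid$n_fixed, seq_len(n_combo)),
    function(con, nf, ci) {
      set.seed(all_seeds[ci, 1])
      A <- random_interaction_matrix(config$S, con, max_pep = max_pep,
                                     value_range = value_range,
                                     diag_value = diag_value)
      fixed <- sample.int(config$S, nf, replace = TRUE)
      mig <- runif(config$S)
      combo_cfg <- config
      combo_cfg$n_fixed <- as.integer(nf)
      combo_cfg$migration_probs <- mig
      rep_seeds <- all_seeds[ci, -1]
      purrr::map_dfr(seq_len(R), function(r) {
        init <- initial_state(combo_cfg, fixed, seed = rep_seeds[r])
        res <- if (con == 0) {
          simulate_hubbell(combo_cfg, init)
        } else {
          simulate_soi(combo_cfg, A, init)
        }
        ab <- setNames(as.list(res$abundance),
                       paste0("sp", seq_len(config$S)))
        tibble::tibble(connectivity = con, n_fixed = nf, replicate = r,
                       seed = rep_seeds[r], model = res$model, !!!ab)
      })
    }
  )
}

#' Write an experiment abundance table as TSV
#'
#' @param results Tibble from [run_experiment()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_experiment <- function(results, path) {
  readr::write_tsv(results, path, progress = FALSE)
  invisible(path)
}
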