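#' Specification for synthetic community tables with known attractors
#'
#' Parameters of the generators that emulate the statistical structure
#' the landscape analysis assumes: `K` archetypal functional profiles
#' over `F` features, Dirichlet compositional noise around them, and
#' (for the longitudinal generator) trajectories that converge from
#' distinct starting compositions to shared target archetypes.
#'
#' @param K Number of archetypes (attractors) to plant.
#' @param F Number of features; must be at least `K`.
#' @param separation In `[0, 1]`: 1 gives disjoint dominant-feature
#'   blocks (maximal pairwise divergence), 0 collapses all archetypes to
#'   the uniform composition.
#' @param concentration Dirichlet concentration; higher is tighter noise
#'   around the archetype.
#' @param n_per_group Samples per archetype (cross-sectional), subjects
#'   per start mode (trajectories) or lineages per archetype
#'   (generational).
#' @param generations Generations for the generational design.
#' @param timepoints Timepoints (months) for the trajectory design.
#' @param start_modes Number of distinct starting compositions (e.g. two
#'   birth modes).
#' @param convergence_rate Per-step pull toward the target archetype, in
#'   `(0, 1]`.
#' @param drift Per-generation probability that a lineage switches to a
#'   different archetype (generational design).
#' @param depth Optional multinomial sampling depth; when set, tables
#'   hold integer counts instead of proportions.
#' @param seed Integer seed used by all generators.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(K = 3, F = 200, separation = 1,
                           concentration = 200, n_per_group = 30,
                           generations = 3, timepoints = 12,
                           start_modes = 2, convergence_rate = 0.3,
                           drift = 0, depth = NULL, seed = 1) {
  stopifnot(K >= 1, F >= 2, separation >= 0, separation <= 1,
            concentration > 0, n_per_group >= 1, generations >= 1,
            timepoints >= 1, start_modes >= 1,
            convergence_rate > 0, convergence_rate <= 1,
            drift >= 0, drift <= 1)
  structure(list(K = as.integer(K), F = as.integer(F),
                 separation = separation, concentration = concentration,
                 n_per_group = as.integer(n_per_group),
                 generations = as.integer(generations),
                 timepoints = as.integer(timepoints),
                 start_modes = as.integer(start_modes),
                 convergence_rate = convergence_rate, drift = drift,
                 depth = depth, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Archetypal compositions with controlled separation
#'
#' Builds `K` compositions over `F` features from disjoint
#' dominant-feature blocks blended toward the uniform composition:
#' `a_k = separation * block_k + (1 - separation) * uniform`.  At
#' `separation = 1` the supports are disjoint so pairwise Jensen-Shannon
#' divergence is 1; at `separation = 0` all archetypes coincide with the
#' uniform composition.
#'
#' @param spec A [synthetic_spec()] (or arguments `K`, `F`, `separation`
#'   via a spec).
#' @return A `K x F` matrix whose rows are compositions.
#' @export
make_archetypes <- function(spec) {
  K <- spec$K; F <- spec$F
  if (K > F) abort("cannot build K disjoint dominant blocks with K > F features")
  # contiguous dominant-feature blocks of near-equal size
  sizes <- diff(round(seq(0, F, length.out = K + 1)))
  arch <- matrix(0, K, F)
  stop_at <- cumsum(sizes)
  start_at <- c(1, head(stop_at, -1) + 1)
  for (k in seq_len(K)) {
    pure <- numeric(F)
    pure[start_at[k]:stop_at[k]] <- 1 / sizes[k]
    arch[k, ] <- spec$separation * pure + (1 - spec$separation) / F
  }
  rownames(arch) <- paste0("archetype", seq_len(K))
  colnames(arch) <- paste0("f", seq_len(F))
  arch
}

# Dirichlet rows around a base composition (shape = concentration * base)
rdirichlet_rows <- function(n, base, concentration) {
  F <- length(base)
  g <- matrix(rgamma(n * F, shape = concentration * base), nrow = n,
              byrow = TRUE)
  rs <- rowSums(g)
  # zero-shape components are exact zeros; an all-zero draw cannot occur
  # for a valid composition (some shape is always positive)
  g / rs
}

# optionally replace proportions by multinomial counts at fixed depth
apply_depth <- function(mat, depth) {
  if (is.null(depth)) return(mat)
  t(apply(mat, 1, function(p) rmultinom(1, depth, p)[, 1]))
}

#' Cross-sectional mixture of archetypal profiles
#'
#' For each archetype, `n_per_group` samples are drawn from a Dirichlet
#' distribution centred on it.  The generating archetype of every sample
#' is recorded as ground truth.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `table` (community tibble), `labels` (tibble:
#'   `sample_id`, `archetype`) and `archetypes` (the matrix used).
#' @export
sample_cross_sectional <- function(spec) {
  set.seed(spec$seed)
  arch <- make_archetypes(spec)
  rows <- list(); labels <- character(0)
  for (k in seq_len(spec$K)) {
    rows[[k]] <- rdirichlet_rows(spec$n_per_group, arch[k, ],
                                 spec$concentration)
    labels <- c(labels, rep(rownames(arch)[k], spec$n_per_group))
  }
  m <- do.call(rbind, rows)
  m <- apply_depth(m, spec$depth)
  rownames(m) <- sprintf("s%03d", seq_len(nrow(m)))
  colnames(m) <- colnames(arch)
  list(table = as_community_table(m),
       labels = tibble::tibble(sample_id = rownames(m), archetype = labels),
       archetypes = arch)
}

#' Longitudinal trajectories converging to shared target archetypes
#'
#' Each subject starts at a composition specific to its start mode (e.g.
#' birth mode) and evolves by
#' `p_{t+1} = normalize((1 - r) * p_t + r * target)` with convergence
#' rate `r`; the observed sample at each timepoint is a Dirichlet draw
#' around `p_t`.  All start modes share the same target archetype by
#' default, emulating succession toward a common mature state.
#'
#' @param spec A [synthetic_spec()]; `K` sets the number of candidate
#'   target archetypes (target = archetype 1), `start_modes` the number
#'   of distinct initial compositions.
#' @param target Index of the target archetype (default 1), or a vector
#'   of per-subject targets.
#' @return A list with `table`, `metadata` (tibble: `sample_id`,
#'   `subject`, `timepoint`, `start_mode`), `labels` (per-subject target)
#'   and `archetypes`.
#' @export
sample_trajectories <- function(spec, target = 1) {
  set.seed(spec$seed)
  # targets first, then one extra archetype per start mode
  base_spec <- spec
  base_spec$K <- spec$K + spec$start_modes
  arch <- make_archetypes(base_spec)
  targets_pool <- arch[seq_len(spec$K), , drop = FALSE]
  starts <- arch[spec$K + seq_len(spec$start_modes), , drop = FALSE]

  n_subj <- spec$n_per_group * spec$start_modes
  target <- rep(target, length.out = n_subj)
  rows <- list(); meta <- list(); idx <- 0
  for (mode in seq_len(spec$start_modes)) {
    for (s in seq_len(spec$n_per_group)) {
      idx <- idx + 1
      subject <- sprintf("m%d_subj%02d", mode, s)
      p <- starts[mode, ]
      tgt <- targets_pool[target[idx], ]
      for (t in seq_len(spec$timepoints)) {
        p <- (1 - spec$convergence_rate) * p + spec$convergence_rate * tgt
        p <- p / sum(p)
        obs <- rdirichlet_rows(1, p, spec$concentration)[1, ]
        rows[[length(rows) + 1]] <- obs
        meta[[length(meta) + 1]] <- tibble::tibble(
          subject = subject, timepoint = t, start_mode = paste0("mode", mode),
          target = rownames(targets_pool)[target[idx]])
      }
    }
  }
  m <- do.call(rbind, rows)
  m <- apply_depth(m, spec$depth)
  rownames(m) <- sprintf("s%04d", seq_len(nrow(m)))
  colnames(m) <- colnames(arch)
  md <- dplyr::bind_rows(meta) %>%
    dplyr::mutate(sample_id = rownames(m), .before = 1)
  list(table = as_community_table(m),
       metadata = md %>% dplyr::select(-"target"),
       labels = md %>% dplyr::select("sample_id", "subject", "target"),
       archetypes = arch)
}

#' Multi-generation lineages with archetype drift
#'
#' Each lineage starts on an archetype and, per generation, switches to a
#' uniformly chosen different archetype with probability `drift`
#' (`drift = 0` models perfect functional persistence across
#' generations; positive drift models divergence).  One sample per
#' lineage and generation is drawn around the lineage's current
#' archetype.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `table`, `metadata` (tibble: `sample_id`,
#'   `lineage`, `generation`, `treatment` = founding archetype), `labels`
#'   (per-sample generating archetype) and `archetypes`.
#' @export
sample_generational <- function(spec) {
  set.seed(spec$seed)
  arch <- make_archetypes(spec)
  rows <- list(); meta <- list()
  for (k in seq_len(spec$K)) {
    for (l in seq_len(spec$n_per_group)) {
      lineage <- sprintf("a%d_lin%02d", k, l)
      cur <- k
      for (g in seq_len(spec$generations)) {
        if (g > 1 && spec$K > 1 && runif(1) < spec$drift) {
          cur <- sample(setdiff(seq_len(spec$K), cur), 1)
        }
        obs <- rdirichlet_rows(1, arch[cur, ], spec$concentration)[1, ]
        rows[[length(rows) + 1]] <- obs
        meta[[length(meta) + 1]] <- tibble::tibble(
          lineage = lineage, generation = g,
          treatment = rownames(arch)[k],
          archetype = rownames(arch)[cur])
      }
    }
  }
  m <- do.call(rbind, rows)
  m <- apply_depth(m, spec$depth)
  rownames(m) <- sprintf("s%04d", seq_len(nrow(m)))
  colnames(m) <- colnames(arch)
  md <- dplyr::bind_rows(meta) %>%
    dplyr::mutate(sample_id = rownames(m), .before = 1)
  list(table = as_community_table(m),
       metadata = md %>% dplyr::select("sample_id", "lineage",
                                       "generation", "treatment"),
       labels = md %>% dplyr::select("sample_id", "archetype"),
       archetypes = arch)
}
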