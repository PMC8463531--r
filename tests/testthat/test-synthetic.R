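test_that("archetypes form separated blocks that collapse as separation drops", {
  sp <- synthetic_spec(K = 2, F = 4, separation = 1)
  a <- make_archetypes(sp)
  expect_equal(unname(a[1, ]), c(0.5, 0.5, 0, 0))
  expect_equal(unname(a[2, ]), c(0, 0, 0.5, 0.5))
  expect_gte(jsd_ref(a[1, ], a[2, ]), 0.9)

  expect_equal(nrow(make_archetypes(synthetic_spec(K = 1, F = 5))), 1)
  expect_error(make_archetypes(synthetic_spec(K = 6, F = 5)), "K > F")

  flat <- make_archetypes(synthetic_spec(K = 3, F = 9, separation = 0))
  expect_equal(unname(flat), matrix(1 / 9, 3, 9))
  expect_lt(jsd_ref(flat[1, ], flat[2, ]), 1e-12)
})

test_that("cross-sectional samples are balanced compositions near archetypes", {
  sp <- synthetic_spec(K = 3, F = 30, n_per_group = 30, seed = 2)
  xs <- sample_cross_sectional(sp)
  expect_equal(nrow(xs$table), 90)
  expect_equal(as.integer(table(xs$labels$archetype)), rep(30L, 3))
  m <- community_matrix(xs$table)
  expect_true(all(abs(rowSums(m) - 1) <= 1e-9))
  expect_true(all(m >= 0))
  # same seed reproduces the table exactly
  expect_identical(sample_cross_sectional(sp)$table, xs$table)

  tight <- sample_cross_sectional(
    synthetic_spec(K = 2, F = 20, n_per_group = 5, concentration = 1e6,
                   seed = 3))
  mt <- community_matrix(tight$table)
  for (i in seq_len(nrow(mt))) {
    k <- match(tight$labels$archetype[i], rownames(tight$archetypes))
    expect_lt(jsd_ref(mt[i, ], tight$archetypes[k, ]), 1e-3)
  }
})

test_that("trajectories contract toward the shared target archetype", {
  # near-noiseless observation: immediate jump at full convergence rate
  sp1 <- synthetic_spec(K = 1, F = 20, start_modes = 1, n_per_group = 1,
                        timepoints = 4, convergence_rate = 1,
                        concentration = 1e8, seed = 4)
  tr1 <- sample_trajectories(sp1)
  m1 <- community_matrix(tr1$table)
  tgt <- tr1$archetypes[1, ]
  for (i in seq_len(nrow(m1))) expect_lt(jsd_ref(m1[i, ], tgt), 1e-3)

  # partial convergence: divergence to the target strictly decreases
  sp2 <- synthetic_spec(K = 1, F = 20, start_modes = 1, n_per_group = 1,
                        timepoints = 8, convergence_rate = 0.3,
                        concentration = 1e7, seed = 5)
  tr2 <- sample_trajectories(sp2)
  m2 <- community_matrix(tr2$table)
  dvg <- apply(m2, 1, jsd_ref, q = tr2$archetypes[1, ])
  expect_true(all(diff(dvg) < 0))

  # two start modes converge into one divergence ball around the target
  sp3 <- synthetic_spec(K = 1, F = 40, start_modes = 2, n_per_group = 6,
                        timepoints = 10, convergence_rate = 0.5,
                        concentration = 500, seed = 6)
  tr3 <- sample_trajectories(sp3)
  m3 <- community_matrix(tr3$table)
  last <- tr3$metadata$timepoint == 10
  dvg_last <- apply(m3[last, ], 1, jsd_ref, q = tr3$archetypes[1, ])
  first <- tr3$metadata$timepoint == 1
  dvg_first <- apply(m3[first, ], 1, jsd_ref, q = tr3$archetypes[1, ])
  expect_lt(max(dvg_last), min(dvg_first))
  expect_lt(max(dvg_last), 0.1)
})

test_that("generational lineages persist or drift as configured", {
  sp0 <- synthetic_spec(K = 3, F = 30, n_per_group = 5, generations = 4,
                        drift = 0, seed = 7)
  g0 <- sample_generational(sp0)
  per_lineage <- split(g0$labels$archetype, g0$metadata$lineage)
  expect_true(all(vapply(per_lineage,
                         function(v) length(unique(v)) == 1, logical(1))))

  sp1 <- synthetic_spec(K = 3, F = 30, n_per_group = 5, generations = 4,
                        drift = 1, seed = 8)
  g1 <- sample_generational(sp1)
  changes <- vapply(split(g1$labels$archetype, g1$metadata$lineage),
                    function(v) all(v[-1] != v[-length(v)]), logical(1))
  expect_true(all(changes))

  sp5 <- synthetic_spec(K = 4, F = 30, n_per_group = 40, generations = 6,
                        drift = 0.5, seed = 9)
  g5 <- sample_generational(sp5)
  switches <- unlist(lapply(split(g5$labels$archetype, g5$metadata$lineage),
                            function(v) v[-1] != v[-length(v)]))
  p_hat <- mean(switches)
  se <- sqrt(0.5 * 0.5 / length(switches))
  expect_lte(abs(p_hat - 0.5), 3 * se)
})

test_that("the trajectory fixture shows both start modes in the target basin", {
  sp <- synthetic_spec(K = 2, F = 60, start_modes = 2, n_per_group = 8,
                       timepoints = 6, convergence_rate = 0.6,
                       concentration = 400, seed = 10)
  tr <- sample_trajectories(sp)
  D <- jsd_matrix(tr$table)
  part <- find_attractors(prune_singletons(mapper(pcoa(D), D)), D)
  occ <- occupancy_summary(part, tr$metadata, c("timepoint", "start_mode"))
  final <- occ %>% dplyr::filter(.data$timepoint == 6,
                                 .data$attractor != "unassigned")
  # both modes occupy one shared attractor at the final timepoint
  expect_setequal(final$start_mode, c("mode1", "mode2"))
  expect_equal(dplyr::n_distinct(final$attractor), 1)
})
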