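test_that("Morisita overlap matches hand-evaluated cases", {
  expect_equal(morisita_overlap(c(4, 0), c(0, 4)), 0)
  expect_equal(morisita_dissimilarity(c(4, 0), c(0, 4)), 1)
  expect_equal(morisita_overlap(c(2, 2), c(2, 2)), 1.5)
  expect_equal(morisita_dissimilarity(c(2, 2), c(2, 2)), -0.5)
  # identical even communities approach full overlap from above
  ds <- vapply(c(10, 100, 1000),
               function(n) abs(morisita_dissimilarity(c(n, n), c(n, n))),
               numeric(1))
  expect_true(all(diff(ds) < 0))
  expect_error(morisita_overlap(c(1, 0), c(3, 3)), "at least 2")
})

test_that("Morisita is symmetric and ignores shared absent species", {
  set.seed(3)
  for (i in 1:10) {
    x <- rpois(12, 5); y <- rpois(12, 5)
    x[1] <- x[1] + 2; y[2] <- y[2] + 2 # ensure totals >= 2
    expect_equal(morisita_overlap(x, y), morisita_overlap(y, x))
    expect_equal(morisita_overlap(c(x, 0, 0), c(y, 0, 0)),
                 morisita_overlap(x, y))
  }
})

test_that("Morisita dissimilarity agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(5)
  for (i in 1:10) {
    x <- rpois(15, 8); y <- rpois(15, 8)
    x[1] <- x[1] + 2; y[1] <- y[1] + 2
    v <- as.numeric(vegan::vegdist(rbind(x, y), method = "morisita"))
    # vegan truncates overlap-above-one (negative dissimilarity) at zero
    expect_equal(max(morisita_dissimilarity(x, y), 0), v,
                 tolerance = 1e-12)
  }
  # a strongly aggregated disjoint pair exercises the positive branch
  x <- c(20, 1, 0, 0); y <- c(0, 0, 1, 20)
  v <- as.numeric(vegan::vegdist(rbind(x, y), method = "morisita"))
  expect_gt(v, 0.5)
  expect_equal(morisita_dissimilarity(x, y), v, tolerance = 1e-12)
})

test_that("replicate pairing is a perfect matching", {
  p <- pair_replicates(1:450, seed = 1)
  expect_equal(nrow(p), 225)
  expect_setequal(c(p$id_a, p$id_b), 1:450)
  expect_equal(anyDuplicated(c(p$id_a, p$id_b)), 0)
  expect_equal(nrow(pair_replicates(c("x", "y"))), 1)
  expect_error(pair_replicates(1:5), "even")
})

test_that("gamma GLM reproduces closed-form and exact inverse problems", {
  set.seed(2)
  y <- rgamma(40, shape = 3, scale = 1)
  fit <- fit_gamma_glm(data.frame(response = y), response ~ 1)
  expect_equal(unname(fitted(fit$fit)[1]), mean(y), tolerance = 1e-8)
  expect_equal(fit$k, 2L)

  con <- rep(c(0, 0.01, 0.1), each = 20)
  exact <- data.frame(Con = con, response = 1 / (2 + 3 * con))
  fit2 <- fit_gamma_glm(exact, response ~ Con)
  expect_equal(unname(fit2$coefficients), c(2, 3), tolerance = 1e-6)

  expect_error(fit_gamma_glm(data.frame(response = c(1, 0, 2)),
                             response ~ 1), "positive")
})

test_that("the package likelihood convention matches the gamma density", {
  set.seed(4)
  d <- data.frame(Con = runif(30, 0.5, 2))
  d$response <- rgamma(30, shape = 2, scale = 1 / (2 * (1 + d$Con)))
  fit <- fit_gamma_glm(d, response ~ Con)
  phi <- fit$dispersion_deviance
  mu <- fitted(fit$fit)
  ll <- sum(dgamma(d$response, shape = 1 / phi, scale = mu * phi, log = TRUE))
  expect_equal(fit$logLik, ll, tolerance = 1e-10)
})

test_that("IRLS agrees with direct likelihood maximisation", {
  set.seed(6)
  for (i in 1:5) {
    d <- data.frame(Con = runif(20, 0, 1), Fix = runif(20, 0, 2))
    eta <- 1.5 + 0.8 * d$Con + 0.4 * d$Fix
    d$response <- rgamma(20, shape = 4, scale = 1 / (eta * 4))
    fit <- fit_gamma_glm(d, response ~ Con + Fix)
    # independent oracle: maximise the gamma log-likelihood directly
    # (the score in beta does not depend on the shape parameter)
    nll <- function(beta) {
      mu <- 1 / (beta[1] + beta[2] * d$Con + beta[3] * d$Fix)
      if (any(mu <= 0)) return(1e10)
      -sum(dgamma(d$response, shape = 1, scale = mu, log = TRUE))
    }
    opt <- optim(c(1, 0, 0), nll, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 1000))
    expect_equal(unname(fit$coefficients), opt$par, tolerance = 1e-4)
  }
})

test_that("AICc follows the small-sample formula and its limits", {
  expect_equal(aicc(0, k = 2, n = 10), 4 + 12 / 7)
  expect_lt(abs(aicc(-10, k = 4, n = 1e9) - (2 * 10 + 2 * 4)), 1e-6)
  expect_error(aicc(0, k = 4, n = 5), "n > k")
})

test_that("model ranking sorts by AICc with normalised weights", {
  set.seed(8)
  d <- study_design()
  d <- gamma_design(d, b0 = 2, b1 = 3)
  fits <- list(null = fit_gamma_glm(d, response ~ 1),
               Con = fit_gamma_glm(d, response ~ Con))
  rk <- rank_models(fits)
  expect_equal(rk$delta[1], 0)
  expect_equal(sum(rk$weight), 1, tolerance = 1e-9)
  expect_true(all(diff(rk$AICc) >= 0))

  single <- rank_models(fits["Con"])
  expect_equal(single$weight, 1)

  short <- fit_gamma_glm(d[1:100, ], response ~ 1)
  expect_error(rank_models(list(a = fits$null, b = short)), "same number")
})

test_that("deviance tests compare nested models on the scaled chi-square", {
  set.seed(9)
  d <- gamma_design(study_design(), b0 = 2, b1 = 3)
  f_con <- fit_gamma_glm(d, response ~ Con)
  f_full <- fit_gamma_glm(d, response ~ Con * Fix)
  self <- deviance_test(f_full, f_full)
  expect_equal(self$deviance, 0)
  expect_equal(self$p_value, 1)
  dt <- deviance_test(f_con, f_full)
  expect_equal(dt$df, 2L)
  expect_gte(dt$p_value, 0)
  expect_lte(dt$p_value, 1)
  f_fix <- fit_gamma_glm(d, response ~ Fix)
  expect_error(deviance_test(f_fix, f_con), "not nested")
})

test_that("the metastability analysis assembles pairs, ranking and test", {
  cfg <- sim_config(S = 8, I = 60, timesteps = 30, replicates = 6)
  res <- run_experiment(c(0, 0.1), c(0, 10), cfg, seed = 11)
  an <- metastability_analysis(res, seed = 12)
  expect_equal(nrow(an$pairs), 4 * 3) # 4 combinations x 3 pairs
  expect_setequal(an$ranking$model,
                  c("null", "Con", "Fix", "Con + Fix", "Con + Fix + Con:Fix"))
  expect_setequal(an$ranking$df, c(2L, 3L, 3L, 4L, 5L))
  expect_true(all(an$pairs$response > 0))
  an2 <- metastability_analysis(res, seed = 12)
  expect_identical(an$ranking, an2$ranking)
  expect_identical(an$pairs, an2$pairs)
})
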