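#' Fit a gamma GLM with an inverse link
#'
#' Fits `y ~ terms` with a gamma error distribution and the inverse link
#' (mean `mu = 1 / eta`) by iteratively reweighted least squares.  The
#' likelihood convention follows the gamma family's small-dispersion
#' plug-in: dispersion `phi = deviance / n`, log-likelihood
#' `sum(log dgamma(y; shape = 1/phi, scale = mu * phi))`, and parameter
#' count `k = p + 1` (coefficients plus the dispersion).
#'
#' @param data A data frame holding the response and covariates.
#' @param formula Model formula; the response must be strictly positive.
#' @return An object of class `gamma_glm`: list with `fit` (the
#'   underlying `glm`), `coefficients`, `logLik`, `k`, `n`, `deviance`,
#'   `dispersion_deviance` and `dispersion_pearson`.
#' @export
fit_gamma_glm <- function(data, formula) {
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  if (any(y <= 0)) {
    abort("gamma GLM needs a strictly positive response")
  }
  fit <- glm(formula, family = Gamma(link = "inverse"), data = data,
             control = glm.control(epsilon = 1e-8, maxit = 50))
  if (!fit$converged) {
    abort(paste0("IRLS did not converge in ", fit$iter, " iterations"))
  }
  ll <- logLik(fit)
  n <- length(y)
  p <- length(coef(fit))
  structure(
    list(fit = fit,
         coefficients = coef(fit),
         logLik = as.numeric(ll),
         k = as.integer(attr(ll, "df")), # p + 1 (dispersion counted)
         n = n,
         deviance = fit$deviance,
         dispersion_deviance = fit$deviance / n,
         dispersion_pearson = sum(residuals(fit, "pearson")^2) /
           df.residual(fit),
         formula = formula),
    class = "gamma_glm")
}

#' @export
print.gamma_glm <- function(x, ...) {
  cat("<gamma_glm> ", deparse(x$formula), "\n  logLik ",
      sprintf("%.3f", x$logLik), ", k ", x$k, ", n ", x$n, ", AICc ",
      sprintf("%.2f", aicc(x)), "\n", sep = "")
  invisible(x)
}

#' @describeIn fit_gamma_glm Coefficient table.
#' @param x A `gamma_glm`.
#' @param ... Unused.
#' @export
tidy.gamma_glm <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1],
                 std_error = s[, 2], statistic = s[, 3],
                 p_value = s[, 4])
}

#' @describeIn fit_gamma_glm One-row fit summary.
#' @export
glance.gamma_glm <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, df = x$k, AICc = aicc(x),
                 deviance = x$deviance, n = x$n,
                 dispersion = x$dispersion_pearson)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)`.
#'
#' @param object A `gamma_glm` fit, or a numeric log-likelihood (in which
#'   case `k` and `n` must be given).
#' @param k Parameter count (coefficients plus dispersion).
#' @param n Number of observations; must exceed `k + 1`.
#' @param ... Unused.
#' @return The AICc value.
#' @export
aicc <- function(object, ...) UseMethod("aicc")

#' @rdname aicc
#' @export
aicc.gamma_glm <- function(object, ...) {
  aicc(object$logLik, k = object$k, n = object$n)
}

#' @rdname aicc
#' @export
aicc.numeric <- function(object, k, n, ...) {
  if (n <= k + 1) abort("AICc needs n > k + 1")
  -2 * object + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc differences
#'
#' @param delta Numeric vector of AICc differences from the best model.
#' @return Weights `exp(-delta / 2)` normalised to sum to 1.
#' @export
akaike_weights <- function(delta) {
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Rank fitted models by AICc
#'
#' @param fits Named list of `gamma_glm` fits on the same response.
#' @return A tibble of class `model_ranking`, sorted by ascending AICc,
#'   with columns `model`, `df`, `logLik`, `AICc`, `delta`, `weight`.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1) {
    abort("all models must be fitted to the same number of observations")
  }
  tab <- tibble::tibble(
    model = names(fits),
    df = unname(vapply(fits, function(f) f$k, integer(1))),
    logLik = unname(vapply(fits, function(f) f$logLik, numeric(1))),
    AICc = unname(vapply(fits, aicc, numeric(1)))
  ) %>%
    dplyr::arrange(.data$AICc) %>%
    dplyr::mutate(delta = .data$AICc - min(.data$AICc),
                  weight = akaike_weights(.data$delta))
  class(tab) <- c("model_ranking", class(tab))
  tab
}

#' @describeIn rank_models Bar chart of Akaike weights.
#' @param object A `model_ranking`.
#' @param ... Unused.
#' @export
autoplot.model_ranking <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$model, -.data$weight), y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Akaike weight") +
    ggplot2::theme_minimal()
}

#' Deviance test between nested gamma GLMs
#'
#' The deviance difference is referred to a chi-square distribution after
#' scaling by the Pearson dispersion of the full model:
#' `p = P(chi2_df > (dev_nested - dev_full) / phi_full)` with
#' `df` the coefficient-count difference.
#'
#' @param nested,full `gamma_glm` fits; the nested model's terms must be
#'   a subset of the full model's.
#' @return A list of class `deviance_test` with `deviance`, `df` and
#'   `p_value`.
#' @export
deviance_test <- function(nested, full) {
  t_nested <- attr(terms(nested$formula), "term.labels")
  t_full <- attr(terms(full$formula), "term.labels")
  if (!all(t_nested %in% t_full)) {
    abort("models are not nested (nested terms must be a subset of full terms)")
  }
  if (nested$n != full$n) abort("models were fitted to different data")
  df <- length(coef(full$fit)) - length(coef(nested$fit))
  dev_diff <- nested$deviance - full$deviance
  p <- if (df == 0) 1 else
    pchisq(dev_diff / full$dispersion_pearson, df, lower.tail = FALSE)
  structure(list(deviance = dev_diff, df = as.integer(df), p_value = p),
            class = "deviance_test")
}

#' @export
print.deviance_test <- function(x, ...) {
  cat(sprintf("Deviance = %.4f, df = %d, P = %.4f\n", x$deviance, x$df,
              x$p_value))
  invisible(x)
}

#' @describeIn deviance_test One-row tibble.
#' @param x A `deviance_test`.
#' @param ... Unused.
#' @export
tidy.deviance_test <- function(x, ...) {
  tibble::tibble(deviance = x$deviance, df = x$df, p_value = x$p_value)
}

#' Metastability analysis of a simulation experiment
#'
#' The full beta-diversity study on [run_experiment()] output: within
#' every (connectivity, n_fixed) combination the replicates are grouped
#' into disjoint random pairs, the Morisita overlap `C` and dissimilarity
#' `d = 1 - C` are computed per pair, and the response is modelled with
#' gamma GLMs (inverse link) with numeric connectivity and
#' fixed-individual covariates.  Five models are ranked by AICc (null,
#' `Con`, `Fix`, `Con + Fix`, `Con + Fix + Con:Fix`) and the best model is
#' compared with the complete model by a scaled deviance test.
#'
#' The gamma family needs a positive response.  With `response = "auto"`
#' (default) the dissimilarity is reflected (`y = -d`) when every pair's
#' dissimilarity is negative — the regime where within-community
#' diversity exceeds between-community diversity — and the overlap
#' (`y = C`) is used otherwise; the choice taken is recorded in the
#' result.
#'
#' @param results Tibble from [run_experiment()].
#' @param seed Integer seed for the random pairing.
#' @param response `"auto"`, `"neg_dissimilarity"` (`y = -d`) or
#'   `"overlap"` (`y = C`).
#' @return A list of class `metastability_analysis`: `pairs` (per-pair
#'   tibble with `connectivity`, `n_fixed`, ids, `C`, `d`, `response`),
#'   `ranking` (a `model_ranking`), `dev_test` (best vs complete model)
#'   and `response_used`.
#' @export
metastability_analysis <- function(results, seed = 1,
                                   response = c("auto", "neg_dissimilarity",
                                                "overlap")) {
  response <- match.arg(response)
  sp_cols <- grep("^sp[0-9]+$", names(results), value = TRUE)
  if (length(sp_cols) == 0) abort("no species abundance columns (sp1, sp2, ...)")
  set.seed(seed)

  pairs <- results %>%
    dplyr::group_by(.data$connectivity, .data$n_fixed) %>%
    dplyr::group_modify(function(df, key) {
      pr <- pair_replicates(df$replicate)
      ab <- as.matrix(df[, sp_cols])
      rownames(ab) <- as.character(df$replicate)
      purrr::pmap_dfr(pr, function(id_a, id_b) {
        C <- morisita_overlap(ab[as.character(id_a), ],
                              ab[as.character(id_b), ])
        tibble::tibble(id_a = id_a, id_b = id_b, C = C, d = 1 - C)
      })
    }) %>%
    dplyr::ungroup()

  used <- switch(response,
                 auto = if (all(pairs$d < 0)) "neg_dissimilarity" else "overlap",
                 response)
  pairs$response <- switch(used,
                           neg_dissimilarity = -pairs$d,
                           overlap = pairs$C)
  if (any(pairs$response <= 0)) {
    abort(paste0("response '", used, "' is not strictly positive; ",
                 "use response = 'overlap'"))
  }

  dat <- pairs %>% dplyr::rename(Con = "connectivity", Fix = "n_fixed")
  fits <- list(
    null = fit_gamma_glm(dat, response ~ 1),
    Con = fit_gamma_glm(dat, response ~ Con),
    Fix = fit_gamma_glm(dat, response ~ Fix),
    `Con + Fix` = fit_gamma_glm(dat, response ~ Con + Fix),
    `Con + Fix + Con:Fix` = fit_gamma_glm(dat, response ~ Con * Fix)
  )
  ranking <- rank_models(fits)
  best <- ranking$model[1]
  dev_test <- deviance_test(fits[[best]], fits[["Con + Fix + Con:Fix"]])

  structure(list(pairs = pairs, ranking = ranking, dev_test = dev_test,
                 fits = fits, response_used = used),
            class = "metastability_analysis")
}

#' @export
print.metastability_analysis <- function(x, ...) {
  cat("<metastability_analysis> ", nrow(x$pairs), " pairs, response = ",
      x$response_used, "\n", sep = "")
  print(tibble::as_tibble(x$ranking))
  print(x$dev_test)
  invisible(x)
}
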