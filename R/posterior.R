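#' Variance partition coefficients
#'
#' The share of total latent-tie variance attributable to groups, actors,
#' partners, and dyads. The dyadic variance is fixed at 1 by the probit
#' identification constraint, so the total is
#' `sigma2_m + sigma2_a + sigma2_b + 1` and the four shares sum to 1.
#' Vectorised: pass posterior draws to obtain per-draw VPCs.
#'
#' @param sigma2_m,sigma2_a,sigma2_b Nonnegative variance components
#'   (scalars or vectors of equal length).
#' @return A tibble with columns `p_m`, `p_a`, `p_b`, `p_e`.
#' @examples
#' vpc(0.15, 1.17, 0.71) # 0.05, 0.39, 0.23, 0.33 at two decimals
#' @export
vpc <- function(sigma2_m, sigma2_a, sigma2_b) {
  if (any(sigma2_m < 0, na.rm = TRUE) || any(sigma2_a < 0, na.rm = TRUE) ||
    any(sigma2_b < 0, na.rm = TRUE)) {
    abort("variances must be nonnegative", class = "srmtie_domain_error")
  }
  total <- sigma2_m + sigma2_a + sigma2_b + 1
  tibble::tibble(
    p_m = sigma2_m / total,
    p_a = sigma2_a / total,
    p_b = sigma2_b / total,
    p_e = 1 / total
  )
}

#' Fraction of a variance component explained by added predictors
#'
#' `(var_before - var_after) / var_before`: the proportional reduction in a
#' random-effect variance when covariates are added (e.g. partner variance
#' 0.71 in the empty model falling to 0.50 under the full covariate set is
#' a reduction of about 30%).
#'
#' @param var_before Baseline variance (> 0).
#' @param var_after Variance after adding predictors.
#' @return The explained fraction.
#' @export
variance_explained <- function(var_before, var_after) {
  if (any(var_before <= 0)) {
    abort("baseline variance must be positive", class = "srmtie_domain_error")
  }
  (var_before - var_after) / var_before
}

srm_parameter_cols <- function(draws) {
  setdiff(names(draws), c(".chain", ".iteration"))
}

#' Tidy posterior summary of a probit SRM fit
#'
#' One row per parameter (coefficients, variance components, reciprocity
#' correlations, and per-draw variance partition coefficients) with the
#' posterior mean, standard deviation, central credible interval, effective
#' sample size, and split-chain potential scale reduction (reported as `NA`
#' with a single chain).
#'
#' @param x An `srm_fit`.
#' @param conf_level Width of the equal-tailed credible interval.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `ess`, `rhat`.
#' @method tidy srm_fit
#' @export
tidy.srm_fit <- function(x, conf_level = 0.90, ...) {
  draws <- x$draws
  chains <- sort(unique(draws$.chain))
  alpha <- (1 - conf_level) / 2
  purrr::map_dfr(srm_parameter_cols(draws), function(par) {
    v <- draws[[par]]
    if (all(is.na(v))) {
      return(NULL)
    }
    mat <- matrix(v, ncol = length(chains))
    tibble::tibble(
      term = par,
      estimate = mean(v),
      std.error = sd(v),
      conf.low = unname(quantile(v, alpha)),
      conf.high = unname(quantile(v, 1 - alpha)),
      ess = mcmc_ess(mat),
      rhat = if (length(chains) >= 2) mcmc_rhat(mat) else NA_real_
    )
  })
}

#' One-line summary of a probit SRM fit
#'
#' @param x An `srm_fit`.
#' @param ... Unused.
#' @return A one-row tibble with chain/draw counts, the Metropolis
#'   acceptance rate for the dyadic correlation, and worst-case convergence
#'   diagnostics.
#' @method glance srm_fit
#' @export
glance.srm_fit <- function(x, ...) {
  s <- tidy(x)
  tibble::tibble(
    model = x$model,
    n_obs = x$n_obs,
    chains = x$config$chains,
    draws = nrow(x$draws),
    accept_rho = mean(x$accept_rho),
    min_ess = min(s$ess, na.rm = TRUE),
    max_rhat = if (all(is.na(s$rhat))) NA_real_ else max(s$rhat, na.rm = TRUE)
  )
}

coef_matrix <- function(fit) {
  as.matrix(fit$draws[, fit$terms, drop = FALSE])
}

align_coefs <- function(coefs, terms) {
  if (!is.null(names(coefs)) && all(terms %in% names(coefs))) {
    coefs <- coefs[terms]
  } else if (length(coefs) != length(terms)) {
    abort(paste0(
      "coefficient vector must cover the design terms: ",
      paste(terms, collapse = ", ")
    ), class = "srmtie_config_error")
  }
  unname(coefs)
}

#' Plug-in predicted tie probability
#'
#' `Phi(x'beta)` with all random effects at zero: the conditional
#' (cluster-average) probability of a directed tie at the given covariate
#' setting. For posterior-draw-averaged predictions with credible bands, use
#' [prediction_grid()].
#'
#' @param coefs Coefficient vector (named by design term, or positional).
#' @param settings A data frame (or named list) of covariate values on the
#'   transformed scale, one row per setting; must cover every variable the
#'   model formula uses.
#' @param model One of [srm_models()].
#' @return Numeric vector of probabilities, one per setting row.
#' @examples
#' b <- nba_reference_estimates()$model2
#' predicted_probability(b,
#'   tibble::tibble(allstar_i = 4 / 17, performance = c(-1, 1)),
#'   model = "status_by_performance"
#' )
#' @export
predicted_probability <- function(coefs, settings, model = "empty") {
  settings <- tibble::as_tibble(settings)
  X <- build_design(settings, model)
  unname(drop(pnorm(X %*% align_coefs(coefs, colnames(X)))))
}

#' Posterior prediction grid
#'
#' Evaluates `Phi(x'beta)` for every stored posterior draw at each covariate
#' setting (random effects at zero) and summarises with the posterior mean
#' and a central credible band.
#'
#' @param fit An `srm_fit` (or a data frame of posterior coefficient draws
#'   whose columns are the design terms, in which case `model` must be
#'   given).
#' @param grid Data frame of covariate settings, one row per grid point.
#' @param model Model name; defaults to the fit's model.
#' @param level Credible-band mass (default 0.90, equal-tailed).
#' @return An `srm_prediction` tibble: the grid columns plus `estimate`
#'   (posterior-mean probability), `conf.low`, `conf.high`.
#' @export
prediction_grid <- function(fit, grid, model = NULL, level = 0.90) {
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0) {
    abort("empty prediction grid", class = "srmtie_config_error")
  }
  if (inherits(fit, "srm_fit")) {
    beta <- coef_matrix(fit)
    model <- model %||% fit$model
  } else {
    if (is.null(model)) {
      abort("model must be supplied with raw draws", class = "srmtie_config_error")
    }
    beta <- as.matrix(fit)
  }
  X <- build_design(grid, model)
  beta <- beta[, colnames(X), drop = FALSE]
  probs <- pnorm(X %*% t(beta)) # settings x draws
  alpha <- (1 - level) / 2
  out <- dplyr::bind_cols(
    grid,
    tibble::tibble(
      estimate = unname(rowMeans(probs)),
      conf.low = unname(apply(probs, 1, quantile, alpha)),
      conf.high = unname(apply(probs, 1, quantile, 1 - alpha))
    )
  )
  class(out) <- c("srm_prediction", class(out))
  attr(out, "level") <- level
  out
}

#' Side-by-side posterior summary table for a model sequence
#'
#' Formats several fits in the conventional reporting layout: one row per
#' parameter, one column per model, cells showing "posterior mean (sd)".
#'
#' @param fits Named list of `srm_fit` objects (names become columns).
#' @param digits Decimal places.
#' @return A tibble with a `parameter` column plus one column per fit.
#' @export
srm_report <- function(fits, digits = 2) {
  stopifnot(is.list(fits), length(fits) > 0)
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  cols <- purrr::imap(fits, function(fit, nm) {
    s <- tidy(fit)
    tibble::tibble(
      parameter = s$term,
      !!nm := sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
        s$estimate, s$std.error
      )
    )
  })
  purrr::reduce(cols, dplyr::full_join, by = "parameter")
}

#' Persist posterior draws as long-format CSV
#'
#' Columns `chain`, `iteration`, `parameter`, `value`; re-readable with
#' standard tools.
#'
#' @param fit An `srm_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  long <- tidyr::pivot_longer(fit$draws, -c(".chain", ".iteration"),
    names_to = "parameter", values_to = "value"
  )
  long <- dplyr::rename(long, chain = ".chain", iteration = ".iteration")
  readr::write_csv(long, path, progress = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest for a fit
#'
#' Records the model, seed, MCMC configuration, prior hyperparameters, data
#' dimensions, and acceptance diagnostics as JSON.
#'
#' @param fit An `srm_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(fit, path) {
  manifest <- list(
    model = fit$model,
    terms = fit$terms,
    config = unclass(fit$config),
    prior = unclass(fit$prior),
    n_obs = fit$n_obs,
    n_groups = fit$n_groups,
    n_individuals = fit$n_individuals,
    accept_rho = fit$accept_rho
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
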