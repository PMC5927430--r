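#' Prior specification for the probit SRM
#'
#' Diffuse-but-proper defaults: independent normal(0, `beta_sd`^2) priors on
#' regression coefficients; half-t(`nu`, scale) priors on the group, actor,
#' and partner standard deviations and a marginal uniform(-1, 1) prior on the
#' actor-partner correlation, implemented jointly through the Huang-Wand
#' auxiliary inverse-gamma construction (an inverse-Wishart on the
#' actor-partner covariance mixed over auxiliary scales), which keeps every
#' conditional conjugate; and a uniform(-1, 1) prior on the dyadic
#' reciprocity correlation. With `nu = 2` the implied correlation prior is
#' exactly uniform.
#'
#' @param beta_sd Prior standard deviation of each regression coefficient.
#' @param nu Degrees of freedom of the half-t scale priors (2 gives a
#'   uniform marginal prior on the actor-partner correlation).
#' @param scale_m Half-t scale for the group (team) standard deviation.
#' @param scale_a,scale_b Half-t scales for the actor and partner standard
#'   deviations.
#' @return An `srm_prior` list.
#' @export
srm_prior <- function(beta_sd = 10, nu = 2, scale_m = 5, scale_a = 5, scale_b = 5) {
  stopifnot(beta_sd > 0, nu > 0, scale_m > 0, scale_a > 0, scale_b > 0)
  structure(
    list(
      beta_sd = beta_sd, nu = nu,
      scale_m = scale_m, scale_a = scale_a, scale_b = scale_b
    ),
    class = "srm_prior"
  )
}

#' MCMC configuration
#'
#' The default is a desk-scale configuration (4 chains, 2,000 burn-in sweeps,
#' 10,000 sampling sweeps thinned by 10, i.e. 1,000 stored draws per chain).
#' The large-scale configuration used for the published NBA fits (100,000
#' burn-in, 1,000,000 sweeps, thin 200) is available by setting the fields
#' explicitly.
#'
#' @param chains Number of independent chains (seeded `seed`, `seed + 1`, ...).
#' @param burn_in Discarded warm-up sweeps per chain.
#' @param iterations Post-burn-in sweeps per chain.
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param seed Integer base seed; identical (seed, config, data) gives
#'   bit-identical draws.
#' @param step_init Initial random-walk step (on the Fisher-z scale) of the
#'   Metropolis update for the dyadic reciprocity correlation.
#' @param adapt_every Step-size adaptation interval; adaptation runs only
#'   during burn-in (then freezes, preserving detailed balance).
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(chains = 4, burn_in = 2000, iterations = 10000,
                        thin = 10, seed = 1, step_init = 0.25,
                        adapt_every = 50) {
  stopifnot(
    chains >= 1, burn_in >= 0, iterations >= 1, thin >= 1,
    step_init > 0, adapt_every >= 1
  )
  if (floor(iterations / thin) < 1) {
    abort("configuration stores zero samples", class = "srmtie_config_error")
  }
  structure(
    list(
      chains = as.integer(chains), burn_in = as.integer(burn_in),
      iterations = as.integer(iterations), thin = as.integer(thin),
      seed = as.integer(seed), step_init = step_init,
      adapt_every = as.integer(adapt_every)
    ),
    class = "mcmc_config"
  )
}

#' SRM parameter set
#'
#' Bundles regression coefficients and variance components; used as the
#' truth for [simulate_srm_network()] and for plug-in computations. The
#' dyadic residual variances are fixed at 1 (the probit identification
#' constraint), so the dyadic covariance is fully described by `rho_ee`.
#'
#' @param beta Numeric coefficient vector (length must match the design of
#'   the model it is used with; a single intercept for the empty model).
#' @param sigma2_m Group-level variance (>= 0).
#' @param sigma2_a,sigma2_b Actor and partner variances (>= 0).
#' @param rho_ab Generalized reciprocity correlation, in (-1, 1).
#' @param rho_ee Dyadic reciprocity correlation, in (-1, 1).
#' @return An `srm_params` list with the implied 2x2 actor-partner
#'   covariance in `$Sigma_ab`.
#' @export
srm_params <- function(beta = 0, sigma2_m = 0.15, sigma2_a = 1.17,
                       sigma2_b = 0.71, rho_ab = 0.75, rho_ee = 0.90) {
  if (sigma2_m < 0 || sigma2_a < 0 || sigma2_b < 0) {
    abort("variances must be nonnegative", class = "srmtie_domain_error")
  }
  if (abs(rho_ab) >= 1 || abs(rho_ee) >= 1) {
    abort("correlations must lie in (-1, 1)", class = "srmtie_domain_error")
  }
  sab <- rho_ab * sqrt(sigma2_a * sigma2_b)
  Sigma_ab <- matrix(c(sigma2_a, sab, sab, sigma2_b), 2, 2)
  structure(
    list(
      beta = beta, sigma2_m = sigma2_m, sigma2_a = sigma2_a,
      sigma2_b = sigma2_b, rho_ab = rho_ab, rho_ee = rho_ee,
      Sigma_ab = Sigma_ab
    ),
    class = "srm_params"
  )
}
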