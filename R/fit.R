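#' Fit the multilevel probit Social Relations Model
#'
#' Gibbs sampler with latent-variable augmentation for directed binary ties
#' in a round-robin multi-group design. The latent tie propensity of row
#' `(i -> j, group k)` is
#' `y* = x'beta + m_k + a_i + b_j + e_ij`, with the observed tie equal to 1
#' exactly when `y* >= 0`; `m_k` is a group effect, `(a_i, b_i)` a bivariate
#' actor-partner pair with covariance `Sigma_ab` (correlation `rho_ab`,
#' generalized reciprocity), and the two directed residuals of each dyad are
#' standard bivariate normal with correlation `rho_ee` (dyadic reciprocity;
#' unit variances identify the probit scale).
#'
#' One sweep updates, in order: the latent propensities (blocked by
#' direction, each row drawn from its truncated-normal conditional given its
#' reverse row), the coefficients (generalized-least-squares conjugate step
#' that whitens the paired dyadic residuals), the group effects and their
#' variance, the actor-partner pairs (sequential per-individual bivariate
#' conditionals) and their covariance (inverse-Wishart step of the
#' Huang-Wand prior), and finally `rho_ee` by adaptive random-walk
#' Metropolis on the Fisher-z scale (adaptation frozen after burn-in).
#'
#' @param data A [as_dyad_data()] tibble with the covariate columns the
#'   chosen model needs (already transformed; see
#'   [standardize_covariates()]).
#' @param model One of [srm_models()]; ignored when `design` is supplied.
#' @param design Optional design matrix overriding [build_design()]; must
#'   have one row per observation.
#' @param prior An [srm_prior()].
#' @param config An [mcmc_config()].
#' @param fix_rho_ee Optionally fix the dyadic reciprocity correlation (e.g.
#'   0 for conditionally independent directed residuals).
#' @param drop_partner If `TRUE`, omit partner effects (`b = 0`), reducing
#'   the model to a probit actor-effect GLMM; requires `fix_rho_ee = 0`.
#' @return An object of class `srm_fit`: a list with `draws` (tibble with
#'   `.chain`, `.iteration`, one column per coefficient, the variance
#'   components, both reciprocity correlations, and the per-draw variance
#'   partition coefficients `p_m`, `p_a`, `p_b`, `p_e`), `accept_rho`
#'   (per-chain Metropolis acceptance rate), `terms`, `model`, `config`,
#'   `prior`.
#' @seealso [tidy.srm_fit()], [glance.srm_fit()], [prediction_grid()],
#'   [simulate_srm_network()]
#' @export
srm_fit <- function(data, model = "empty", design = NULL,
                    prior = srm_prior(), config = mcmc_config(),
                    fix_rho_ee = NULL, drop_partner = FALSE) {
  if (!inherits(data, "dyad_data")) data <- as_dyad_data(data)
  if (is.null(design)) {
    design <- build_design(data, model)
  } else {
    model <- "custom"
    if (nrow(design) != nrow(data)) {
      abort("design row count must match the dataset", class = "srmtie_config_error")
    }
    if (is.null(colnames(design))) {
      colnames(design) <- paste0("x", seq_len(ncol(design)))
    }
  }
  if (drop_partner && (is.null(fix_rho_ee) || fix_rho_ee != 0)) {
    abort("drop_partner requires fix_rho_ee = 0", class = "srmtie_config_error")
  }

  prep <- srm_prepare(data, design)
  n_store <- floor(config$iterations / config$thin)

  chains <- vector("list", config$chains)
  accept <- numeric(config$chains)
  for (ch in seq_len(config$chains)) {
    res <- srm_run_chain(prep, prior, config,
      chain_id = ch, n_store = n_store,
      fix_rho_ee = fix_rho_ee, drop_partner = drop_partner
    )
    draws <- tibble::as_tibble(res$draws)
    draws <- dplyr::bind_cols(
      tibble::tibble(.chain = ch, .iteration = seq_len(n_store)), draws
    )
    chains[[ch]] <- draws
    accept[ch] <- res$accept_rate
  }
  draws <- dplyr::bind_rows(chains)
  draws <- dplyr::bind_cols(
    draws,
    vpc(draws$sigma2_m, draws$sigma2_a, draws$sigma2_b)
  )

  structure(
    list(
      draws = draws,
      accept_rho = accept,
      terms = colnames(prep$X),
      model = model,
      config = config,
      prior = prior,
      drop_partner = drop_partner,
      fix_rho_ee = fix_rho_ee,
      n_obs = prep$n, n_groups = prep$K, n_individuals = prep$N
    ),
    class = "srm_fit"
  )
}

#' @export
print.srm_fit <- function(x, ...) {
  cat(sprintf(
    "Multilevel probit SRM fit ('%s' model)\n  %d directed observations, %d groups, %d individuals\n  %d chains x %d stored draws; Metropolis acceptance (rho_ee): %s\n",
    x$model, x$n_obs, x$n_groups, x$n_individuals,
    x$config$chains, nrow(x$draws) / x$config$chains,
    paste(sprintf("%.2f", x$accept_rho), collapse = ", ")
  ))
  print(tidy(x), n = 30)
  invisible(x)
}

# ---- internal machinery -----------------------------------------------------

# Index structures shared by all chains.
srm_prepare <- function(data, X) {
  n <- nrow(data)
  if (n %% 2 != 0) abort("odd row count; not a round robin", class = "srmtie_data_error")
  rev <- reverse_index(data)

  groups <- unique(data$group)
  gidx <- match(data$group, groups)
  K <- length(groups)

  inds <- unique(c(
    paste(data$group, data$actor, sep = "\r"),
    paste(data$group, data$partner, sep = "\r")
  ))
  ia <- match(paste(data$group, data$actor, sep = "\r"), inds)
  ip <- match(paste(data$group, data$partner, sep = "\r"), inds)
  N <- length(inds)
  ind_group <- gidx[match(inds, paste(data$group, data$actor, sep = "\r"))]
  ind_group[is.na(ind_group)] <-
    gidx[match(inds[is.na(ind_group)], paste(data$group, data$partner, sep = "\r"))]
  group_size <- tabulate(ind_group, nbins = K)

  dir1 <- which(data$actor < data$partner)
  dir2 <- which(data$actor > data$partner)

  list(
    y = as.numeric(data$outcome), X = X, n = n, p = ncol(X),
    rev = rev, gidx = gidx, K = K,
    ia = ia, ip = ip, N = N, ind_group = ind_group,
    c_ind = group_size[ind_group] - 1,
    n_rows_g = tabulate(gidx, nbins = K),
    out_rows = split(seq_len(n), factor(ia, levels = seq_len(N))),
    in_rows = split(seq_len(n), factor(ip, levels = seq_len(N))),
    dir1 = dir1, dir2 = dir2,
    XtX = crossprod(X), XtXrev = crossprod(X, X[rev, , drop = FALSE])
  )
}

# Draw from N(mean, sd^2) truncated to [0, Inf) when y = 1, (-Inf, 0) when
# y = 0, by inverse-CDF in the relevant tail (stable for |mean/sd| well past
# anything this model produces).
rtrunc_sign <- function(y, mean, sd) {
  s <- 2 * y - 1
  u <- runif(length(y))
  tail_p <- pnorm(0, mean = s * mean, sd = sd, lower.tail = FALSE)
  z <- qnorm(u * tail_p, mean = s * mean, sd = sd, lower.tail = FALSE)
  bad <- !is.finite(z) | z <= 0
  if (any(bad)) z[bad] <- 1e-8
  s * z
}

srm_init_state <- function(prep, prior, config, fix_rho_ee, drop_partner) {
  beta <- tryCatch(
    {
      fit <- suppressWarnings(glm.fit(prep$X, prep$y, family = binomial("probit")))
      b <- coef(fit)
      b[!is.finite(b)] <- 0
      unname(b)
    },
    error = function(e) numeric(prep$p)
  )
  xb <- drop(prep$X %*% beta)
  mu <- xb
  # latent start at the truncated-normal mean given the probit fit
  ystar <- ifelse(prep$y == 1,
    mu + dnorm(mu) / pmax(pnorm(mu), 1e-10),
    mu - dnorm(mu) / pmax(pnorm(-mu), 1e-10)
  )
  list(
    beta = beta, xb = xb, ystar = ystar,
    m = numeric(prep$K), a = numeric(prep$N), b = numeric(prep$N),
    a_row = numeric(prep$n), b_row = numeric(prep$n),
    s2m = 0.1,
    Sab = diag(c(0.5, 0.5)),
    aux_m = 1, aux_ab = c(1, 1),
    rho = if (is.null(fix_rho_ee)) 0 else fix_rho_ee,
    fix_rho = !is.null(fix_rho_ee),
    drop_partner = drop_partner,
    step = config$step_init,
    acc_window = 0L, n_window = 0L, acc_total = 0L, n_total = 0L
  )
}

# Systematic part of the latent propensity: x'beta + m_k + a_i + b_j per row.
srm_mu <- function(st, prep) {
  st$xb + st$m[prep$gidx] + st$a_row + st$b_row
}

update_latents <- function(st, prep) {
  mu <- srm_mu(st, prep)
  rho <- st$rho
  if (rho == 0) {
    st$ystar <- rtrunc_sign(prep$y, mu, 1)
  } else {
    sdv <- sqrt(1 - rho^2)
    for (idx in list(prep$dir1, prep$dir2)) {
      r <- prep$rev[idx]
      cm <- mu[idx] + rho * (st$ystar[r] - mu[r])
      st$ystar[idx] <- rtrunc_sign(prep$y[idx], cm, sdv)
    }
  }
  st
}

update_beta <- function(st, prep, prior) {
  rho <- st$rho
  q <- 1 - rho^2
  z <- st$ystar - st$m[prep$gidx] - st$a_row - st$b_row
  A <- (prep$XtX - rho * prep$XtXrev) / q
  rhs <- (crossprod(prep$X, z) - rho * crossprod(prep$X, z[prep$rev])) / q
  post_prec <- A + diag(1 / prior$beta_sd^2, prep$p)
  R <- chol(post_prec)
  mean_b <- backsolve(R, forwardsolve(t(R), rhs))
  st$beta <- drop(mean_b + backsolve(R, rnorm(prep$p)))
  st$xb <- drop(prep$X %*% st$beta)
  st
}

update_group_effects <- function(st, prep, prior) {
  resid <- st$ystar - st$xb - st$a_row - st$b_row
  sums <- as.vector(rowsum(resid, factor(prep$gidx, levels = seq_len(prep$K))))
  prec <- prep$n_rows_g / (1 + st$rho) + 1 / st$s2m
  mean_m <- (sums / (1 + st$rho)) / prec
  st$m <- mean_m + rnorm(prep$K) / sqrt(prec)

  nu <- prior$nu
  st$s2m <- 1 / rgamma(1,
    shape = (nu + prep$K) / 2,
    rate = nu / st$aux_m + 0.5 * sum(st$m^2)
  )
  st$aux_m <- 1 / rgamma(1,
    shape = (nu + 1) / 2,
    rate = nu / st$s2m + 1 / prior$scale_m^2
  )
  st
}

update_actor_partner <- function(st, prep, prior) {
  w <- st$ystar - st$xb - st$m[prep$gidx]
  nu <- prior$nu

  if (st$drop_partner) {
    # probit actor-effect GLMM reduction: rows independent (rho fixed at 0)
    S1 <- as.vector(rowsum(w, factor(prep$ia, levels = seq_len(prep$N))))
    s2a <- st$Sab[1, 1]
    prec <- prep$c_ind + 1 / s2a
    st$a <- S1 / prec + rnorm(prep$N) / sqrt(prec)
    st$a_row <- st$a[prep$ia]
    s2a <- 1 / rgamma(1,
      shape = (nu + prep$N) / 2,
      rate = nu / st$aux_ab[1] + 0.5 * sum(st$a^2)
    )
    st$aux_ab[1] <- 1 / rgamma(1,
      shape = (nu + 1) / 2,
      rate = nu / s2a + 1 / prior$scale_a^2
    )
    st$Sab <- diag(c(s2a, 0))
    return(st)
  }

  rho <- st$rho
  q1 <- 1 / (1 - rho^2)
  q2 <- -rho / (1 - rho^2)
  Sinv <- solve2x2(st$Sab)
  a <- st$a
  b <- st$b
  a_row <- st$a_row
  b_row <- st$b_row
  out_rows <- prep$out_rows
  in_rows <- prep$in_rows
  c_ind <- prep$c_ind
  z <- matrix(rnorm(2 * prep$N), prep$N, 2)

  for (i in seq_len(prep$N)) {
    out <- out_rows[[i]]
    inn <- in_rows[[i]]
    S1 <- sum(w[out]) - sum(b_row[out])
    S2 <- sum(w[inn]) - sum(a_row[inn])
    ci <- c_ind[i]
    P11 <- ci * q1 + Sinv[1, 1]
    P12 <- ci * q2 + Sinv[1, 2]
    P22 <- ci * q1 + Sinv[2, 2]
    r1 <- q1 * S1 + q2 * S2
    r2 <- q2 * S1 + q1 * S2
    det <- P11 * P22 - P12^2
    mu1 <- (P22 * r1 - P12 * r2) / det
    mu2 <- (P11 * r2 - P12 * r1) / det
    # sample via the Cholesky of the 2x2 precision
    L11 <- sqrt(P11)
    L21 <- P12 / L11
    L22 <- sqrt(P22 - L21^2)
    d2 <- z[i, 2] / L22
    d1 <- (z[i, 1] - L21 * d2) / L11
    ai <- mu1 + d1
    bi <- mu2 + d2
    a[i] <- ai
    b[i] <- bi
    a_row[out] <- ai
    b_row[inn] <- bi
  }
  st$a <- a
  st$b <- b
  st$a_row <- a_row
  st$b_row <- b_row

  S <- matrix(
    c(sum(a * a), sum(a * b), sum(a * b), sum(b * b)), 2, 2
  )
  df <- nu + 1 + prep$N
  scale_mat <- diag(2 * nu / st$aux_ab) + S
  st$Sab <- rinvwishart(df, scale_mat)
  Sinv_new <- solve2x2(st$Sab)
  st$aux_ab <- 1 / rgamma(2,
    shape = (nu + 2) / 2,
    rate = nu * diag(Sinv_new) + 1 / c(prior$scale_a, prior$scale_b)^2
  )
  st
}

rho_logpost_z <- function(z, Qs, Cs, npair) {
  rho <- tanh(z)
  -0.5 * npair * log(1 - rho^2) - (Qs - rho * Cs) / (2 * (1 - rho^2)) +
    log(1 - rho^2) # Jacobian of z -> rho under a uniform prior on rho
}

update_rho_ee <- function(st, prep, adapt) {
  if (st$fix_rho) {
    return(st)
  }
  e <- st$ystar - srm_mu(st, prep)
  Qs <- sum(e * e)
  Cs <- sum(e * e[prep$rev])
  npair <- prep$n / 2

  z <- atanh(st$rho)
  zp <- z + st$step * rnorm(1)
  log_ratio <- rho_logpost_z(zp, Qs, Cs, npair) - rho_logpost_z(z, Qs, Cs, npair)
  accepted <- is.finite(log_ratio) && log(runif(1)) < log_ratio
  if (accepted) st$rho <- tanh(zp)

  st$acc_window <- st$acc_window + accepted
  st$n_window <- st$n_window + 1L
  st$acc_total <- st$acc_total + accepted
  st$n_total <- st$n_total + 1L
  if (adapt && st$n_window >= attr(st, "adapt_every") %||% 50L) {
    rate <- st$acc_window / st$n_window
    st$step <- min(2, max(0.01, st$step * exp(0.7 * (rate - 0.44))))
    st$acc_window <- 0L
    st$n_window <- 0L
  }
  st
}

srm_sweep <- function(st, prep, prior, adapt = FALSE) {
  st <- update_latents(st, prep)
  st <- update_beta(st, prep, prior)
  st <- update_group_effects(st, prep, prior)
  st <- update_actor_partner(st, prep, prior)
  st <- update_rho_ee(st, prep, adapt)
  st
}

srm_run_chain <- function(prep, prior, config, chain_id, n_store,
                          fix_rho_ee = NULL, drop_partner = FALSE) {
  set.seed(config$seed + chain_id - 1)
  st <- srm_init_state(prep, prior, config, fix_rho_ee, drop_partner)
  attr(st, "adapt_every") <- config$adapt_every

  par_names <- c(
    colnames(prep$X), "sigma2_m", "sigma2_a", "sigma2_b", "rho_ab", "rho_ee"
  )
  draws <- matrix(NA_real_, n_store, length(par_names),
    dimnames = list(NULL, par_names)
  )

  for (it in seq_len(config$burn_in)) {
    st <- srm_sweep(st, prep, prior, adapt = TRUE)
  }
  row <- 0L
  for (it in seq_len(config$iterations)) {
    st <- srm_sweep(st, prep, prior, adapt = FALSE)
    if (it %% config$thin == 0) {
      row <- row + 1L
      s2a <- st$Sab[1, 1]
      s2b <- st$Sab[2, 2]
      rho_ab <- if (drop_partner) NA_real_ else st$Sab[1, 2] / sqrt(s2a * s2b)
      draws[row, ] <- c(st$beta, st$s2m, s2a, s2b, rho_ab, st$rho)
    }
  }
  if (anyNA(draws[, c("sigma2_m", "sigma2_a", "rho_ee")])) {
    abort("sampler produced non-finite draws", class = "srmtie_numeric_error")
  }
  list(
    draws = draws,
    accept_rate = if (st$n_total > 0) st$acc_total / st$n_total else NA_real_
  )
}

# Regenerate (y*, y) from the current parameters and random effects; used by
# the successive-conditional (joint distribution) sampler checks.
srm_regenerate_data <- function(st, prep) {
  npair <- prep$n / 2
  e <- numeric(prep$n)
  z1 <- rnorm(npair)
  z2 <- st$rho * z1 + sqrt(1 - st$rho^2) * rnorm(npair)
  e[prep$dir1] <- z1
  e[prep$rev[prep$dir1]] <- z2
  ystar <- st$xb + st$m[prep$gidx] + st$a_row + st$b_row + e
  list(ystar = ystar, y = as.numeric(ystar >= 0))
}

# ---- small numeric helpers --------------------------------------------------

solve2x2 <- function(S) {
  det <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (!is.finite(det) || det <= 0) {
    abort("actor-partner covariance is not positive definite",
      class = "srmtie_numeric_error"
    )
  }
  matrix(c(S[2, 2], -S[1, 2], -S[1, 2], S[1, 1]), 2, 2) / det
}

rinvwishart <- function(df, S) {
  W <- rWishart(1, df, solve(S))[, , 1]
  V <- solve(W)
  (V + t(V)) / 2
}

#' @importFrom stats rgamma glm.fit
NULL

#' Log-likelihood of one observed dyad
#'
#' The log orthant probability that a bivariate-normal pair of latent
#' propensities with means `mu_pair`, unit variances, and correlation
#' `rho_ee` falls in the quadrant implied by the two directed binary
#' outcomes. With `rho_ee = 0` this is the sum of the two univariate probit
#' log-likelihoods.
#'
#' @param outcome_pair Numeric pair of 0/1 outcomes `(y_ij, y_ji)`.
#' @param mu_pair Numeric pair of latent means `(mu_ij, mu_ji)`.
#' @param rho_ee Dyadic residual correlation in (-1, 1).
#' @return A single log-probability.
#' @export
dyad_loglik <- function(outcome_pair, mu_pair, rho_ee) {
  if (abs(rho_ee) >= 1) {
    abort("rho_ee must lie in (-1, 1)", class = "srmtie_domain_error")
  }
  stopifnot(length(outcome_pair) == 2, length(mu_pair) == 2)
  if (!all(outcome_pair %in% c(0, 1))) {
    abort("outcomes must be 0/1", class = "srmtie_data_error")
  }
  s <- 2 * outcome_pair - 1
  # P(s1(mu1 + e1) >= 0, s2(mu2 + e2) >= 0) = Phi2(s1 mu1, s2 mu2; s1 s2 rho)
  log(pbinorm(s[1] * mu_pair[1], s[2] * mu_pair[2], s[1] * s[2] * rho_ee))
}

# Bivariate standard-normal CDF P(X <= a, Y <= b) with correlation r, by
# reducing to a one-dimensional integral of phi(x) * Phi((b - r x)/sqrt(1-r^2)).
pbinorm <- function(a, b, r) {
  if (r == 0) {
    return(pnorm(a) * pnorm(b))
  }
  s <- sqrt(1 - r^2)
  f <- function(x) dnorm(x) * pnorm((b - r * x) / s)
  val <- integrate(f,
    lower = -Inf, upper = a,
    rel.tol = 1e-12, abs.tol = 1e-14, stop.on.error = FALSE
  )$value
  min(max(val, 1e-300), 1)
}
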