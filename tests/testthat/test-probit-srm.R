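# Component-level checks of the Gibbs sampler against independent oracles.

make_state <- function(d, model = "empty", prior = srm_prior(), seed = 1) {
  X <- build_design(d, model)
  prep <- srmtie:::srm_prepare(d, X)
  st <- srmtie:::srm_init_state(prep, prior, mcmc_config(seed = seed), NULL, FALSE)
  attr(st, "adapt_every") <- 50L
  list(prep = prep, st = st, X = X)
}

zero_effects <- function(st, prep) {
  st$m <- numeric(prep$K)
  st$a <- numeric(prep$N)
  st$b <- numeric(prep$N)
  st$a_row <- numeric(prep$n)
  st$b_row <- numeric(prep$n)
  st
}

test_that("the latent mean equals the brute-force sum of its parts", {
  set.seed(31)
  d <- small_sim(seed = 31, n_groups = 3, sizes = c(4, 5))
  ms <- make_state(d)
  st <- ms$st
  prep <- ms$prep
  st$beta <- rnorm(1)
  st$xb <- drop(ms$X %*% st$beta)
  st$m <- rnorm(prep$K, 0, 0.5)
  st$a <- rnorm(prep$N)
  st$b <- rnorm(prep$N)
  st$a_row <- st$a[prep$ia]
  st$b_row <- st$b[prep$ip]

  mu <- srmtie:::srm_mu(st, prep)
  brute <- vapply(seq_len(prep$n), function(r) {
    sum(ms$X[r, ] * st$beta) + st$m[prep$gidx[r]] +
      st$a[prep$ia[r]] + st$b[prep$ip[r]]
  }, numeric(1))
  expect_equal(mu, brute, tolerance = 1e-12)

  # plain fixed-effect sum: zero coefficients, known effects
  st2 <- zero_effects(st, prep)
  st2$beta <- 0
  st2$xb <- rep(0, prep$n)
  st2$m <- rep(0.5, prep$K)
  st2$a_row <- rep(-0.2, prep$n)
  st2$b_row <- rep(0.1, prep$n)
  expect_equal(unique(srmtie:::srm_mu(st2, prep)), 0.4)
})

test_that("the status-by-performance linear predictor reproduces the reference cell", {
  X <- build_design(
    tibble::tibble(allstar_i = 4 / 17, performance = 1),
    "status_by_performance"
  )
  beta <- c(0.20, -2.92, 0.23, 1.80)
  expect_equal(round(drop(X %*% beta), 3), 0.166)
})

test_that("dyad log-likelihood factorises at rho 0 and matches symmetric quadrants", {
  # independence: sum of two univariate probit log-likelihoods
  for (y in list(c(1, 1), c(1, 0), c(0, 0))) {
    mu <- c(0.3, -0.7)
    expect_equal(
      dyad_loglik(y, mu, 0),
      sum(log(pnorm((2 * y - 1) * mu))),
      tolerance = 1e-10
    )
  }
  # symmetric quadrant at the origin
  expect_equal(dyad_loglik(c(1, 1), c(0, 0), 0), log(0.25), tolerance = 1e-12)
  # positive correlation inflates the mutual quadrant
  expect_gt(dyad_loglik(c(1, 1), c(0, 0), 0.9), log(0.25))
  expect_error(dyad_loglik(c(1, 1), c(0, 0), 1), class = "srmtie_domain_error")
})

test_that("latent updates respect truncation and the half-normal mean", {
  # closed form: standard normal truncated to [0, Inf) has mean sqrt(2/pi)
  set.seed(1)
  draws <- srmtie:::rtrunc_sign(rep(1, 20000), 0, 1)
  expect_true(all(draws >= 0))
  expect_equal(mean(draws), sqrt(2 / pi), tolerance = 0.02)
  draws0 <- srmtie:::rtrunc_sign(rep(0, 20000), 0, 1)
  expect_true(all(draws0 < 0))
  expect_equal(mean(draws0), -sqrt(2 / pi), tolerance = 0.02)
  # extreme conditional means stay finite and on the right side
  extreme <- srmtie:::rtrunc_sign(c(1, 0), c(-40, 40), 1)
  expect_true(is.finite(extreme[1]) && extreme[1] >= 0)
  expect_true(is.finite(extreme[2]) && extreme[2] < 0)
})

test_that("latent updates use the partner-conditional mean under dyadic correlation", {
  d <- as_dyad_data(toy_round_robin(c("a", "b"), ties = c("a>b", "b>a")))
  ms <- make_state(d)
  prep <- ms$prep
  st <- zero_effects(ms$st, prep)
  st$beta <- 0
  st$xb <- rep(0, 2)
  rho <- 0.9
  st$rho <- rho
  v <- 1.3 # fixed partner latent value
  set.seed(2)
  first <- prep$dir1
  other <- prep$dir2
  draws <- replicate(6000, {
    st$ystar[other] <- v
    srmtie:::update_latents(st, prep)$ystar[first]
  })
  # oracle: truncated normal mean with mean rho*v, sd sqrt(1-rho^2), lower 0
  m0 <- rho * v
  s <- sqrt(1 - rho^2)
  alpha <- -m0 / s
  oracle <- m0 + s * dnorm(alpha) / (1 - pnorm(alpha))
  expect_true(all(draws >= 0))
  expect_equal(mean(draws), oracle, tolerance = 0.02)
})

test_that("sign consistency of latents with outcomes holds after every sweep", {
  d <- small_sim(seed = 5, n_groups = 3, sizes = c(4, 5))
  ms <- make_state(d)
  st <- ms$st
  prior <- srm_prior()
  set.seed(9)
  for (i in 1:30) {
    st <- srmtie:::srm_sweep(st, ms$prep, prior)
    expect_true(all(st$ystar[d$outcome == 1] >= 0))
    expect_true(all(st$ystar[d$outcome == 0] < 0))
  }
})

test_that("the coefficient update matches a brute-force GLS oracle", {
  d <- small_sim(seed = 12, n_groups = 3, sizes = c(4, 5))
  set.seed(55)
  X <- cbind(
    intercept = 1, x1 = rnorm(nrow(d)), x2 = rnorm(nrow(d)), x3 = rnorm(nrow(d))
  )
  prep <- srmtie:::srm_prepare(d, X)
  st <- srmtie:::srm_init_state(prep, srm_prior(), mcmc_config(seed = 1), NULL, FALSE)
  st <- zero_effects(st, prep)
  rho <- 0.6
  st$rho <- rho
  set.seed(99)
  st$ystar <- rnorm(prep$n)

  # dense-matrix GLS oracle: full row covariance with 2x2 dyad blocks
  Sigma <- diag(prep$n)
  for (r in seq_len(prep$n)) Sigma[r, prep$rev[r]] <- rho
  prior <- srm_prior()
  P0 <- diag(1 / prior$beta_sd^2, prep$p)
  Si <- solve(Sigma)
  oracle_prec <- t(X) %*% Si %*% X + P0
  oracle_mean <- drop(solve(oracle_prec, t(X) %*% Si %*% st$ystar))
  oracle_cov <- solve(oracle_prec)

  set.seed(7)
  draws <- t(replicate(4000, srmtie:::update_beta(st, prep, prior)$beta))
  # posterior sds here are ~0.15, so 0.01 is ~4 Monte Carlo errors
  expect_lt(max(abs(colMeans(draws) - oracle_mean)), 0.012)
  expect_lt(max(abs(stats::cov(draws) - oracle_cov)), 0.005)

  # intercept-only sanity: conditional mean is essentially mean(y*)
  ms0 <- make_state(d, model = "empty")
  st0 <- zero_effects(ms0$st, ms0$prep)
  st0$rho <- 0
  st0$ystar <- st$ystar
  set.seed(8)
  b0 <- replicate(3000, srmtie:::update_beta(st0, ms0$prep, prior)$beta)
  expect_lt(abs(mean(b0) - mean(st$ystar)), 0.01)
})

test_that("group-effect updates shrink between the residual mean and zero", {
  d <- as_dyad_data(toy_round_robin(letters[1:5]))
  ms <- make_state(d)
  prep <- ms$prep
  st <- zero_effects(ms$st, prep)
  st$beta <- 0
  st$xb <- rep(0, prep$n)
  st$rho <- 0
  set.seed(21)
  st$ystar <- rnorm(prep$n, 0.8, 1)
  resid_mean <- mean(st$ystar)
  n_rows <- prep$n

  # huge prior variance: conditional mean ~ group mean residual
  st$s2m <- 1e6
  set.seed(3)
  m_draws <- replicate(4000, srmtie:::update_group_effects(st, prep, srm_prior())$m)
  expect_lt(abs(mean(m_draws) - resid_mean), 0.02)
  expect_lt(abs(sd(m_draws) - sqrt(1 / n_rows)), 0.01)

  # degenerate prior: effects collapse to zero
  st$s2m <- 1e-10
  m0 <- replicate(200, srmtie:::update_group_effects(st, prep, srm_prior())$m)
  expect_lt(max(abs(m0)), 1e-3)
})

test_that("actor-partner updates match hand-derived 2x2 precision algebra", {
  d <- as_dyad_data(toy_round_robin(c("a", "b"), ties = c("a>b", "b>a")))
  ms <- make_state(d)
  prep <- ms$prep
  st <- zero_effects(ms$st, prep)
  st$beta <- 0
  st$xb <- rep(0, 2)
  st$rho <- 0
  st$ystar <- c(1.2, -0.4) # canonical order: (a->b, b->a)
  Sab <- matrix(c(1.0, 0.3, 0.3, 0.5), 2, 2)
  st$Sab <- Sab

  # individual "a" has one out-row (y* = 1.2) and one in-row (y* = -0.4);
  # with rho = 0 its conditional precision is I + Sab^{-1} and the mean
  # solves (I + Sab^{-1}) mu = (S1, S2).
  Sinv <- solve(Sab)
  oracle_mean <- solve(diag(2) + Sinv, c(1.2, -0.4))
  oracle_cov <- solve(diag(2) + Sinv)

  set.seed(4)
  draws <- t(replicate(6000, {
    out <- srmtie:::update_actor_partner(st, prep, srm_prior())
    c(out$a[1], out$b[1])
  }))
  expect_lt(max(abs(colMeans(draws) - oracle_mean)), 0.03)
  expect_lt(max(abs(stats::cov(draws) - oracle_cov)), 0.03)
})

test_that("actor-partner effects collapse when their covariance vanishes", {
  d <- small_sim(seed = 6, n_groups = 2, sizes = c(4, 4))
  ms <- make_state(d)
  st <- ms$st
  st$Sab <- diag(c(1e-10, 1e-10))
  out <- srmtie:::update_actor_partner(st, ms$prep, srm_prior())
  expect_lt(max(abs(c(out$a, out$b))), 1e-3)
})

test_that("the Metropolis update concentrates on the residual correlation", {
  d <- small_sim(seed = 8, n_groups = 10, sizes = c(8, 10))
  ms <- make_state(d)
  prep <- ms$prep

  run_chain_at <- function(rho_true, iters = 1500) {
    st <- zero_effects(ms$st, prep)
    st$beta <- 0
    st$xb <- rep(0, prep$n)
    npair <- prep$n / 2
    set.seed(rho_true * 100 + 17)
    z1 <- rnorm(npair)
    z2 <- rho_true * z1 + sqrt(1 - rho_true^2) * rnorm(npair)
    e <- numeric(prep$n)
    e[prep$dir1] <- z1
    e[prep$rev[prep$dir1]] <- z2
    st$ystar <- e
    vals <- numeric(iters)
    for (i in seq_len(iters)) {
      st <- srmtie:::update_rho_ee(st, prep, adapt = i < 500)
      vals[i] <- st$rho
    }
    list(vals = vals[-(1:500)], emp = stats::cor(z1, z2))
  }

  chain9 <- run_chain_at(0.9)
  expect_true(all(abs(chain9$vals) < 1))
  # concentrates on the realised pair correlation, which is near the truth
  expect_lt(abs(mean(chain9$vals) - chain9$emp), 0.03)
  expect_lt(abs(mean(chain9$vals) - 0.9), 0.05)

  chain0 <- run_chain_at(0)
  expect_lt(abs(mean(chain0$vals) - chain0$emp), 0.03)
  expect_lt(abs(mean(chain0$vals)), 3.2 / sqrt(length(chain0$vals) / 2))
})

test_that("fits are deterministic, finite, and respect parameter supports", {
  d <- as_dyad_data(toy_round_robin(c("a", "b"), ties = "a>b"))
  cfg <- mcmc_config(chains = 1, burn_in = 50, iterations = 100, thin = 2, seed = 3)
  f1 <- srm_fit(d, config = cfg)
  f2 <- srm_fit(d, config = cfg)
  expect_identical(f1$draws, f2$draws) # same seed, bit-identical draws
  expect_true(all(is.finite(as.matrix(f1$draws))))

  d2 <- small_sim(seed = 10, n_groups = 3, sizes = c(4, 5))
  f3 <- srm_fit(d2, config = tiny_config(seed = 4, chains = 1))
  expect_true(all(f3$draws$sigma2_m > 0))
  expect_true(all(f3$draws$sigma2_a > 0))
  expect_true(all(f3$draws$sigma2_b > 0))
  expect_true(all(abs(f3$draws$rho_ab) < 1))
  expect_true(all(abs(f3$draws$rho_ee) < 1))
})
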