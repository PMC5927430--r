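#' Structure of a simulated multi-group round-robin study
#'
#' Defaults mirror the scale of the NBA teammate study: 30 groups of 11 +- 1
#' members (sizes drawn uniformly from `size_range`), so that recovery
#' tolerances calibrated against the published fits are meaningful. Smaller
#' presets suit fast tests.
#'
#' @param n_groups Number of groups (>= 1).
#' @param size_range Integer range (length 2) of members per group; all
#'   sizes must be >= 2.
#' @param stats Moment targets for the covariate generators (see
#'   [nba_summary_stats()]).
#' @return A `sim_structure` list.
#' @export
sim_structure <- function(n_groups = 30, size_range = c(10, 12),
                          stats = nba_summary_stats()) {
  stopifnot(n_groups >= 1, length(size_range) == 2, size_range[1] >= 2,
    size_range[2] >= size_range[1]
  )
  structure(
    list(n_groups = as.integer(n_groups), size_range = as.integer(size_range),
      stats = stats
    ),
    class = "sim_structure"
  )
}

stat_row <- function(stats, v) as.list(stats[stats$variable == v, ])

#' Simulate actor-, team-, and dyad-level covariates
#'
#' Draws covariates from simple parametric families whose marginal moments
#' target the published NBA summary table: team playoff performance is
#' generated on the square-root scale as a nonnegative normal (stored raw,
#' i.e. squared, so the standard `sqrt -> zscore` chain applies); All-Star
#' appearances are zero-inflated shifted-geometric counts capped at 17;
#' league tenure is a rounded lognormal season count; salary is lognormal in
#' millions; Twitter account age and height are (clamped) normals; years as
#' teammates is binomial on 0..13; same college is a symmetric per-dyad
#' Bernoulli. Only the marginals are targeted, not any joint structure.
#'
#' @param structure A [sim_structure()].
#' @param seed Integer seed.
#' @return A list of tibbles: `teams` (`group`, `performance`),
#'   `players` (`group`, `id`, `allstar`, `tenure`, `salary`, `twitter`,
#'   `height`), and a function-free `sizes` vector is implied by `players`.
#' @export
simulate_covariates <- function(structure = sim_structure(), seed = 1) {
  set.seed(seed)
  st <- structure$stats
  size_pool <- seq(structure$size_range[1], structure$size_range[2])
  sizes <- size_pool[sample.int(length(size_pool), structure$n_groups, replace = TRUE)]
  groups <- sprintf("g%02d", seq_len(structure$n_groups))
  perf <- stat_row(st, "performance")
  teams <- tibble::tibble(
    group = groups,
    # generated on the sqrt scale, stored raw so the transform chain applies
    performance = pmax(0, rnorm(structure$n_groups, perf$mean, perf$sd))^2
  )
  all_st <- stat_row(st, "allstar")
  ten <- stat_row(st, "tenure")
  sal <- stat_row(st, "salary")
  twi <- stat_row(st, "twitter")
  hei <- stat_row(st, "height")
  n_players <- sum(sizes)
  players <- tibble::tibble(
    group = rep(groups, sizes),
    id = sprintf("%s_p%02d", rep(groups, sizes), unlist(lapply(sizes, seq_len))),
    allstar = pmin(
      all_st$max,
      ifelse(runif(n_players) < 0.85, 0, 1 + stats::rgeom(n_players, 0.231))
    ),
    tenure = pmin(19, pmax(1, round(exp(rnorm(n_players, ten$mean, ten$sd))))),
    salary = exp(rnorm(n_players, sal$mean, sal$sd)),
    twitter = pmin(twi$max, pmax(twi$min, rnorm(n_players, twi$mean, twi$sd))),
    height = rnorm(n_players, hei$mean, hei$sd)
  )
  list(teams = teams, players = players)
}

#' Simulate a directed binary network from the SRM generative model
#'
#' Draws group effects, bivariate actor-partner effects, and per-dyad
#' correlated residual pairs from the model's distributions, forms the
#' latent propensities, and thresholds at zero. The result is a complete
#' round-robin [as_dyad_data()] dataset (it always passes validation) and is
#' deterministic given the seed.
#'
#' @param params An [srm_params()] truth; `params$beta` must match the
#'   design of `model` (a single intercept for `"empty"`).
#' @param structure A [sim_structure()].
#' @param seed Integer seed.
#' @param model Design whose linear predictor feeds the latent mean; with
#'   `"empty"` no covariates are attached unless `covariates = TRUE`.
#' @param covariates Attach simulated (transformed) covariate columns?
#'   Defaults to `TRUE` whenever `model != "empty"`.
#' @return A `dyad_data` tibble with attribute `truth = params`.
#' @export
simulate_srm_network <- function(params, structure = sim_structure(), seed = 1,
                                 model = "empty",
                                 covariates = !identical(model, "empty")) {
  stopifnot(inherits(params, "srm_params"))
  ev <- eigen(params$Sigma_ab, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12) {
    abort("actor-partner covariance is not positive semidefinite",
      class = "srmtie_domain_error"
    )
  }

  covs <- simulate_covariates(structure, seed = seed)
  players <- covs$players
  teams <- covs$teams
  groups <- teams$group
  n_players <- nrow(players)

  set.seed(seed + 1L)
  m <- rnorm(length(groups), 0, sqrt(params$sigma2_m))
  L <- chol_psd(params$Sigma_ab)
  ab <- matrix(rnorm(2 * n_players), n_players, 2) %*% L
  players$a_eff <- ab[, 1]
  players$b_eff <- ab[, 2]

  dyads <- players |>
    dplyr::group_by(.data$group) |>
    dplyr::reframe(as_pair_frame(.data$id)) |>
    dplyr::ungroup()
  n_pairs <- nrow(dyads)
  # dyad-level covariates, symmetric within the unordered pair
  yt <- stat_row(structure$stats, "years_teammates")
  dyads$years_teammates_raw <- rbinom(n_pairs, as.integer(yt$max), 0.12)
  sc <- stat_row(structure$stats, "same_college")
  dyads$same_college <- rbinom(n_pairs, 1, sc$mean)

  e1 <- rnorm(n_pairs)
  e2 <- params$rho_ee * e1 + sqrt(1 - params$rho_ee^2) * rnorm(n_pairs)

  long <- dplyr::bind_rows(
    dplyr::mutate(dyads, actor = .data$id1, partner = .data$id2, e = e1),
    dplyr::mutate(dyads, actor = .data$id2, partner = .data$id1, e = e2)
  )

  long <- long |>
    dplyr::left_join(
      dplyr::select(players, "id", "group",
        allstar_i = "allstar", tenure_i = "tenure", salary_i = "salary",
        twitter_i = "twitter", height_i = "height", a_eff = "a_eff"
      ),
      by = c(actor = "id", group = "group")
    ) |>
    dplyr::left_join(
      dplyr::select(players, "id", "group",
        allstar_j = "allstar", tenure_j = "tenure", salary_j = "salary",
        twitter_j = "twitter", height_j = "height", b_eff = "b_eff"
      ),
      by = c(partner = "id", group = "group")
    ) |>
    dplyr::left_join(teams, by = "group") |>
    dplyr::rename(years_teammates = "years_teammates_raw")

  if (covariates || model != "empty") {
    long <- standardize_covariates(long, stats = structure$stats)
    X <- build_design(long, model)
  } else {
    X <- matrix(1, nrow(long), 1, dimnames = list(NULL, "intercept"))
  }
  beta <- align_coefs(params$beta, colnames(X))
  mu <- drop(X %*% beta) + m[match(long$group, groups)] + long$a_eff + long$b_eff
  long$outcome <- as.integer(mu + long$e >= 0)

  keep <- c(
    "group", "actor", "partner", "outcome",
    if (covariates || model != "empty") {
      setdiff(
        names(long),
        c("group", "actor", "partner", "outcome", "id1", "id2", "e",
          "a_eff", "b_eff")
      )
    }
  )
  out <- as_dyad_data(long[, keep, drop = FALSE])
  attr(out, "truth") <- params
  out
}

as_pair_frame <- function(ids) {
  pr <- utils::combn(sort(ids), 2)
  tibble::tibble(id1 = pr[1, ], id2 = pr[2, ])
}

chol_psd <- function(S) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(out)) {
    ei <- eigen(S, symmetric = TRUE)
    out <- diag(sqrt(pmax(ei$values, 0))) %*% t(ei$vectors)
  }
  out
}

#' Simulate-fit-summarise recovery experiment
#'
#' For each seed: generate a network at the true parameters, fit the model,
#' and report the posterior mean, credible interval, truth, coverage flag,
#' and absolute error for every variance component, correlation, and
#' coefficient.
#'
#' @param true_params An [srm_params()] truth.
#' @param structure A [sim_structure()].
#' @param config An [mcmc_config()] for the fits.
#' @param seeds Integer vector; one replicate per seed.
#' @param model Design for both simulation and fitting.
#' @param prior An [srm_prior()].
#' @param conf_level Credible-interval mass for the coverage flag.
#' @return A tibble with one row per (seed, parameter).
#' @export
recovery_experiment <- function(true_params, structure = sim_structure(),
                                config = mcmc_config(), seeds = 1:3,
                                model = "empty", prior = srm_prior(),
                                conf_level = 0.90) {
  truth <- c(
    setNames(true_params$beta, if (model == "empty") "intercept" else names(true_params$beta)),
    sigma2_m = true_params$sigma2_m,
    sigma2_a = true_params$sigma2_a,
    sigma2_b = true_params$sigma2_b,
    rho_ab = true_params$rho_ab,
    rho_ee = true_params$rho_ee
  )
  purrr::map_dfr(seeds, function(s) {
    dat <- simulate_srm_network(true_params, structure, seed = s, model = model)
    cfg <- config
    cfg$seed <- as.integer(config$seed + s)
    fit <- srm_fit(dat, model = model, prior = prior, config = cfg)
    tidy(fit, conf_level = conf_level) |>
      dplyr::filter(.data$term %in% names(truth)) |>
      dplyr::mutate(
        seed = s,
        truth = unname(truth[.data$term]),
        covered = .data$truth >= .data$conf.low & .data$truth <= .data$conf.high,
        abs_error = abs(.data$estimate - .data$truth)
      ) |>
      dplyr::select("seed", "term", "truth", "estimate", "std.error",
        "conf.low", "conf.high", "covered", "abs_error"
      )
  })
}
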