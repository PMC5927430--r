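# Shared fixtures: all built in code at test time.

# Minimal complete round robin: one group, the named actors, tie matrix
# given as a named list of directed ties (defaults to none).
toy_round_robin <- function(actors = c("a", "b", "c"), ties = character(),
                            group = "g1") {
  pairs <- expand.grid(actor = actors, partner = actors,
    stringsAsFactors = FALSE
  )
  pairs <- pairs[pairs$actor != pairs$partner, ]
  key <- paste(pairs$actor, pairs$partner, sep = ">")
  tibble::tibble(
    group = group,
    actor = pairs$actor,
    partner = pairs$partner,
    outcome = as.integer(key %in% ties)
  )
}

# Quick MCMC settings for smoke-level fits.
tiny_config <- function(seed = 1, chains = 2) {
  mcmc_config(
    chains = chains, burn_in = 200, iterations = 400, thin = 2, seed = seed
  )
}

# Small simulated dataset reused across tests.
small_sim <- function(seed = 7, n_groups = 6, sizes = c(6, 8),
                      params = srm_params()) {
  simulate_srm_network(params, sim_structure(n_groups, sizes), seed = seed)
}

# Settings table used in design/prediction tests.
model2_settings <- function() {
  tibble::tibble(
    allstar_i = c(4 / 17, 4 / 17, 0, 0),
    performance = c(1, -1, 1, -1)
  )
}
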