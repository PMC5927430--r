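# MCMC summary diagnostics: split-chain potential scale reduction and
# autocorrelation-based effective sample size (Geyer initial monotone
# sequence truncation). Deterministic given the draws.

split_chains <- function(x) {
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE], x[(n - h + 1):n, , drop = FALSE])
}

#' Split-chain potential scale reduction factor
#'
#' @param x Numeric matrix of draws, iterations by chains (a single vector is
#'   treated as one chain).
#' @return The split-Rhat statistic; `NA` when only one chain of fewer than
#'   4 draws is supplied.
#' @export
mcmc_rhat <- function(x) {
  x <- as.matrix(x)
  x <- split_chains(x)
  n <- nrow(x)
  m <- ncol(x)
  if (n < 2 || m < 2) {
    return(NA_real_)
  }
  means <- colMeans(x)
  vars <- apply(x, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) {
    return(if (B == 0) 1 else Inf)
  }
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Effective sample size of MCMC draws
#'
#' Combines chains via the rank-one between/within decomposition and
#' truncates the autocorrelation sum by Geyer's initial monotone positive
#' sequence.
#'
#' @inheritParams mcmc_rhat
#' @return Estimated effective sample size (capped at the number of draws).
#' @export
mcmc_ess <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  total <- n * m
  if (n < 4) {
    return(NA_real_)
  }
  acov <- sapply(seq_len(m), function(j) {
    acf(x[, j], lag.max = n - 1, type = "covariance", plot = FALSE,
      demean = TRUE
    )$acf[, 1, 1]
  })
  acov <- matrix(acov, nrow = n)
  chain_var <- acov[1, ] * n / (n - 1)
  W <- mean(chain_var)
  if (W == 0) {
    return(total)
  }
  mean_acov <- rowMeans(acov)
  var_plus <- W * (n - 1) / n
  if (m > 1) var_plus <- var_plus + var(colMeans(x))
  rho <- 1 - (W - mean_acov) / var_plus

  # Geyer initial monotone positive sequence on paired sums
  max_pairs <- floor((n - 1) / 2)
  sum_rho <- 0
  prev_pair <- Inf
  for (k in seq_len(max_pairs)) {
    pair <- rho[2 * k] + rho[2 * k + 1]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev_pair)
    prev_pair <- pair
    sum_rho <- sum_rho + pair
  }
  ess <- total / (1 + 2 * sum_rho)
  min(ess, total)
}
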