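---
title: "The multilevel probit Social Relations Model in srmtie"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multilevel probit Social Relations Model in srmtie}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srmtie)
```

## The model

srmtie analyses *directed binary ties* observed among all members of multiple
bounded groups — a multi-group round-robin design. The motivating application
is whether NBA player $i$ follows teammate $j$ on Twitter, but the same
structure arises whenever every member of a group can direct a yes/no relation
at every other member: grooming or aggression in animal groups, advice-seeking
in work teams, food sharing between households.

Each ordered pair $(i \to j)$ within group $k$ carries a latent continuous
propensity

$$y^{*}_{ik,jk} = \mathbf{x}'_{ik,jk}\beta + m_k + a_{ik} + b_{jk} + e_{ik,jk},$$

and the observed tie is $y = 1$ exactly when $y^{*} \ge 0$ (a probit link).
The random effects decompose the non-systematic variation by social role:

* $m_k \sim \mathrm{N}(0, \sigma^2_m)$ — some groups are denser than others;
* $(a_{ik}, b_{ik}) \sim \mathrm{MVN}(\mathbf{0}, \Sigma_{ab})$ — an
  individual's propensity to *direct* ties (actor effect $a$) and to
  *attract* them (partner effect $b$), with correlation
  $\rho_{ab} = \sigma_{ab}/\sqrt{\sigma^2_a\sigma^2_b}$, the **generalized
  reciprocity** correlation: do prolific senders also receive a lot?
* $(e_{ik,jk}, e_{jk,ik})$ — the two directed residuals of each unordered
  dyad, standard bivariate normal with correlation $\rho_{ee}$, the **dyadic
  reciprocity** correlation: are ties returned beyond what the individual
  effects explain? The unit variances are the identification constraint of
  the probit scale, not an assumption about the data.

Because the dyadic variance is fixed at 1, the share of latent variance at
each level is well defined. These **variance partition coefficients** are

$$p_m = \frac{\sigma^2_m}{T},\quad p_a = \frac{\sigma^2_a}{T},\quad
  p_b = \frac{\sigma^2_b}{T},\quad p_e = \frac{1}{T},\qquad
  T = \sigma^2_m + \sigma^2_a + \sigma^2_b + 1,$$

computed per posterior draw by `vpc()` (so their posterior spread is
reported, not just a plug-in value). They always sum to one.

## Estimation: data-augmented Gibbs sampling

`srm_fit()` samples the joint posterior by Markov chain Monte Carlo with
latent-variable augmentation. One sweep updates:

1. **Latent propensities.** Given its reverse row, each $y^*_{ij}$ is
   univariate normal with mean $\mu_{ij} + \rho_{ee}(y^*_{ji} - \mu_{ji})$
   and variance $1-\rho_{ee}^2$, truncated to $[0,\infty)$ or $(-\infty,0)$
   by the observed tie. Rows are updated in two blocks by direction; within
   a block rows are conditionally independent given the other block, so the
   blocked update is exact Gibbs. Truncated draws use inverse-CDF sampling
   in the relevant tail, which is stable far beyond the $|\mu|$ this model
   produces.
2. **Coefficients.** A conjugate generalized-least-squares step. The paired
   residual covariance enters in closed form:
   $X'\Sigma^{-1}X = (X'X - \rho_{ee} X'X_{rev})/(1-\rho_{ee}^2)$, where
   $X_{rev}$ is the design with each row replaced by its reverse row.
3. **Group effects and $\sigma^2_m$.** Each $m_k$ shrinks the group's mean
   residual toward zero with precision $n_k(n_k-1)/(1+\rho_{ee}) +
   1/\sigma^2_m$; the variance follows from its conjugate conditional.
4. **Actor–partner effects and $\Sigma_{ab}$.** For individual $i$, every
   teammate $j$ contributes the bivariate observation
   $(w_{i\to j} - b_j,\; w_{j\to i} - a_j)$ with mean $(a_i, b_i)$ and the
   dyadic residual covariance, so the pair $(a_i, b_i)$ has a bivariate
   normal full conditional that is sampled exactly, individual by
   individual (sequential-scan Gibbs). $\Sigma_{ab}$ then follows from an
   inverse-Wishart conditional.
5. **Dyadic reciprocity $\rho_{ee}$.** Random-walk Metropolis on the
   Fisher-$z$ scale with a uniform$(-1,1)$ prior on $\rho_{ee}$; the
   proposal step adapts toward a 44% acceptance rate during burn-in only,
   so detailed balance holds for all stored draws.

Initial values are deliberately simple: $\beta$ from a probit GLM that
ignores the random effects, effects at zero, correlations at zero, and
latents at their truncated-normal means; dispersion between chains comes
from the chain seeds.

### Priors

All priors are proper but diffuse. Coefficients are independent
$\mathrm{N}(0, 10^2)$ — essentially flat on the probit scale, where effects
beyond $|3|$ saturate the link. The three standard deviations
($\sigma_m, \sigma_a, \sigma_b$) get half-$t(\nu{=}2, A{=}5)$ priors and the
actor–partner correlation a marginal uniform$(-1,1)$, implemented jointly via
the Huang–Wand auxiliary inverse-gamma construction: an inverse-Wishart on
$\Sigma_{ab}$ whose scale matrix is mixed over auxiliary inverse-gamma
variables. This single family delivers weakly-informative half-$t$ scales
*and* an inverse-Wishart-type covariance prior while keeping every
conditional conjugate. With $\nu = 2$ the implied prior on $\rho_{ab}$ is
exactly uniform, so the high reciprocity correlations typical of social data
are not built in by the prior. All hyperparameters are adjustable through
`srm_prior()`.

Because the hyperparameters of the original analysis's software are not
published, replication of its posterior summaries is expected within
posterior uncertainty, not digit for digit.

### Configuration and problem sizes

The default `mcmc_config()` is a desk-scale setting: 4 chains, 2,000
burn-in sweeps, 10,000 sampling sweeps thinned by 10 (4,000 stored draws).
On a dataset of the study's size (30 groups of 11 ± 1 actors, ~3,300
directed observations) this runs in a few minutes on one core and yields
effective sample sizes of several hundred for every parameter except
$\rho_{ee}$, whose Metropolis chain mixes more slowly (ESS ≈ 50–100; its
posterior is nevertheless located to within ±0.03). The large-scale
configuration of the original analysis (100,000 burn-in, 1,000,000 sweeps,
thin 200, 5,000 stored draws per chain) is available by setting the fields
explicitly; it changes Monte Carlo error, not the model.

## Covariate construction

`standardize_covariates()` reproduces the covariate pipeline of the NBA
analysis, and `nba_summary_stats()` carries the published marginal moments
so transformations can be pinned for exact replication rather than
re-estimated from whatever subset is at hand:

* **Team playoff performance**: yearly playoff wins are aggregated by
  `decay_weighted_score()` with inverse-recency weights
  $w_t = 1/(\text{reference} - t + 1)$ — the only simple weighting family
  consistent with the published anchor that 2007 carries ≈11% (1/9) of
  2015's weight — then square-root transformed (the raw score is right
  skewed) and $z$-scored. The weighted *mean* (not sum) is the default;
  the distinction is absorbed by the $z$-scoring.
* **All-Star appearances** and **years as teammates** are proportionally
  scaled by their observed maxima (17 and 13), mapping them to $[0, 1]$.
* **League tenure** and **salary** are log transformed then $z$-scored;
  tenure is a season count $\ge 1$ so $\log$ is defined and its minimum is
  0; log salary in millions may be negative.
* **Twitter account age** and **height** are $z$-scored.
* **Homophily terms** are multiplicative: the design contains the actor's
  value, the partner's value, and their product, built exactly as
  elementwise products by `build_design()`.

The four standard designs mirror the published model sequence: `empty`
(1 column), `status_by_performance` (4), `three_way` (8), `full` (22).

## Predictions

`predicted_probability()` is the plug-in estimator $\Phi(\mathbf{x}'\beta)$
with random effects at zero — a *conditional* (cluster-average) probability.
`prediction_grid()` evaluates $\Phi(\mathbf{x}'\beta)$ under every stored
posterior draw and reports the posterior mean with an equal-tailed 90%
credible band. For smooth monotone settings the two estimators agree to
within about a percentage point; both are provided because published
figures are often draw-averaged while in-text percentages are typically
plug-in. A marginal variant (re-drawing random effects) is deliberately not
the default: the reported quantities in this literature are conditional.

One caveat surfaced by the replication tests: plug-in probabilities are
sensitive to rounding of the coefficients. At the published
status-by-performance posterior means rounded to two decimals, the
All-Star/+1SD cell computes to 56.6%, which rounds to 57 rather than the
published 56; the discrepancy is entirely input rounding (four coefficients
each rounded by up to 0.005 move the linear predictor by up to ~0.013).

## The synthetic generator

`simulate_srm_network()` draws group effects, bivariate actor–partner
effects, and correlated dyadic residual pairs from the model's own
distributions, thresholds at zero, and returns a complete round-robin
dataset that always passes `validate_dyads()`. Default scale mirrors the
study: 30 groups of 11 ± 1 members, so recovery tolerances calibrated
against the published fits are meaningful.

`simulate_covariates()` targets the published *marginal* moments with
simple parametric families (zero-inflated geometric All-Star counts capped
at 17, lognormal salary, rounded-lognormal tenure, clamped normals for
account age and height, binomial years-as-teammates on 0–13, Bernoulli
same-college). Deliberately not emulated: the joint dependence among
covariates (e.g. All-Stars clustering on successful teams), degree
heterogeneity beyond what the SRM itself induces, and any platform-specific
behaviour. Consequently, passing recovery tests demonstrates that the
sampler inverts the model's own generative process at the study's scale and
information content — not that the model is well specified for any
particular empirical network.

## Numerical choices

* Truncated-normal draws by inverse CDF in the relevant tail; non-finite
  results (possible only past $|z| \approx 37$) are clamped to a small
  offset on the correct side.
* The bivariate-normal orthant probability behind `dyad_loglik()` reduces
  to a one-dimensional integral of $\phi(x)\Phi\{(b - \rho x)/\sqrt{1-\rho^2}\}$,
  evaluated with `stats::integrate()` at tight tolerance; tests verify
  agreement with an independent two-dimensional Gauss–Legendre quadrature
  to $10^{-6}$.
* Inverse-Wishart draws via `stats::rWishart()` on the inverse scale, with
  symmetrisation against accumulated round-off.
* The canonical row ordering (group, unordered pair, direction with the
  lexicographically smaller actor first) fixes the pairing used by all
  bivariate updates and makes fits bit-reproducible for a given seed.
* Ties are broken nowhere: inputs with duplicate ordered pairs, missing
  reverse rows, self-ties, non-binary outcomes, individuals in two groups,
  or missing covariates are rejected with a full violation report
  (`validate_dyads()`), never repaired.

## Validation strategy

Three independent lines of evidence back the sampler, all run in the test
suite:

1. **Conditional-level oracles**: the coefficient step against a dense
   generalized-least-squares solve; the actor–partner step against
   hand-derived 2×2 precision algebra; the latent step against closed-form
   truncated-normal moments; the Metropolis step against the empirical
   correlation of simulated residual pairs.
2. **A joint-distribution (successive-conditional) check**: alternating a
   full Gibbs sweep with regeneration of the data from the current
   parameters must leave the prior invariant; the chain's marginals are
   compared against the analytic half-$t$, uniform-correlation, and normal
   prior marginals. The bounds are sized to the chain's Monte Carlo error
   but would catch a $\sqrt{2}$ scale error in any variance conditional.
3. **Reductions and recovery**: with partner effects removed and
   $\rho_{ee} = 0$ the model is a probit GLMM and the posterior agrees with
   an independent `lme4::glmer()` fit; simulating at the published
   empty-model estimates (variances 0.15/1.17/0.71, $\rho_{ab} = 0.75$,
   $\rho_{ee} = 0.90$) at the study scale and refitting recovers variances
   within ±0.2 and correlations within ±0.1 (and, for the reciprocity
   correlations and VPCs, within ±0.05 in the configuration used by the
   acceptance suite).

## Known limitations

* Only the probit link is implemented; no logit, no multiple-membership or
  bipartite designs, no longitudinal extension.
* Individuals must belong to exactly one group; the data model enforces
  this rather than supporting multi-group membership.
* $\rho_{ee}$ mixes slowest of all parameters; for publication-grade
  summaries of $\rho_{ee}$ on large datasets, lengthen the chains beyond
  the desk-scale default.
* The original study's raw dataset is not redistributed with the package;
  replication against it requires supplying the CSV supplement, and the
  corresponding descriptive checks report its absence otherwise.
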