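#' Inverse-recency decay weights
#'
#' Weight for observations from `year` when aggregated relative to
#' `reference_year`: `w = 1 / (reference_year - year + 1)`, so the reference
#' year gets weight 1, the previous year 1/2, and so on. With reference 2015,
#' 2007 carries 1/9 (about 11%) of the weight of 2015.
#'
#' @param year Integer vector of years, all `<= reference_year`.
#' @param reference_year The anchor year.
#' @return Numeric weights in `(0, 1]`, strictly decreasing with age.
#' @export
decay_weight <- function(year, reference_year) {
  if (any(year > reference_year)) {
    abort("decay_weight: year beyond the reference year", class = "srmtie_domain_error")
  }
  1 / (reference_year - year + 1)
}

#' Recency-weighted score over yearly values
#'
#' Aggregates nonnegative yearly values (e.g. playoff wins per season) into a
#' single score with inverse-recency weights from [decay_weight()]. The
#' default is a weighted mean (`normalize = TRUE`); `normalize = FALSE` gives
#' the weighted sum. Downstream standardization absorbs the overall scale, so
#' the choice only matters for interpretation of the raw score.
#'
#' @param values_by_year Named numeric vector: names are years, values are
#'   nonnegative yearly quantities.
#' @param reference_year Anchor year for the weights.
#' @param normalize Divide by the total weight (weighted mean)?
#' @return A single numeric score.
#' @examples
#' decay_weighted_score(c(`2015` = 9, `2014` = 0), 2015) # 9 * 1 / (1 + 0.5) = 6
#' @export
decay_weighted_score <- function(values_by_year, reference_year, normalize = TRUE) {
  years <- as.numeric(names(values_by_year))
  if (anyNA(years)) {
    abort("values_by_year must be named by year", class = "srmtie_config_error")
  }
  if (any(values_by_year < 0)) {
    abort("yearly values must be nonnegative", class = "srmtie_domain_error")
  }
  w <- decay_weight(years, reference_year)
  s <- sum(w * values_by_year)
  if (normalize) s / sum(w) else s
}

#' Declare a covariate and its transform chain
#'
#' A covariate spec names a variable, assigns its role (`actor`, `partner`,
#' or `dyad`), and lists the transforms applied left to right before the
#' variable enters the design matrix. Supported transforms:
#' \describe{
#'   \item{`"log"`}{natural log; input must be positive.}
#'   \item{`"sqrt"`}{square root; input must be nonnegative.}
#'   \item{`"zscore"`}{`(x - mean) / sd` using *supplied* stats, never
#'     recomputed silently.}
#'   \item{`"proportional"`}{`x / max` using the supplied maximum.}
#' }
#'
#' @param name Covariate name (a column of the dataset, without the `_i`/`_j`
#'   suffix for individual-level variables).
#' @param role One of `"actor"`, `"partner"`, `"dyad"`. Individual-level
#'   covariates are usually declared once per role they play.
#' @param transforms Character vector of transform names, applied in order.
#' @return A `covariate_spec` list.
#' @export
covariate_spec <- function(name, role = c("actor", "partner", "dyad"),
                           transforms = character()) {
  role <- match.arg(role)
  ok <- transforms %in% c("log", "sqrt", "zscore", "proportional")
  if (!all(ok)) {
    abort(paste0("unknown transform(s): ", paste(transforms[!ok], collapse = ", ")),
      class = "srmtie_config_error"
    )
  }
  structure(list(name = name, role = role, transforms = transforms),
    class = "covariate_spec"
  )
}

#' Standardization statistics for a set of covariates
#'
#' One row per covariate with the mean, standard deviation, and maximum used
#' by `zscore` / `proportional` transforms. Compute them from your own data
#' with `standardization_stats()`, or pin them to the published NBA marginal
#' moments with [nba_summary_stats()] for exact replication.
#'
#' @param data A data frame.
#' @param vars Character vector of column names to summarise.
#' @return A tibble with columns `variable`, `mean`, `sd`, `max`.
#' @export
standardization_stats <- function(data, vars) {
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("no such columns: ", paste(missing_cols, collapse = ", ")),
      class = "srmtie_config_error"
    )
  }
  purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    tibble::tibble(variable = v, mean = mean(x), sd = sd(x), max = max(x))
  })
}

#' Apply a transform chain to a numeric vector
#'
#' @param values Numeric vector.
#' @param spec A [covariate_spec()].
#' @param stats A one-row data frame (or single-variable subset of a stats
#'   table) with `mean`, `sd`, `max` as required by the chain; may be `NULL`
#'   when the chain uses neither `zscore` nor `proportional`.
#' @return The transformed numeric vector.
#' @export
apply_transform_chain <- function(values, spec, stats = NULL) {
  for (tr in spec$transforms) {
    values <- switch(tr,
      log = {
        if (any(values <= 0)) {
          abort("log transform requires positive values", class = "srmtie_domain_error")
        }
        log(values)
      },
      sqrt = {
        if (any(values < 0)) {
          abort("sqrt transform requires nonnegative values", class = "srmtie_domain_error")
        }
        sqrt(values)
      },
      zscore = {
        st <- require_stats(stats, spec$name, c("mean", "sd"))
        if (!is.finite(st$sd) || st$sd <= 0) {
          abort(paste0("degenerate sd for ", spec$name), class = "srmtie_domain_error")
        }
        (values - st$mean) / st$sd
      },
      proportional = {
        st <- require_stats(stats, spec$name, "max")
        if (!is.finite(st$max) || st$max <= 0) {
          abort(paste0("nonpositive max for ", spec$name), class = "srmtie_domain_error")
        }
        values / st$max
      }
    )
  }
  values
}

require_stats <- function(stats, name, fields) {
  if (is.null(stats)) {
    abort(paste0("standardization stats required for ", name), class = "srmtie_config_error")
  }
  st <- stats
  if ("variable" %in% names(st)) {
    st <- st[st$variable == name, , drop = FALSE]
    if (nrow(st) == 0) {
      abort(paste0("no standardization stats for ", name), class = "srmtie_config_error")
    }
  }
  missing_fields <- setdiff(fields, names(st))
  if (length(missing_fields) > 0) {
    abort(paste0("stats for ", name, " lack: ", paste(missing_fields, collapse = ", ")),
      class = "srmtie_config_error"
    )
  }
  as.list(st[1, ])
}

#' Same-affiliation homophily indicator
#'
#' 1 iff both labels are present (non-`NA`, non-empty) and equal; a missing
#' affiliation on either side can never match.
#'
#' @param actor_college,partner_college Character labels or `NA`.
#' @return Integer vector of 0/1.
#' @export
same_college_indicator <- function(actor_college, partner_college) {
  present <- !is.na(actor_college) & !is.na(partner_college) &
    actor_college != "" & partner_college != ""
  as.integer(present & (actor_college == partner_college))
}

# Model formulas over transformed covariate columns. Individual-level
# variables enter twice (actor value `*_i`, partner value `*_j`); homophily
# terms are the elementwise products model.matrix builds from `*`.
model_formulas <- list(
  empty = ~1,
  status_by_performance = ~ allstar_i * performance,
  three_way = ~ allstar_i * allstar_j * performance,
  full = ~ allstar_i * allstar_j * performance +
    tenure_i * tenure_j + salary_i * salary_j +
    twitter_i * twitter_j + height_i * height_j +
    years_teammates + same_college
)

#' Model names for the fitted sequence
#'
#' The four-model sequence: `empty` (intercept and random effects only),
#' `status_by_performance` (actor status x group performance interaction),
#' `three_way` (adds partner status and all two- and three-way products), and
#' `full` (adds actor/partner/homophily terms for tenure, salary, account
#' age, and height, plus shared-history and shared-college dyadic terms).
#'
#' @return Character vector of model names.
#' @export
srm_models <- function() names(model_formulas)

#' Build the design matrix for one of the standard models
#'
#' Constructs the fixed-effect design over the rows of a dyadic dataset.
#' Covariate columns are expected already transformed (see
#' [standardize_covariates()]); actor-side variables are read from `*_i`
#' columns, partner-side from `*_j`, dyad-level from their plain names.
#' The first column is always the intercept; interaction columns are exact
#' elementwise products of their parents.
#'
#' @param data A `dyad_data` tibble (or any data frame with the needed
#'   columns); may also be a plain tibble of covariate settings when building
#'   prediction rows.
#' @param model One of [srm_models()].
#' @return A numeric matrix with one row per observation and traced column
#'   names.
#' @export
build_design <- function(data, model = srm_models()) {
  model <- match.arg(model)
  f <- model_formulas[[model]]
  needed <- all.vars(f)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "model '", model, "' needs covariate column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "srmtie_config_error")
  }
  X <- model.matrix(f, data = as.data.frame(data))
  colnames(X)[1] <- "intercept"
  rownames(X) <- NULL
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  X
}

#' Default covariate specs for the NBA-style variable set
#'
#' The transform chains used in the teammate-following analysis: playoff
#' performance is square-root transformed then z-scored (after the
#' inverse-recency weighting of [decay_weighted_score()]); All-Star
#' appearances and years as teammates are proportionally scaled by their
#' maxima; league tenure and salary are log transformed then z-scored;
#' Twitter account age and height are z-scored.
#'
#' @return Named list of [covariate_spec()] objects keyed by variable name.
#' @export
default_covariate_specs <- function() {
  list(
    performance = covariate_spec("performance", "dyad", c("sqrt", "zscore")),
    allstar = covariate_spec("allstar", "actor", "proportional"),
    tenure = covariate_spec("tenure", "actor", c("log", "zscore")),
    salary = covariate_spec("salary", "actor", c("log", "zscore")),
    twitter = covariate_spec("twitter", "actor", "zscore"),
    height = covariate_spec("height", "actor", "zscore"),
    years_teammates = covariate_spec("years_teammates", "dyad", "proportional"),
    same_college = covariate_spec("same_college", "dyad")
  )
}

#' Standardize raw covariate columns in place
#'
#' Applies each spec's transform chain to the matching columns of a dyadic
#' dataset. Individual-level variables are transformed in both their `_i`
#' and `_j` columns with the *same* statistics. Statistics default to the
#' supplied table; use [nba_summary_stats()] to pin them to the published
#' marginal moments, or [standardization_stats()] to estimate them from your
#' own individual-level table.
#'
#' @param data A `dyad_data` tibble with raw covariate columns.
#' @param specs Named list of [covariate_spec()]s (default
#'   [default_covariate_specs()]).
#' @param stats A stats table with columns `variable`, `mean`, `sd`, `max`.
#'   Note the stats must describe the variable on the scale at which its
#'   `zscore`/`proportional` step runs (e.g. post-sqrt for performance,
#'   post-log for tenure and salary, as in the published table).
#' @return `data` with transformed covariate columns.
#' @export
standardize_covariates <- function(data, specs = default_covariate_specs(),
                                   stats = nba_summary_stats()) {
  for (spec in specs) {
    cols <- intersect(
      c(spec$name, paste0(spec$name, "_i"), paste0(spec$name, "_j")),
      names(data)
    )
    for (col in cols) {
      data[[col]] <- apply_transform_chain(data[[col]], spec, stats)
    }
  }
  data
}

#' Published marginal moments of the NBA teammate-following covariates
#'
#' Means, standard deviations, and ranges of the predictor variables in the
#' NBA Twitter teammate-following data (330 players on 30 teams; 3,356
#' directed ties over 1,678 dyads), on the scale at which each variable is
#' standardized: playoff performance after the square-root transform, tenure
#' and salary after the log transform. Used to pin `zscore`/`proportional`
#' standardization for exact replication, and as targets for the covariate
#' simulator.
#'
#' @return A tibble with columns `variable`, `level`, `mean`, `sd`, `min`,
#'   `max`.
#' @export
nba_summary_stats <- function() {
  tibble::tribble(
    ~variable, ~level, ~mean, ~sd, ~min, ~max,
    "performance", "team", 1.453, 0.759, 0, 2.864,
    "allstar", "individual", 0.649, 2.071, 0, 17,
    "tenure", "individual", 1.457, 0.829, 0, 2.944,
    "salary", "individual", 0.978, 1.217, -3.524, 3.157,
    "twitter", "individual", 4.528, 1.392, 0.066, 6.727,
    "height", "individual", 79.16, 3.4, 71, 86,
    "years_teammates", "dyad", 1.563, 1.097, 0, 13,
    "same_college", "dyad", 0.016, NA, 0, 1
  )
}

#' Reference posterior-mean estimates for the NBA teammate-following fits
#'
#' Posterior means reported for the four-model sequence on the NBA Twitter
#' data, usable as plug-in coefficients for predicted probabilities and as
#' generating values for synthetic stand-in networks. `model1` carries the
#' empty model's variance components and reciprocity correlations; `model2`
#' the status-by-performance coefficients; `model4_sigma2_b` the partner
#' variance after the full covariate set (against `model1`'s 0.71 it implies
#' the covariates explain about 30% of partner-level variation).
#'
#' @return A named list with elements `model1` (named numeric:
#'   `sigma2_m`, `sigma2_a`, `sigma2_b`, `rho_ab`, `rho_ee`), `model2`
#'   (named numeric of coefficients: `intercept`, `allstar_i`, `performance`,
#'   `allstar_i:performance`), and `model4_sigma2_b`.
#' @export
nba_reference_estimates <- function() {
  list(
    model1 = c(
      sigma2_m = 0.15, sigma2_a = 1.17, sigma2_b = 0.71,
      rho_ab = 0.75, rho_ee = 0.90
    ),
    model2 = c(
      intercept = 0.20, allstar_i = -2.92, performance = 0.23,
      `allstar_i:performance` = 1.80
    ),
    model4_sigma2_b = 0.50
  )
}
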