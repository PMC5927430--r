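#' Directed dyadic datasets
#'
#' A dyadic dataset holds one row per *ordered* pair of distinct individuals
#' (an actor `i` who may direct a tie and a partner `j` who may receive it)
#' within a bounded group `k`, together with a binary tie outcome and any
#' number of covariate columns. The design is a complete round robin: every
#' unordered within-group pair must contribute exactly two directed rows.
#'
#' `as_dyad_data()` validates a data frame and returns it in canonical order
#' (group, unordered pair, direction with the lexicographically smaller actor
#' first), which is the ordering the paired dyadic MCMC updates rely on.
#' Individuals are scoped to a single group: the same id appearing in two
#' groups is an error, matching the one-group-per-individual random-effect
#' structure of the model.
#'
#' @param x A data frame with columns `group`, `actor`, `partner`, `outcome`
#'   (after applying `column_map`); all other columns are carried along as
#'   covariates.
#' @param column_map Named character vector mapping the required roles to
#'   column names in `x`, e.g. `c(group = "team", actor = "ego",
#'   partner = "alter", outcome = "tie")`. Defaults to identity names.
#' @return A tibble of class `dyad_data` in canonical row order.
#' @examples
#' df <- tibble::tibble(
#'   group = "g1", actor = c("a", "b", "a", "c", "b", "c"),
#'   partner = c("b", "a", "c", "a", "c", "b"), outcome = c(1, 1, 0, 1, 0, 0)
#' )
#' d <- as_dyad_data(df)
#' network_density(d)
#' @export
as_dyad_data <- function(x, column_map = NULL) {
  stopifnot(is.data.frame(x))
  x <- tibble::as_tibble(x)
  map <- default_column_map(column_map)
  missing_cols <- setdiff(unname(map), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "column_map refers to columns absent from the data: ",
      paste(missing_cols, collapse = ", ")
    ), class = "srmtie_config_error")
  }
  x <- dplyr::rename(x, !!!setNames(unname(map), names(map)))
  x <- dplyr::relocate(x, "group", "actor", "partner", "outcome")
  x <- dplyr::mutate(x, dplyr::across(c("group", "actor", "partner"), as.character))

  report <- validate_dyad_frame(x)
  if (nrow(report) > 0) {
    abort(paste0(
      "invalid dyadic data:\n",
      paste0("  - ", report$message[seq_len(min(10, nrow(report)))], collapse = "\n"),
      if (nrow(report) > 10) sprintf("\n  (%d further problems)", nrow(report) - 10) else ""
    ), class = "srmtie_data_error")
  }

  x <- canonical_order(x)
  class(x) <- c("dyad_data", class(x))
  x
}

default_column_map <- function(column_map) {
  map <- c(group = "group", actor = "actor", partner = "partner", outcome = "outcome")
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || !all(names(column_map) %in% names(map))) {
      abort("column_map names must be among: group, actor, partner, outcome",
        class = "srmtie_config_error"
      )
    }
    map[names(column_map)] <- column_map
  }
  map
}

canonical_order <- function(x) {
  lo <- pmin(x$actor, x$partner)
  hi <- pmax(x$actor, x$partner)
  x[order(x$group, lo, hi, x$actor), , drop = FALSE]
}

#' Read a directed dyadic dataset from CSV
#'
#' Reads a long-format CSV (UTF-8, header row; one directed observation per
#' row), applies the column mapping, validates the round-robin structure, and
#' returns a canonical [as_dyad_data()] tibble. Unmapped columns become
#' covariates.
#'
#' @param path Path to a CSV file.
#' @inheritParams as_dyad_data
#' @return A `dyad_data` tibble.
#' @export
read_dyad_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "srmtie_config_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_dyad_data(df, column_map = column_map)
}

#' Write a dyadic dataset (or any result tibble) to CSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dyad_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Validate a dyadic dataset
#'
#' Reports every structural violation rather than stopping at the first:
#' self-ties, non-binary outcomes, duplicated ordered pairs, directed rows
#' whose reverse direction is missing, individuals appearing in more than one
#' group, and missing covariate values (the model analyses complete data;
#' nothing is imputed). An empty report means the dataset is fit for
#' modelling.
#'
#' @param x A data frame of directed dyadic observations (need not already be
#'   a validated `dyad_data` object).
#' @inheritParams as_dyad_data
#' @return A tibble with columns `check`, `group`, `message`; zero rows iff
#'   the data are valid.
#' @export
validate_dyads <- function(x, column_map = NULL) {
  x <- tibble::as_tibble(x)
  map <- default_column_map(column_map)
  missing_cols <- setdiff(unname(map), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mapped columns: ", paste(missing_cols, collapse = ", ")),
      class = "srmtie_config_error"
    )
  }
  x <- dplyr::rename(x, !!!setNames(unname(map), names(map)))
  x <- dplyr::mutate(x, dplyr::across(c("group", "actor", "partner"), as.character))
  validate_dyad_frame(x)
}

validate_dyad_frame <- function(x) {
  problems <- list()
  note <- function(check, group, message) {
    tibble::tibble(check = check, group = group, message = message)
  }

  bad_outcome <- which(!(x$outcome %in% c(0, 1)) | is.na(x$outcome))
  if (length(bad_outcome) > 0) {
    problems <- c(problems, list(note(
      "outcome", x$group[bad_outcome],
      sprintf("row %d: outcome must be 0 or 1 (got %s)", bad_outcome, x$outcome[bad_outcome])
    )))
  }

  self <- which(x$actor == x$partner)
  if (length(self) > 0) {
    problems <- c(problems, list(note(
      "self_tie", x$group[self],
      sprintf("row %d: self-tie %s -> %s in group %s", self, x$actor[self], x$partner[self], x$group[self])
    )))
  }

  key <- paste(x$group, x$actor, x$partner, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    problems <- c(problems, list(note(
      "duplicate", x$group[dup],
      sprintf("row %d: duplicated ordered pair %s -> %s in group %s", dup, x$actor[dup], x$partner[dup], x$group[dup])
    )))
  }

  rev_key <- paste(x$group, x$partner, x$actor, sep = "\r")
  ok <- x$actor != x$partner
  missing_rev <- which(ok & !(rev_key %in% key))
  if (length(missing_rev) > 0) {
    problems <- c(problems, list(note(
      "missing_reverse", x$group[missing_rev],
      sprintf(
        "row %d: directed row %s -> %s has no reverse row %s -> %s in group %s",
        missing_rev, x$actor[missing_rev], x$partner[missing_rev],
        x$partner[missing_rev], x$actor[missing_rev], x$group[missing_rev]
      )
    )))
  }

  members <- dplyr::distinct(
    tibble::tibble(
      group = c(x$group, x$group),
      id = c(x$actor, x$partner)
    )
  )
  multi <- members |>
    dplyr::count(.data$id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    problems <- c(problems, list(note(
      "multi_group", NA_character_,
      sprintf("individual %s appears in more than one group", multi$id)
    )))
  }

  covar_cols <- setdiff(names(x), c("group", "actor", "partner", "outcome"))
  if (length(covar_cols) > 0) {
    incomplete <- which(!complete.cases(x[covar_cols]))
    if (length(incomplete) > 0) {
      problems <- c(problems, list(note(
        "missing_covariate", x$group[incomplete],
        sprintf("row %d: missing covariate value(s)", incomplete)
      )))
    }
  }

  if (length(problems) == 0) {
    tibble::tibble(check = character(), group = character(), message = character())
  } else {
    dplyr::bind_rows(problems)
  }
}

group_table <- function(x, groups = NULL) {
  if (!is.null(groups)) {
    unknown <- setdiff(groups, unique(x$group))
    if (length(unknown) > 0) {
      abort(paste0("unknown group(s): ", paste(unknown, collapse = ", ")),
        class = "srmtie_lookup_error"
      )
    }
    x <- dplyr::filter(x, .data$group %in% groups)
  }
  x
}

#' Per-group network density
#'
#' The fraction of realised directed ties among the `n_k * (n_k - 1)`
#' possible ordered pairs in each group.
#'
#' @param x A `dyad_data` tibble (or compatible data frame).
#' @param groups Optional character vector restricting the output to the
#'   named groups; unknown groups are an error.
#' @return A tibble with columns `group`, `n_actors`, `n_ties`, `density`.
#' @export
network_density <- function(x, groups = NULL) {
  x <- group_table(tibble::as_tibble(x), groups)
  x |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(
      n_actors = dplyr::n_distinct(c(.data$actor, .data$partner)),
      n_ties = sum(.data$outcome),
      density = sum(.data$outcome) / dplyr::n(),
      .groups = "drop"
    )
}

#' Dyad census: mutual, asymmetric, and null pairs
#'
#' Counts, per group, the unordered pairs in which both directed ties are
#' present (mutual), exactly one is present (asymmetric), or neither is
#' (null). The identities `2 * mutual + asymmetric = ties` and
#' `mutual + asymmetric + null = choose(n_k, 2)` hold by construction.
#'
#' @inheritParams network_density
#' @return A tibble with columns `group`, `mutual`, `asymmetric`, `null`,
#'   `n_pairs`.
#' @export
dyad_census <- function(x, groups = NULL) {
  x <- group_table(tibble::as_tibble(x), groups)
  x |>
    dplyr::mutate(
      pair = paste(.data$group, pmin(.data$actor, .data$partner),
        pmax(.data$actor, .data$partner),
        sep = "\r"
      )
    ) |>
    dplyr::group_by(group = .data$group, pair = .data$pair) |>
    dplyr::summarise(ties = sum(.data$outcome), .groups = "drop") |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(
      mutual = sum(.data$ties == 2),
      asymmetric = sum(.data$ties == 1),
      null = sum(.data$ties == 0),
      n_pairs = dplyr::n(),
      .groups = "drop"
    )
}

#' Per-actor out- and in-degree
#'
#' @inheritParams network_density
#' @return A tibble with columns `group`, `id`, `out_degree`, `in_degree`.
#' @export
actor_degrees <- function(x, groups = NULL) {
  x <- group_table(tibble::as_tibble(x), groups)
  out_deg <- x |>
    dplyr::group_by(group = .data$group, id = .data$actor) |>
    dplyr::summarise(out_degree = sum(.data$outcome), .groups = "drop")
  in_deg <- x |>
    dplyr::group_by(group = .data$group, id = .data$partner) |>
    dplyr::summarise(in_degree = sum(.data$outcome), .groups = "drop")
  dplyr::full_join(out_deg, in_deg, by = c("group", "id")) |>
    dplyr::arrange(.data$group, .data$id)
}

#' One-row-per-group network summary
#'
#' Joins [network_density()] and [dyad_census()].
#'
#' @inheritParams network_density
#' @return A tibble with density, tie counts, and dyad census per group.
#' @export
network_summary <- function(x, groups = NULL) {
  dplyr::left_join(
    network_density(x, groups),
    dyad_census(x, groups),
    by = "group"
  )
}

# Row index of the reverse-direction row for every row of a canonical
# dyad_data tibble. Used by all paired (bivariate) MCMC updates.
reverse_index <- function(x) {
  key <- paste(x$group, x$actor, x$partner, sep = "\r")
  rev_key <- paste(x$group, x$partner, x$actor, sep = "\r")
  idx <- match(rev_key, key)
  stopifnot(!anyNA(idx), all(idx != seq_along(idx)))
  idx
}
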