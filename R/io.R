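# Readers for the CSV schemas and the packaged data-table fixtures.
# Identity is by ISO-3166 alpha-2 code throughout; display names travel in
# a separate column. All files are UTF-8 CSV with period decimal separators
# and explicit unit columns.

.fixture_files <- c(
  table1 = "registries_table1.csv",
  table2 = "folate_surveys_table2.csv",
  table3 = "impact_table3.csv",
  borrowing_map = "borrowing_map.csv",
  eu_membership = "eu_membership.csv",
  literature_prevalence = "literature_prevalence.csv")

.read_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    na.strings = c("", "NA"),
                                    fileEncoding = "UTF-8"))
}

.check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' Load a packaged data fixture
#'
#' The package bundles transcriptions of the published registry, folate
#' survey and impact tables, plus the cross-country borrowing rules, EU
#' membership sets, and the two literature prevalence values for countries
#' with neither registry nor borrowing rule.
#'
#' @param name One of `"table1"` (registry NTD counts 1998-2017),
#'   `"table2"` (serum-folate survey summaries), `"table3"` (published
#'   per-country impact figures), `"borrowing_map"`, `"eu_membership"`,
#'   `"literature_prevalence"`.
#' @return A validated tibble.
#' @export
load_fixture <- function(name) {
  if (!name %in% names(.fixture_files)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.fixture_files), collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", .fixture_files[[name]], package = "ntdfort",
                      mustWork = TRUE)
  df <- .read_csv(path)
  switch(name,
    table1 = {
      .check_columns(df, c("country_code", "registry_name", "first_year",
                           "last_year", "total_cases", "prevalence_per_1000",
                           "coverage_pct"), "table1")
      stopifnot(all(df$total_cases >= 0),
                all(df$first_year <= df$last_year))
    },
    table2 = {
      .check_columns(df, c("country_code", "country_name", "statistic_kind",
                           "value", "value_unit", "sd", "log_sd", "source",
                           "estimated_from_prevalence"), "table2")
      bad <- !is.na(df$value) & df$value <= 0
      if (any(bad)) {
        stop("table2: non-positive folate value for ",
             paste(df$country_code[bad], collapse = ", "), call. = FALSE)
      }
      df$estimated_from_prevalence <-
        tolower(as.character(df$estimated_from_prevalence)) == "true"
    },
    table3 = {
      .check_columns(df, c("country_code", "prevalence",
                           "pct_reduction_nosupp", "prevented_nosupp",
                           "pct_reduction_supp", "prevented_supp"), "table3")
    },
    borrowing_map = .check_columns(df, c("quantity", "target_country",
                                         "source_countries"),
                                   "borrowing_map"),
    eu_membership = .check_columns(df, c("country_code", "country_name",
                                         "eu1998", "eu2017"),
                                   "eu_membership"),
    literature_prevalence = .check_columns(df, c("country_code",
                                                 "prevalence_per_1000",
                                                 "source"),
                                           "literature_prevalence"))
  df
}

#' EU membership country sets
#'
#' @param set `"eu15"` (EU members in 1998), `"eu28"` (members in 2019) or
#'   `"non_eu"` (countries modelled but outside the EU).
#' @return Character vector of ISO-2 codes.
#' @export
country_set <- function(set = c("eu15", "eu28", "non_eu")) {
  set <- match.arg(set)
  eu <- load_fixture("eu_membership")
  switch(set,
         eu15 = eu$country_code[eu$eu1998 == "Y"],
         eu28 = eu$country_code[eu$eu2017 == "Y"],
         non_eu = eu$country_code[eu$eu2017 == "N"])
}

#' Annualize registry period totals into per-year records
#'
#' The published registry table prints only period totals (cases, and
#' births recoverable as `1000 * cases / prevalence`). This helper spreads
#' both uniformly across each registry's active years (remainder cases
#' assigned to the earliest years), giving an approximate annual record set
#' suitable for integration tests and demonstrations, not for per-year
#' inference.
#'
#' @param table1 The `table1` fixture (or same schema).
#' @return Tibble of records: `registry_name`, `country_code`, `year`,
#'   `cases`, `births_covered`.
#' @export
annualize_registry_totals <- function(table1) {
  .check_columns(table1, c("country_code", "registry_name", "first_year",
                           "last_year", "total_cases",
                           "prevalence_per_1000"), "table1")
  rows <- lapply(seq_len(nrow(table1)), function(i) {
    r <- table1[i, ]
    years <- seq(r$first_year, r$last_year)
    n <- length(years)
    total_births <- round(1000 * r$total_cases / r$prevalence_per_1000)
    cases <- rep(r$total_cases %/% n, n)
    extra <- r$total_cases %% n
    if (extra > 0) cases[seq_len(extra)] <- cases[seq_len(extra)] + 1
    tibble::tibble(registry_name = r$registry_name,
                   country_code = r$country_code,
                   year = as.integer(years),
                   cases = as.integer(cases),
                   births_covered = round(total_births / n))
  })
  dplyr::bind_rows(rows)
}

#' Fit folate distributions for every country in a survey table
#'
#' Rows reporting a median are taken as-is (unit-converted to nmol/L); rows
#' reporting an arithmetic mean and SD are inverted by closed-form moment
#' matching. Rows with a missing log-scale SD receive the median SD across
#' all surveys reporting one (`default_sd` overrides this). Countries with
#' no survey value inherit another country's distribution via the folate
#' rows of the borrowing map.
#'
#' @param surveys Survey table in the `table2` schema.
#' @param borrowing_map Borrowing-map tibble; only rows with
#'   `quantity == "folate"` are used. `NULL` skips borrowing.
#' @param default_sd Log-scale SD for surveys lacking one; default the
#'   median of the observed log-scale SDs.
#' @return Named list of [folate_distribution()] keyed by country code,
#'   with attribute `defaulted_sd_countries` naming countries that received
#'   the default SD.
#' @export
fit_folate_table <- function(surveys, borrowing_map = NULL,
                             default_sd = NULL) {
  if (is.null(default_sd)) default_sd <- default_log_sd(surveys$log_sd)
  defaulted <- character()
  dists <- list()
  for (i in seq_len(nrow(surveys))) {
    r <- surveys[i, ]
    if (is.na(r$value)) next
    value <- convert_units(r$value, r$value_unit, "nmol/L")
    if (r$statistic_kind == "median") {
      sigma <- r$log_sd
      if (is.na(sigma)) {
        sigma <- default_sd
        defaulted <- c(defaulted, r$country_code)
      }
      dists[[r$country_code]] <- folate_distribution(value, sigma)
    } else if (r$statistic_kind == "arithmetic_mean") {
      if (is.na(r$sd)) {
        d <- folate_distribution(value, default_sd)
        defaulted <- c(defaulted, r$country_code)
      } else {
        d <- fit_lognormal_closed_form(value,
                                       convert_units(r$sd, r$value_unit,
                                                     "nmol/L"))
      }
      dists[[r$country_code]] <- d
    } else {
      stop("unknown statistic_kind '", r$statistic_kind, "' for ",
           r$country_code, call. = FALSE)
    }
  }
  if (!is.null(borrowing_map)) {
    fmap <- borrowing_map[borrowing_map$quantity == "folate", ]
    for (i in seq_len(nrow(fmap))) {
      target <- fmap$target_country[i]
      if (!is.null(dists[[target]])) next # a direct survey wins
      src <- trimws(strsplit(fmap$source_countries[i], ";")[[1]])
      if (length(src) != 1 || is.null(dists[[src]])) {
        stop("folate borrowing for ", target, ": source ",
             fmap$source_countries[i], " unavailable", call. = FALSE)
      }
      dists[[target]] <- dists[[src]]
    }
  }
  attr(dists, "defaulted_sd_countries") <- defaulted
  attr(dists, "default_sd") <- default_sd
  dists
}

#' Read a scenario from a YAML file
#'
#' Recognised keys: `preset` (`us_1998`/`chile`) or `added_intake_ug_day`,
#' plus `supplementation_coverage`, `method`, `n_bands`.
#'
#' @param path YAML file path.
#' @return A [scenario()].
#' @export
read_scenario_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$preset)) {
    scenario_preset(cfg$preset,
                    supplementation_coverage =
                      cfg$supplementation_coverage %||% 0,
                    method = cfg$method %||% "quantile_bands",
                    n_bands = cfg$n_bands %||% 5L)
  } else {
    scenario(added_intake_ug_day = cfg$added_intake_ug_day %||% 200,
             supplementation_coverage = cfg$supplementation_coverage %||% 0,
             method = cfg$method %||% "quantile_bands",
             n_bands = cfg$n_bands %||% 5L)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
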