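# Combine prevalence series, folate distributions, births and a
# fortification scenario into prevented-pregnancy estimates. The reduction
# is a country-level constant (folate surveys carry no time structure);
# prevented cases in a year are births * baseline_prevalence/1000 *
# effective_reduction.

#' Predict the fortification impact for one country
#'
#' The scenario reduction is computed once from the country's folate
#' distribution (method per the scenario), discounted for supplementation
#' coverage, then applied to every year of the prevalence series.
#'
#' @param series Completed prevalence series tibble (`country_code`, `year`,
#'   `prevalence`, `provenance`).
#' @param births Data frame with `country_code`, `year`, `births`; must
#'   cover every year of `series` for this country.
#' @param dist [folate_distribution()] for the country.
#' @param scn [scenario()].
#' @param params [risk_model_params()].
#' @return Tibble of impact rows: `country_code`, `year`,
#'   `baseline_prevalence`, `reduction_fraction` (after supplementation),
#'   `counterfactual_prevalence`, `births`, `prevented_pregnancies`.
#' @export
predict_country_impact <- function(series, births, dist, scn,
                                   params = risk_model_params()) {
  stopifnot(inherits(dist, "folate_distribution"), inherits(scn, "scenario"))
  cc <- unique(series$country_code)
  stopifnot(length(cc) == 1)
  b <- births[births$country_code == cc, c("year", "births")]
  gaps <- setdiff(series$year, b$year)
  if (length(gaps) > 0) {
    stop("no births for ", cc, " in years: ",
         paste(sort(gaps), collapse = ", "), call. = FALSE)
  }
  if (any(b$births <= 0)) stop("births must be positive", call. = FALSE)
  red <- apply_supplementation(scenario_reduction(dist, scn, params),
                               scn$supplementation_coverage)
  out <- dplyr::left_join(series, b, by = "year")
  tibble::tibble(
    country_code = cc,
    year = out$year,
    baseline_prevalence = out$prevalence,
    reduction_fraction = red,
    counterfactual_prevalence = out$prevalence * (1 - red),
    births = out$births,
    prevented_pregnancies = out$births * out$prevalence / 1000 * red)
}

#' Aggregate impact rows over a set of countries
#'
#' Totals are sums over country-years; the overall percentage reduction is
#' prevented cases over expected baseline cases; pooled prevalences divide
#' total (counterfactual) cases by total births.
#'
#' @param impacts Tibble of impact rows (rbind of
#'   [predict_country_impact()] outputs).
#' @param country_set Character vector of ISO-2 codes to aggregate over;
#'   `NULL` aggregates everything present.
#' @return One-row tibble: `n_countries`, `total_births`, `baseline_cases`,
#'   `prevented`, `counterfactual_cases`, `baseline_prevalence`,
#'   `counterfactual_prevalence`, `pct_reduction`.
#' @export
aggregate_impacts <- function(impacts, country_set = NULL) {
  if (!is.null(country_set)) {
    missing_cc <- setdiff(country_set, unique(impacts$country_code))
    if (length(missing_cc) > 0) {
      stop("no impact rows for: ", paste(missing_cc, collapse = ", "),
           call. = FALSE)
    }
    impacts <- impacts[impacts$country_code %in% country_set, ]
  }
  baseline_cases <- sum(impacts$births * impacts$baseline_prevalence / 1000)
  prevented <- sum(impacts$prevented_pregnancies)
  tibble::tibble(
    n_countries = length(unique(impacts$country_code)),
    total_births = sum(impacts$births),
    baseline_cases = baseline_cases,
    prevented = prevented,
    counterfactual_cases = baseline_cases - prevented,
    baseline_prevalence = 1000 * baseline_cases / sum(impacts$births),
    counterfactual_prevalence =
      1000 * (baseline_cases - prevented) / sum(impacts$births),
    pct_reduction = 100 * prevented / baseline_cases)
}

#' Sensitivity analysis: a single folate median for every country
#'
#' Recomputes the aggregate impact with each country's median serum folate
#' replaced by the pooled (births-weighted) median; log-scale SDs are
#' retained per country unless `sigma_override` is given.
#'
#' @param series_by_country Named list of completed prevalence series.
#' @param births Births data frame (`country_code`, `year`, `births`).
#' @param dists Named list of [folate_distribution()] per country.
#' @param pooled_median Common median serum folate, nmol/L, `> 0`.
#' @param scn [scenario()].
#' @param params [risk_model_params()].
#' @param sigma_override Optional single log-scale SD used for all
#'   countries.
#' @param country_set Countries to aggregate; default all in
#'   `series_by_country`.
#' @return As [aggregate_impacts()].
#' @export
uniform_folate_sensitivity <- function(series_by_country, births, dists,
                                       pooled_median, scn,
                                       params = risk_model_params(),
                                       sigma_override = NULL,
                                       country_set = NULL) {
  stopifnot(pooled_median > 0)
  ccs <- if (is.null(country_set)) names(series_by_country) else country_set
  impacts <- dplyr::bind_rows(lapply(ccs, function(cc) {
    sigma <- if (is.null(sigma_override)) dists[[cc]]$sigma_log else
      sigma_override
    predict_country_impact(series_by_country[[cc]], births,
                           folate_distribution(pooled_median, sigma),
                           scn, params)
  }))
  aggregate_impacts(impacts)
}

#' Render a country-level or aggregate impact report
#'
#' Mirrors a published-table layout: per country, the baseline prevalence,
#' the prevalence with fortification, the percentage reduction and the
#' prevented pregnancies, summed over the years covered.
#'
#' @param impacts Tibble of impact rows.
#' @param style `"country_table"` (one row per country) or `"aggregate"`
#'   (one row).
#' @param rounding If `TRUE` (default), prevalences to 2 decimals,
#'   percentages to whole percent (half away from zero), prevented counts to
#'   whole pregnancies; `FALSE` emits full precision.
#' @return Tibble report.
#' @export
render_report <- function(impacts, style = c("country_table", "aggregate"),
                          rounding = TRUE) {
  style <- match.arg(style)
  if (nrow(impacts) == 0) stop("no impact rows to report", call. = FALSE)
  if (style == "aggregate") {
    agg <- aggregate_impacts(impacts)
    if (rounding) {
      agg$baseline_prevalence <- round_half_up(agg$baseline_prevalence, 2)
      agg$counterfactual_prevalence <-
        round_half_up(agg$counterfactual_prevalence, 2)
      agg$pct_reduction <- round_half_up(agg$pct_reduction)
      agg$prevented <- round_half_up(agg$prevented)
    }
    return(agg)
  }
  out <- impacts |>
    dplyr::group_by(.data$country_code) |>
    dplyr::summarise(
      baseline_cases = sum(.data$births * .data$baseline_prevalence / 1000),
      total_births = sum(.data$births),
      prevented = sum(.data$prevented_pregnancies),
      reduction_fraction = .data$prevented / .data$baseline_cases,
      .groups = "drop") |>
    dplyr::mutate(
      baseline_prevalence = 1000 * .data$baseline_cases / .data$total_births,
      counterfactual_prevalence =
        .data$baseline_prevalence * (1 - .data$reduction_fraction),
      pct_reduction = 100 * .data$reduction_fraction) |>
    dplyr::select("country_code", "baseline_prevalence",
                  "counterfactual_prevalence", "pct_reduction", "prevented")
  if (rounding) {
    out$baseline_prevalence <- round_half_up(out$baseline_prevalence, 2)
    out$counterfactual_prevalence <-
      round_half_up(out$counterfactual_prevalence, 2)
    out$pct_reduction <- round_half_up(out$pct_reduction)
    out$prevented <- round_half_up(out$prevented)
  }
  out
}

#' Back-compute approximate national births from a published impact table
#'
#' A published impact table gives, per country, the baseline prevalence per
#' 1,000, the whole-percent reduction and the prevented count; total births
#' over the period are then approximately
#' `prevented / (prevalence/1000 * reduction)`. The unrounded reduction from
#' this package's own risk engine is used where a folate distribution is
#' supplied, otherwise the printed whole-percent value. Approximate by
#' construction — for demonstrations and integration tests only.
#'
#' @param table Data frame with `country_code`, `prevalence`,
#'   `pct_reduction_nosupp`, `prevented_nosupp`.
#' @param dists Optional named list of [folate_distribution()] to supply
#'   unrounded reductions.
#' @param scn [scenario()] used for the unrounded reductions.
#' @param params [risk_model_params()].
#' @return Tibble `country_code`, `births_total` over the table's period.
#' @export
backcompute_births <- function(table, dists = NULL,
                               scn = scenario(),
                               params = risk_model_params()) {
  red <- table$pct_reduction_nosupp / 100
  if (!is.null(dists)) {
    for (i in seq_len(nrow(table))) {
      cc <- table$country_code[i]
      if (!is.null(dists[[cc]])) {
        red[i] <- scenario_reduction(dists[[cc]], scn, params)
      }
    }
  }
  tibble::tibble(country_code = table$country_code,
                 births_total = table$prevented_nosupp /
                   (table$prevalence / 1000 * red))
}
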