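# Assembly of complete per-country annual NTD prevalence series from
# partial multi-registry observations: pool registries within country-year,
# impute missing years from the nearest three observed years, and borrow
# whole series across countries where no registry exists.

#' Pool registry records into an observed per-year prevalence series
#'
#' For each year with at least one reporting registry, prevalence is total
#' cases over total covered births across the registries reporting that
#' year, per 1,000 births.
#'
#' @param records Data frame with columns `registry_name`, `country_code`,
#'   `year`, `cases`, `births_covered`; all rows must share one country.
#' @param window Optional integer year range to restrict to.
#' @return Tibble with `country_code`, `year`, `prevalence` (per 1,000),
#'   `cases`, `births_covered`, `provenance = "observed"`; observed years
#'   only. Empty input gives an empty series.
#' @export
pool_registries <- function(records, window = NULL) {
  required <- c("country_code", "year", "cases", "births_covered")
  if (!all(required %in% names(records))) {
    stop("records must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0) {
    return(tibble::tibble(country_code = character(), year = integer(),
                          prevalence = numeric(), cases = numeric(),
                          births_covered = numeric(),
                          provenance = character()))
  }
  if (length(unique(records$country_code)) > 1) {
    stop("records span multiple countries: ",
         paste(unique(records$country_code), collapse = ", "), call. = FALSE)
  }
  if (any(records$births_covered <= 0)) {
    stop("births_covered must be positive", call. = FALSE)
  }
  if (any(records$cases < 0)) stop("cases must be >= 0", call. = FALSE)
  out <- records |>
    dplyr::filter(if (is.null(window)) TRUE else .data$year %in% window) |>
    dplyr::group_by(.data$country_code, .data$year) |>
    dplyr::summarise(cases = sum(.data$cases),
                     births_covered = sum(.data$births_covered),
                     .groups = "drop") |>
    dplyr::mutate(prevalence = 1000 * .data$cases / .data$births_covered,
                  provenance = "observed") |>
    dplyr::select("country_code", "year", "prevalence", "cases",
                  "births_covered", "provenance") |>
    dplyr::arrange(.data$year)
  out
}

#' Fill missing years of a prevalence series by three-year averaging
#'
#' Each missing year takes the mean prevalence of up to three nearest
#' preceding years with a value; a year with no preceding values (a leading
#' gap) takes the mean of up to three nearest following observed years.
#' Years are filled in ascending order, so imputed values may feed later
#' imputations across multi-year gaps; provenance records which rule fired.
#'
#' @param series Tibble as returned by [pool_registries()] (columns
#'   `country_code`, `year`, `prevalence`, `provenance` at minimum).
#' @param window Integer vector of years the completed series must cover.
#' @return Tibble with one row per year of `window`, provenance one of
#'   `observed`, `imputed_prev3`, `imputed_next3` (or the input's own
#'   provenance for carried-over years).
#' @export
impute_missing_years <- function(series, window) {
  stopifnot(is.numeric(window), length(window) >= 1)
  if (nrow(series) == 0) {
    stop("cannot impute: series has no observed years", call. = FALSE)
  }
  window <- sort(as.integer(window))
  cc <- unique(series$country_code)
  stopifnot(length(cc) == 1)

  have <- series[series$year %in% window, ]
  years <- window
  prev <- stats::setNames(rep(NA_real_, length(years)), years)
  prov <- stats::setNames(rep(NA_character_, length(years)), years)
  prev[as.character(have$year)] <- have$prevalence
  prov[as.character(have$year)] <- have$provenance
  # observed years outside the window may still anchor leading imputations
  obs_following <- series[series$provenance == "observed", ]

  for (i in seq_along(years)) {
    if (!is.na(prev[i])) next
    filled_before <- which(!is.na(prev[seq_len(i - 1)]))
    if (length(filled_before) > 0) {
      take <- utils::tail(filled_before, 3)
      prev[i] <- mean(prev[take])
      prov[i] <- "imputed_prev3"
    } else {
      following <- obs_following$prevalence[obs_following$year > years[i]]
      fy <- obs_following$year[obs_following$year > years[i]]
      if (length(following) == 0) {
        stop("no observed years available to impute year ", years[i],
             " for ", cc, call. = FALSE)
      }
      take <- order(fy)[seq_len(min(3, length(fy)))]
      prev[i] <- mean(following[take])
      prov[i] <- "imputed_next3"
    }
  }
  tibble::tibble(country_code = cc, year = years,
                 prevalence = unname(prev), provenance = unname(prov))
}

#' Borrow complete prevalence series across countries
#'
#' Countries without registry data receive another country's completed
#' series, or the unweighted year-wise mean of several source countries'
#' series. Provenance is marked `borrowed:<sources>`.
#'
#' @param series_by_country Named list of completed series tibbles (names =
#'   ISO-2 codes).
#' @param borrowing_map Data frame with columns `target_country`,
#'   `source_countries` (semicolon-separated ISO-2 codes).
#' @return `series_by_country` with the targets added (or overwritten).
#' @export
borrow_countries <- function(series_by_country, borrowing_map) {
  stopifnot(all(c("target_country", "source_countries") %in%
                  names(borrowing_map)))
  out <- series_by_country
  for (i in seq_len(nrow(borrowing_map))) {
    target <- borrowing_map$target_country[i]
    sources <- strsplit(borrowing_map$source_countries[i], ";")[[1]]
    sources <- trimws(sources)
    missing_src <- setdiff(sources, names(out))
    if (length(missing_src) > 0) {
      stop("borrowing for ", target, ": missing source series ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    src <- lapply(out[sources], function(s) s[order(s$year), ])
    yrs <- src[[1]]$year
    if (!all(vapply(src, function(s) identical(s$year, yrs), logical(1)))) {
      stop("borrowing for ", target, ": source series cover different years",
           call. = FALSE)
    }
    prev <- rowMeans(do.call(cbind, lapply(src, `[[`, "prevalence")))
    out[[target]] <- tibble::tibble(
      country_code = target, year = yrs, prevalence = prev,
      provenance = paste0("borrowed:", paste(sources, collapse = ";")))
  }
  out
}

#' Overall prevalence from pooled totals
#'
#' @param total_cases Total NTD pregnancies.
#' @param total_births Total births, `> 0`.
#' @return Prevalence per 1,000 births.
#' @examples
#' pooled_prevalence(95213, 104e6) # ~0.92
#' @export
pooled_prevalence <- function(total_cases, total_births) {
  if (any(total_births <= 0)) stop("total_births must be > 0", call. = FALSE)
  if (any(total_cases < 0)) stop("total_cases must be >= 0", call. = FALSE)
  1000 * total_cases / total_births
}
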