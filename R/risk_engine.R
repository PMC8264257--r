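# Dose-response core. Two empirical results are combined: serum folate rises
# by 0.94 ng/mL per additional 0.1 mg/day of folic acid intake (Wald's
# meta-analysis), and NTD risk falls with serum folate as a power law with
# exponent -0.81 (from Daly's log-linear risk association). Fortification at
# the 1998 US level delivers about 200 ug/day, i.e. a 4.26 nmol/L increment.

#' Dose-response model parameters
#'
#' @param exponent_beta Power-law exponent on the folate ratio; negative
#'   (risk falls as folate rises). Default -0.81.
#' @param slope_ng_ml_per_100ug Serum-folate increase (ng/mL) per 100 ug/day
#'   additional folic acid. Default 0.94.
#' @param reference_intake_ug_day Daily intake delivered by US-level
#'   fortification. Default 200.
#' @param unit_factor nmol/L per ng/mL. Default 2.2655.
#' @return A `risk_model_params` list.
#' @export
risk_model_params <- function(exponent_beta = -0.81,
                              slope_ng_ml_per_100ug = 0.94,
                              reference_intake_ug_day = 200,
                              unit_factor = NMOL_PER_NG_ML) {
  stopifnot(exponent_beta < 0, slope_ng_ml_per_100ug > 0,
            reference_intake_ug_day > 0, unit_factor > 0)
  structure(list(exponent_beta = exponent_beta,
                 slope_ng_ml_per_100ug = slope_ng_ml_per_100ug,
                 reference_intake_ug_day = reference_intake_ug_day,
                 unit_factor = unit_factor),
            class = "risk_model_params")
}

#' Fortification scenario
#'
#' @param added_intake_ug_day Folic acid intake delivered by fortification,
#'   ug/day, `>= 0`. The `us_1998` preset uses 200; `chile` scales this by
#'   its higher flour fortification level (2.2 vs 1.4 mg/kg).
#' @param supplementation_coverage Fraction of births to women already taking
#'   periconceptional supplements, in `[0, 1]`; these births are assumed to
#'   gain nothing further from fortification.
#' @param method Risk-integration method: `"quantile_bands"` (evaluate the
#'   power law at the medians of `n_bands` equal-probability bands and
#'   average), `"median"` (evaluate at the population median only), or
#'   `"weighted_bands"` (band mean weighted by baseline risk).
#' @param n_bands Number of bands for the band methods. Default 5
#'   (quintiles).
#' @return A `scenario` list.
#' @export
scenario <- function(added_intake_ug_day = 200,
                     supplementation_coverage = 0,
                     method = c("quantile_bands", "median", "weighted_bands"),
                     n_bands = 5L) {
  method <- match.arg(method)
  stopifnot(is.numeric(added_intake_ug_day), added_intake_ug_day >= 0,
            is.numeric(supplementation_coverage),
            supplementation_coverage >= 0, supplementation_coverage <= 1,
            n_bands >= 1)
  structure(list(added_intake_ug_day = added_intake_ug_day,
                 supplementation_coverage = supplementation_coverage,
                 method = method, n_bands = as.integer(n_bands)),
            class = "scenario")
}

#' Preset scenarios
#'
#' `us_1998`: fortification at the level the USA adopted in 1998
#' (140 ug/100 g grain product, delivering about 200 ug/day). `chile`:
#' Chile's higher level (2.2 vs 1.4 mg/kg flour), modelled as intake scaled
#' by 220/140.
#'
#' @param name `"us_1998"` or `"chile"`.
#' @param supplementation_coverage Passed through to [scenario()].
#' @param ... Further arguments to [scenario()].
#' @return A [scenario()].
#' @export
scenario_preset <- function(name = c("us_1998", "chile"),
                            supplementation_coverage = 0, ...) {
  name <- match.arg(name)
  intake <- switch(name, us_1998 = 200, chile = 200 * 220 / 140)
  scenario(added_intake_ug_day = intake,
           supplementation_coverage = supplementation_coverage, ...)
}

#' Serum-folate increment produced by an added folic-acid intake
#'
#' Linear in intake: `delta = intake/100 * slope * unit_factor` nmol/L.
#'
#' @param intake_ug_day Added intake, ug/day, `>= 0`.
#' @param params [risk_model_params()].
#' @return Increment in nmol/L.
#' @examples
#' intake_to_increment(200) # ~4.26
#' @export
intake_to_increment <- function(intake_ug_day, params = risk_model_params()) {
  stopifnot(inherits(params, "risk_model_params"))
  if (any(!is.finite(intake_ug_day)) || any(intake_ug_day < 0)) {
    stop("intake must be finite and >= 0", call. = FALSE)
  }
  intake_ug_day / 100 * params$slope_ng_ml_per_100ug * params$unit_factor
}

#' Counterfactual-to-baseline NTD prevalence ratio at a given folate level
#'
#' `((folate + delta) / folate) ^ beta` with `beta = -0.81`: the fraction of
#' baseline prevalence remaining after the serum-folate increment.
#'
#' @param folate Baseline serum folate, nmol/L, `> 0`. Vectorised.
#' @param delta Serum-folate increment, nmol/L, `>= 0`.
#' @param params [risk_model_params()].
#' @return Ratio in `(0, 1]`.
#' @export
prevalence_ratio <- function(folate, delta, params = risk_model_params()) {
  stopifnot(inherits(params, "risk_model_params"))
  if (any(!is.finite(folate)) || any(folate <= 0)) {
    stop("folate must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(delta)) || any(delta < 0)) {
    stop("delta must be finite and >= 0", call. = FALSE)
  }
  ((folate + delta) / folate)^params$exponent_beta
}

#' Prevalence reduction using the population median only
#'
#' @param dist [folate_distribution()].
#' @param delta Serum-folate increment, nmol/L.
#' @param params [risk_model_params()].
#' @return Reduction fraction `1 - prevalence_ratio(median, delta)`.
#' @export
reduction_median_method <- function(dist, delta,
                                    params = risk_model_params()) {
  stopifnot(inherits(dist, "folate_distribution"))
  1 - prevalence_ratio(dist$median_nmol_l, delta, params)
}

#' Prevalence reduction by quantile-band integration
#'
#' Evaluates the prevalence ratio at the median of each of `n_bands`
#' equal-probability bands of the folate distribution and averages with
#' equal weight per band (each band holds the same share of women), so the
#' greater benefit to women with low folate is captured:
#' `1 - mean(prevalence_ratio(q_i, delta))`.
#'
#' `weights = "baseline_risk"` instead weights each band by its baseline
#' risk (proportional to `q_i^beta`), answering what fraction of baseline
#' cases is averted if risk truly follows the power law across bands. The
#' equal-weight mean is the default and is what reproduces published
#' country tables.
#'
#' @param dist [folate_distribution()].
#' @param delta Serum-folate increment, nmol/L.
#' @param n_bands Number of bands, `>= 1`.
#' @param params [risk_model_params()].
#' @param weights `"equal"` or `"baseline_risk"`.
#' @return Reduction fraction; equals [reduction_median_method()] when
#'   `sigma = 0` or `n_bands = 1`.
#' @export
reduction_band_method <- function(dist, delta, n_bands = 5L,
                                  params = risk_model_params(),
                                  weights = c("equal", "baseline_risk")) {
  weights <- match.arg(weights)
  q <- quantile_band_medians(dist, n_bands)
  ratio <- prevalence_ratio(q, delta, params)
  if (weights == "equal") {
    1 - mean(ratio)
  } else {
    w <- q^params$exponent_beta
    1 - sum(w * ratio) / sum(w)
  }
}

#' Prevalence reduction under a scenario's integration method
#'
#' Dispatches to the median or band method according to
#' `scenario$method`, before any supplementation adjustment.
#'
#' @param dist [folate_distribution()].
#' @param scn [scenario()].
#' @param params [risk_model_params()].
#' @return Unadjusted reduction fraction.
#' @export
scenario_reduction <- function(dist, scn, params = risk_model_params()) {
  stopifnot(inherits(scn, "scenario"))
  delta <- intake_to_increment(scn$added_intake_ug_day, params)
  switch(scn$method,
         median = reduction_median_method(dist, delta, params),
         quantile_bands = reduction_band_method(dist, delta, scn$n_bands,
                                                params),
         weighted_bands = reduction_band_method(dist, delta, scn$n_bands,
                                                params,
                                                weights = "baseline_risk"))
}

#' Discount a reduction for existing supplement use
#'
#' Births to women already taking periconceptional folic acid are assumed to
#' receive no additional benefit, so the population reduction scales by
#' `1 - coverage`.
#'
#' @param reduction Reduction fraction in `[0, 1]`.
#' @param coverage Supplementation coverage in `[0, 1]`.
#' @return `(1 - coverage) * reduction`.
#' @export
apply_supplementation <- function(reduction, coverage) {
  if (any(reduction < 0 | reduction > 1, na.rm = TRUE)) {
    stop("reduction must lie in [0, 1]", call. = FALSE)
  }
  if (any(coverage < 0 | coverage > 1, na.rm = TRUE)) {
    stop("coverage must lie in [0, 1]", call. = FALSE)
  }
  (1 - coverage) * reduction
}

#' Infer a serum-folate level from a relative NTD prevalence
#'
#' Inverts the power law: a population whose NTD prevalence is `ratio` times
#' that of a reference population has serum folate
#' `ref_folate * ratio^(1/beta)`. Used where no folate survey exists but the
#' registry prevalence is known (e.g. Ukraine).
#'
#' @param prevalence_ratio_vs_ref Prevalence relative to the reference,
#'   `> 0`.
#' @param ref_folate Reference serum folate, nmol/L, `> 0`.
#' @param params [risk_model_params()].
#' @return Serum folate, nmol/L.
#' @export
folate_from_prevalence_ratio <- function(prevalence_ratio_vs_ref, ref_folate,
                                         params = risk_model_params()) {
  stopifnot(inherits(params, "risk_model_params"))
  if (any(prevalence_ratio_vs_ref <= 0) || any(ref_folate <= 0)) {
    stop("prevalence ratio and reference folate must be > 0", call. = FALSE)
  }
  ref_folate * prevalence_ratio_vs_ref^(1 / params$exponent_beta)
}

#' Round half away from zero
#'
#' Published percentage reductions are rounded half away from zero (so 24.5
#' prints as 25), unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
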