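# Prevented-pregnancy accounting: per-country impacts, EU aggregation,
# sensitivity analysis and report rendering.

mk_series <- function(cc, years, prev) {
  tibble::tibble(country_code = cc, year = as.integer(years),
                 prevalence = prev, provenance = "observed")
}
mk_births <- function(cc, years, b) {
  tibble::tibble(country_code = cc, year = as.integer(years), births = b)
}

test_that("prevented counts are births x prevalence x effective reduction", {
  s <- mk_series("XX", 2000, 1.0)
  b <- mk_births("XX", 2000, 1e5)
  # sigma = 0 and a delta chosen so the reduction is exactly 20%
  f <- us_delta() / (0.8^(-1 / 0.81) - 1)
  d <- folate_distribution(f, 0)
  scn <- scenario(method = "median")
  imp <- predict_country_impact(s, b, d, scn)
  expect_equal(imp$prevented_pregnancies, 20, tolerance = 1e-9)
  expect_equal(imp$counterfactual_prevalence, 0.8, tolerance = 1e-9)
  # 25% supplementation scales everything by 0.75
  scn25 <- scenario(method = "median", supplementation_coverage = 0.25)
  imp25 <- predict_country_impact(s, b, d, scn25)
  expect_equal(imp25$prevented_pregnancies, 15, tolerance = 1e-9)
  expect_error(predict_country_impact(mk_series("XX", 2000:2001, 1), b, d, scn),
               "2001")
})

test_that("Denmark's published row is reproduced end to end", {
  s <- mk_series("DK", 1998:2017, 1.12)
  b <- mk_births("DK", 1998:2017, 65000)
  d <- folate_distribution(8.6, 0.29)
  imp0 <- predict_country_impact(s, b, d, scenario_preset("us_1998"))
  expect_equal(round_half_up(100 * imp0$reduction_fraction[1]), 28)
  imp25 <- predict_country_impact(
    s, b, d, scenario_preset("us_1998", supplementation_coverage = 0.25))
  expect_equal(round_half_up(100 * imp25$reduction_fraction[1]), 21)
})

test_that("baseline cases are conserved as counterfactual plus prevented", {
  set.seed(11)
  pop <- generate_population(6, seed = 11)
  years <- 1998:2017
  b <- dplyr::bind_rows(lapply(seq_len(nrow(pop)), function(i) {
    mk_births(pop$country_code[i], years, pop$annual_births[i])
  }))
  impacts <- dplyr::bind_rows(lapply(seq_len(nrow(pop)), function(i) {
    predict_country_impact(
      mk_series(pop$country_code[i], years, pop$prevalence[i]), b,
      folate_distribution(pop$median_nmol_l[i], pop$sigma_log[i]),
      scenario_preset("us_1998", supplementation_coverage = 0.25))
  }))
  baseline <- impacts$births * impacts$baseline_prevalence / 1000
  counterf <- impacts$births * impacts$counterfactual_prevalence / 1000
  expect_equal(baseline, counterf + impacts$prevented_pregnancies,
               tolerance = 1e-9)
  agg <- aggregate_impacts(impacts)
  expect_equal(agg$baseline_cases,
               agg$counterfactual_cases + agg$prevented, tolerance = 1e-9)
})

test_that("doubling births doubles prevented counts but not percentages", {
  s <- mk_series("XX", 1998:2002, 0.9)
  b1 <- mk_births("XX", 1998:2002, 2e5)
  b2 <- dplyr::mutate(b1, births = births * 2)
  d <- folate_distribution(12, 0.5)
  scn <- scenario_preset("us_1998")
  a1 <- aggregate_impacts(predict_country_impact(s, b1, d, scn))
  a2 <- aggregate_impacts(predict_country_impact(s, b2, d, scn))
  expect_equal(a2$prevented, 2 * a1$prevented)
  expect_equal(a2$pct_reduction, a1$pct_reduction)
})

test_that("aggregate prevented is exactly linear in supplementation coverage", {
  s <- mk_series("XX", 1998:2002, 0.9)
  b <- mk_births("XX", 1998:2002, 2e5)
  d <- folate_distribution(12, 0.5)
  a0 <- aggregate_impacts(predict_country_impact(
    s, b, d, scenario_preset("us_1998")))
  for (p in c(0.25, 0.6, 1)) {
    ap <- aggregate_impacts(predict_country_impact(
      s, b, d, scenario_preset("us_1998", supplementation_coverage = p)))
    expect_identical(ap$prevented, (1 - p) * a0$prevented)
  }
})

test_that("aggregation weights country reductions by expected baseline cases", {
  years <- 2000L
  # two countries with equal baseline cases and reductions 10% / 30%
  imp <- tibble::tibble(
    country_code = c("AA", "BB"), year = years,
    baseline_prevalence = c(1, 1),
    reduction_fraction = c(0.1, 0.3),
    counterfactual_prevalence = c(0.9, 0.7),
    births = c(1e5, 1e5),
    prevented_pregnancies = c(1e5 * 0.001 * 0.1, 1e5 * 0.001 * 0.3))
  agg <- aggregate_impacts(imp)
  expect_equal(agg$pct_reduction, 20)
  single <- aggregate_impacts(imp, "AA")
  expect_equal(single$pct_reduction, 10)
  expect_error(aggregate_impacts(imp, c("AA", "ZZ")), "ZZ")
})

test_that("Chile-level fortification prevents strictly more in every country", {
  g <- survey_grid()
  s_us <- scenario_preset("us_1998")
  s_cl <- scenario_preset("chile")
  for (i in seq_len(nrow(g))) {
    d <- folate_distribution(g$value[i], g$log_sd[i])
    expect_gt(scenario_reduction(d, s_cl), scenario_reduction(d, s_us))
  }
})

test_that("uniform-folate sensitivity reproduces the published 20/15%", {
  # every country assigned the pooled median 14.1 nmol/L and the default
  # log-SD 0.50
  series <- list(AA = mk_series("AA", 1998:2017, 1.1),
                 BB = mk_series("BB", 1998:2017, 0.7))
  births <- dplyr::bind_rows(mk_births("AA", 1998:2017, 3e5),
                             mk_births("BB", 1998:2017, 1e5))
  dists <- list(AA = folate_distribution(9, 0.4),
                BB = folate_distribution(16, 0.6))
  agg0 <- uniform_folate_sensitivity(series, births, dists, 14.1,
                                     scenario_preset("us_1998"),
                                     sigma_override = 0.50)
  expect_equal(round_half_up(agg0$pct_reduction), 20)
  agg25 <- uniform_folate_sensitivity(
    series, births, dists, 14.1,
    scenario_preset("us_1998", supplementation_coverage = 0.25),
    sigma_override = 0.50)
  expect_equal(round_half_up(agg25$pct_reduction), 15)
  # a pooled median equal to each country's own median changes nothing
  same <- uniform_folate_sensitivity(series["AA"], births,
                                     dists["AA"], 9, scenario_preset("us_1998"),
                                     sigma_override = 0.4)
  direct <- aggregate_impacts(predict_country_impact(
    series$AA, births, dists$AA, scenario_preset("us_1998")))
  expect_equal(same$prevented, direct$prevented)
  # full coverage prevents nothing
  none <- uniform_folate_sensitivity(
    series, births, dists, 14.1,
    scenario_preset("us_1998", supplementation_coverage = 1))
  expect_equal(none$prevented, 0)
})

test_that("reports mirror the published table layout and rounding", {
  s <- mk_series("DK", 1998:2017, 1.12)
  b <- mk_births("DK", 1998:2017, 65000)
  imp <- predict_country_impact(s, b, folate_distribution(8.6, 0.29),
                                scenario_preset("us_1998"))
  rep1 <- render_report(imp, "country_table")
  expect_equal(rep1$pct_reduction, 28)
  expect_equal(rep1$baseline_prevalence, 1.12)
  raw <- render_report(imp, "country_table", rounding = FALSE)
  expect_gt(abs(raw$pct_reduction - 28), 0) # full precision retained
  agg <- render_report(imp, "aggregate")
  expect_equal(agg$pct_reduction, 28)
  expect_error(render_report(imp[0, ]), "no impact rows")
})

test_that("births back-computation inverts the impact arithmetic", {
  t3 <- tibble::tibble(country_code = "DK", prevalence = 1.12,
                       pct_reduction_nosupp = 28, prevented_nosupp = 394)
  b <- backcompute_births(t3)
  expect_equal(b$births_total, 394 / (1.12 / 1000 * 0.28))
  # with a folate distribution the unrounded reduction is used
  b2 <- backcompute_births(t3, list(DK = folate_distribution(8.6, 0.29)))
  red <- reduction_band_method(folate_distribution(8.6, 0.29), us_delta(), 5)
  expect_equal(b2$births_total, 394 / (1.12 / 1000 * red))
})
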