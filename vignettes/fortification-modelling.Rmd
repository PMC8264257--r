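---
title: "Modelling folic-acid fortification and neural tube defect prevalence in Europe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling folic-acid fortification and neural tube defect prevalence in Europe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntdfort)
```

## The question

Mandatory folic-acid flour fortification, adopted by the USA in 1998, was
never implemented in the EU. `ntdfort` estimates how many neural tube defect
(NTD) pregnancies — anencephaly, spina bifida, encephalocele, counted across
live births, late fetal deaths and terminations for fetal anomaly — would
have been prevented in European countries between 1998 and 2017 had
fortification been in place, from three ingredients: registry-based NTD
prevalence, population serum-folate levels, and an empirical dose-response
linking the two.

## The model

**Serum folate is log-Gaussian within a population.** Each country's
distribution is parameterised by the median $m$ (nmol/L) and the SD of
natural-log folate $\sigma$, so the quantile function is
$q(p) = m\,e^{\sigma\Phi^{-1}(p)}$. Surveys that report a median are used
directly; surveys that report an arithmetic mean $\bar{x}$ and SD $s$ are
inverted by the log-normal moment identities

$$\sigma = \sqrt{\ln\!\left(1 + (s/\bar{x})^2\right)}, \qquad
  m = \bar{x}\big/\sqrt{1 + (s/\bar{x})^2},$$

which reproduce the published moments exactly
(`fit_lognormal_closed_form()`). A simulation-search variant
(`fit_lognormal_by_search()`) instead adjusts $(m, \sigma)$ until the
arithmetic mean and SD of a simulated sample match the published values —
the procedure one would use without the closed form. It uses a single
antithetic, standardised normal sample per seed (common random numbers), so
it is deterministic and agrees with the closed form to within the requested
tolerance; the closed form is the default because it is exact and fast, and
a test asserts their agreement. Surveys reporting a median but no
dispersion receive the median of the 21 published log-scale SDs, which is
0.50; this default is a single argument (`default_sd`) should a different
prior be preferred.

**Dose-response.** Two empirical results drive the counterfactual. Serum
folate rises by 0.94 ng/mL (× 2.2655 = 2.13 nmol/L) per additional
0.1 mg/day of folic acid, so US-level fortification (≈200 µg/day) raises
folate by $\Delta = 4.26$ nmol/L. NTD risk falls with serum folate $f$ as a
power law, giving the remaining-prevalence ratio

$$R(f) = \left(\frac{f + \Delta}{f}\right)^{-0.81}.$$

The same increment helps a low-folate population much more than a
high-folate one: Denmark (median 8.6 nmol/L) gets a 28% predicted
reduction, Hungary (19.0 nmol/L) only 16%.

**Integrating risk over the distribution.** Because $R$ is nonlinear, the
population-average reduction is not simply $R$ at the median. The
quantile-band method evaluates $R$ at the medians of $k$ equal-probability
bands ($p_i = (2i-1)/2k$; quintiles at the default $k = 5$) and averages
with equal weight per band — each band holds the same share of women:

```{r}
d_nl <- folate_distribution(7.3, 0.48)     # Netherlands
quantile_band_medians(d_nl, 5)
reduction_band_method(d_nl, intake_to_increment(200), 5)   # 0.317 -> 32%
reduction_median_method(d_nl, intake_to_increment(200))    # 0.311
```

The two methods agree to within about a percentage point across the
European survey grid, but the printed country table is matched by the
band method (e.g. Germany rounds to 20% under bands, 19% under the median
method), so `quantile_bands` is the default; both remain selectable per
scenario, plus a third, baseline-risk-weighted band mean (weights
$\propto f_i^{-0.81}$) for the case-averted interpretation — clearly
labelled, and not used for table reproduction. As $k \to \infty$ the band
mean converges to the exact expectation of $R$ under the log-normal
density, which `reduction_quadrature()` computes by adaptive quadrature;
at $k = 2000$ they agree to $10^{-3}$. At $k = 5$ the band mean sits
0.2–2.6% (relative) below quadrature — the tails are truncated at the
outer band medians — which is the dominant bias in end-to-end simulations.

On the published survey grid the band reduction is at least the median
reduction. This is a curvature property of $R$ in log-folate space, not a
theorem: at an extremely low median (the 3.2 nmol/L estimate used for
Ukraine) it reverses by less than $10^{-3}$.

**Supplementation.** A fraction $p$ of births (25% in the published
scenario) is assumed already protected by periconceptional supplements and
to gain nothing from fortification, so the population reduction scales by
$1 - p$ — exactly linear, by construction.

**Prevented pregnancies.** The reduction is treated as constant over
1998–2017 within a country (the folate surveys have no usable time
structure). Per country-year, prevented cases are
births × prevalence/1000 × effective reduction, and baseline cases always
equal counterfactual cases plus prevented cases.

## Assembling prevalence

Registry records carry cases and covered births per year. Within a
country-year, registries are pooled by summing cases and births. Years
with no reporting registry are filled with the mean of up to three nearest
preceding years with a value; a year with nothing before it (a leading
gap) takes the mean of up to three nearest following observed years.
Years are filled in ascending order, so imputed values can cascade across
multi-year gaps — necessary to complete, say, a series observed only
2005–2008 across a 1998–2017 window — and every imputed year is flagged in
the provenance column. Preceding years take priority because that is the
order the rule is stated in; the choice is deterministic and idempotent.

Countries with no registry inherit prevalence by an editable borrowing
table rather than hard-coded rules: Luxembourg from Switzerland, Greece
and Cyprus from Italy, Estonia from Finland, Romania from Poland, Latvia
and Lithuania from the unweighted mean of Poland, Finland and Sweden. The
Slovak Republic and Slovenia use constant literature values (0.53 and 0.74
per 1,000). Folate values have their own borrowing rows (e.g. Malta from
Greece), since the folate and prevalence sources differ by country.

The packaged registry fixture is approximate by construction: the
published table prints only period totals per registry, which
`annualize_registry_totals()` spreads uniformly across each registry's
active years. Totals and period prevalences are preserved; year-to-year
variation is not. It supports integration tests and demonstrations; the
headline per-country reductions never touch it, being functions of the
folate table alone.

## Births, units and other fixed choices

- National births are an input. The package ships a generator for
  synthetic births and a back-computation from the published impact table
  (births ≈ prevented/(prevalence × reduction), using this package's
  unrounded reductions), labelled approximate and used for demonstrations;
  the published EU aggregates are reproduced to within about 0.3% on it.
- Concentrations are nmol/L internally; ng/mL and µg/L (equivalent) convert
  at 2.2655 nmol/L per ng/mL (folic acid, 441.4 g/mol), consistent with the
  published 1.88 ng/mL ↔ 4.26 nmol/L pairing. Where a source states the
  pooled median as 14.1 µg/L we read nmol/L, matching every other use of
  the value.
- Published percentages are rounded half away from zero
  (`round_half_up()`), which reproduces the printed whole-percent cells.
- The pooled European folate level is the births-weighted median of country
  medians with a midpoint rule at exact ties. On the approximate births
  fixture it lands on 14.3 nmol/L — the published 14.1 falls between
  country medians and depends on the authors' exact Eurostat weights.
- EU15/EU28 membership lives in a fixture; Norway, Switzerland and Ukraine
  are modelled but excluded from EU aggregates.
- The Chile preset scales intake by its higher flour-fortification level
  (2.2 vs 1.4 mg/kg): 200 × 220/140 ≈ 314 µg/day.

## What the synthetic generator does and does not emulate

`generate_population()` draws country medians in 7–19 nmol/L, log-SDs in
0.3–0.8 and prevalences in 0.4–1.8 per 1,000 — the ranges spanned by the
European tables — with an optional mode linking prevalence to folate by the
−0.81 power law. Registry counts are Poisson at the true prevalence among
covered births (at ~1/1000 prevalence, indistinguishable from binomial and
standard for registry counts); surveys report the arithmetic mean and SD of
log-normal draws, the exact published form the fitters must invert. It does
not emulate secular trends, registry ascertainment differences, coding
changes, or survey measurement error beyond sampling — so recovery tests
demonstrate the pipeline's statistical correctness under its own
assumptions, not robustness to the heterogeneity of real registries.

With full registry coverage, 20 years and 10⁴-subject surveys, the
pipeline recovers analytic ground-truth prevented totals within 5% across
50 seeds (mean error ≈ −1%, from the quintile discretisation). Test and
script problem sizes (5 countries per world, 25–50 seeds, 10⁴ survey
subjects) keep each check to a few seconds while leaving the Poisson and
discretisation error terms clearly visible.

## Known limitations

- The absolute headline counts depend on the authors' per-country-year
  Eurostat births extract, which is not printed; with back-computed births
  they are reproduced approximately (≈19.5k/14.6k prevented), not exactly.
- One folate survey per country, often from a single time point and
  sometimes a small sample, stands in for 20 years of exposure.
- Point estimates only: the −0.81 exponent and the 0.94 slope are carried
  without uncertainty intervals, as in the published analysis.
- Ukraine's folate level is itself inferred from its prevalence via the
  inverse power law (`folate_from_prevalence_ratio()`); the reference pair
  the original estimate used is unspecified, so the bracketed 3.2 nmol/L is
  taken as given from the survey table rather than re-derived.
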