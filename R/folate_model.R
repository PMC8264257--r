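# Log-normal serum-folate distributions estimated from published survey
# summaries. Serum folate in women of childbearing age is modelled as
# log-Gaussian within a country; surveys report either the median (the
# natural location parameter) or an arithmetic mean and SD, which must be
# converted to the median / log-scale SD parameterisation before use.

NMOL_PER_NG_ML <- 2.2655 # nmol/L per ng/mL, folic acid 441.4 g/mol

.folate_units <- c("nmol/L", "ng/mL", "ug/L")

.canon_unit <- function(unit) {
  u <- gsub("µ|μ", "u", trimws(unit)) # accept micro signs
  u <- .folate_units[match(tolower(u), tolower(.folate_units))]
  if (is.na(u)) {
    stop("unknown folate concentration unit: '", unit,
         "' (expected one of ", paste(.folate_units, collapse = ", "), ")",
         call. = FALSE)
  }
  u
}

#' Convert serum-folate concentrations between units
#'
#' Serum folate is reported either on the mass scale (ng/mL, equivalently
#' ug/L) or the molar scale (nmol/L). One ng/mL equals 2.2655 nmol/L.
#'
#' @param value Numeric vector of concentrations, `>= 0`.
#' @param from,to Unit tags; one of `"nmol/L"`, `"ng/mL"`, `"ug/L"`.
#'   `ng/mL` and `ug/L` are the same scale.
#' @return Numeric vector in the `to` unit.
#' @examples
#' convert_units(1.88, "ng/mL", "nmol/L") # 4.26
#' @export
convert_units <- function(value, from, to) {
  stopifnot(is.numeric(value), all(value >= 0, na.rm = TRUE))
  from <- .canon_unit(from)
  to <- .canon_unit(to)
  mass <- c("ng/mL", "ug/L")
  if (from == to || (from %in% mass && to %in% mass)) return(value)
  if (from %in% mass) value * NMOL_PER_NG_ML else value / NMOL_PER_NG_ML
}

#' Construct a log-normal serum-folate distribution
#'
#' Parameterised by the median `m` (nmol/L) and the SD of natural-log folate
#' `sigma`. The quantile function is `q(p) = m * exp(sigma * qnorm(p))`.
#'
#' @param median_nmol_l Median serum folate, nmol/L, `> 0`.
#' @param sigma_log SD of log folate, `>= 0` (0 gives a point mass at the
#'   median).
#' @return A `folate_distribution` object.
#' @export
folate_distribution <- function(median_nmol_l, sigma_log) {
  stopifnot(is.numeric(median_nmol_l), length(median_nmol_l) == 1,
            is.numeric(sigma_log), length(sigma_log) == 1)
  if (!is.finite(median_nmol_l) || median_nmol_l <= 0) {
    stop("median_nmol_l must be a positive finite number", call. = FALSE)
  }
  if (!is.finite(sigma_log) || sigma_log < 0) {
    stop("sigma_log must be finite and >= 0", call. = FALSE)
  }
  structure(list(median_nmol_l = unname(median_nmol_l),
                 sigma_log = unname(sigma_log)),
            class = "folate_distribution")
}

#' @export
print.folate_distribution <- function(x, ...) {
  cat(sprintf("Log-normal serum folate: median %.3g nmol/L, log-SD %.3g\n",
              x$median_nmol_l, x$sigma_log))
  invisible(x)
}

#' Analytic arithmetic mean and SD of a log-normal folate distribution
#'
#' @param dist A [folate_distribution()].
#' @return Named numeric vector `c(mean, sd)` on the concentration scale.
#' @export
lognormal_moments <- function(dist) {
  stopifnot(inherits(dist, "folate_distribution"))
  mu <- log(dist$median_nmol_l)
  s2 <- dist$sigma_log^2
  m <- exp(mu + s2 / 2)
  c(mean = m, sd = m * sqrt(expm1(s2)))
}

#' Fit a log-normal distribution to an arithmetic mean and SD (closed form)
#'
#' Inverts the log-normal moment identities: with coefficient of variation
#' `cv = sd/mean`, `sigma = sqrt(log(1 + cv^2))` and
#' `median = mean / sqrt(1 + cv^2)`. A log-normal with these parameters has
#' arithmetic mean and SD exactly equal to the inputs.
#'
#' @param mean Arithmetic mean concentration, `> 0`.
#' @param sd Arithmetic SD on the same scale, `>= 0`.
#' @return A [folate_distribution()].
#' @examples
#' fit_lognormal_closed_form(15, 8) # median 13.24, sigma 0.5003
#' @export
fit_lognormal_closed_form <- function(mean, sd) {
  if (!is.numeric(mean) || length(mean) != 1 || !is.finite(mean) || mean <= 0) {
    stop("mean must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(sd) || length(sd) != 1 || !is.finite(sd) || sd < 0) {
    stop("sd must be a single number >= 0", call. = FALSE)
  }
  ratio2 <- 1 + (sd / mean)^2
  folate_distribution(median_nmol_l = mean / sqrt(ratio2),
                      sigma_log = sqrt(log(ratio2)))
}

#' Fit a log-normal distribution to an arithmetic mean and SD by simulation
#' search
#'
#' Mirrors the survey-inversion procedure of trying log-Gaussian
#' distributions until the observed arithmetic mean and SD of a simulated
#' sample match the published values. A single standard-normal sample is
#' drawn once from `seed` and reused for every candidate (common random
#' numbers), so the search is deterministic given the seed; Nelder-Mead
#' minimises the summed squared relative moment errors over (median, sigma).
#'
#' @param mean,sd Published arithmetic mean (`> 0`) and SD (`>= 0`).
#' @param tolerance Maximum relative error allowed on each matched moment.
#' @param seed Integer seed for the simulation sample.
#' @param n_draws Size of the simulation sample.
#' @return A [folate_distribution()] whose simulated moments match the inputs
#'   within `tolerance`.
#' @export
fit_lognormal_by_search <- function(mean, sd, tolerance = 1e-3, seed = 1L,
                                    n_draws = 2e5) {
  stopifnot(is.numeric(tolerance), length(tolerance) == 1, tolerance > 0)
  if (!is.numeric(mean) || length(mean) != 1 || !is.finite(mean) || mean <= 0) {
    stop("mean must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(sd) || length(sd) != 1 || !is.finite(sd) || sd < 0) {
    stop("sd must be a single number >= 0", call. = FALSE)
  }
  if (sd == 0) return(folate_distribution(mean, 0))

  # Common antithetic z-sample, standardised to exact mean 0 / SD 1, drawn
  # without disturbing the caller's RNG stream. Antithetic pairing plus
  # standardisation keeps the simulated-moment error well below typical
  # tolerances at this sample size.
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  z0 <- stats::rnorm(ceiling(n_draws / 2))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  z <- c(z0, -z0)
  z <- z / stats::sd(z)

  sim_err <- function(par) {
    m <- exp(par[1]) # median
    s <- exp(par[2]) # sigma
    x <- m * exp(s * z)
    ((mean(x) - mean) / mean)^2 +
      ((stats::sd(x) - sd) / sd)^2
  }
  start <- fit_lognormal_closed_form(mean, sd)
  fit <- stats::optim(log(c(start$median_nmol_l, start$sigma_log)), sim_err,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  m <- exp(fit$par[1])
  s <- exp(fit$par[2])
  x <- m * exp(s * z)
  rel <- c(abs(mean(x) - mean) / mean, abs(stats::sd(x) - sd) / sd)
  if (any(rel > tolerance)) {
    stop(sprintf(paste0("simulation search did not match mean=%.4g, sd=%.4g ",
                        "within tolerance %.1e (relative errors %.2e, %.2e)"),
                 mean, sd, tolerance, rel[1], rel[2]), call. = FALSE)
  }
  folate_distribution(m, s)
}

#' Default log-scale SD for countries reporting only a median
#'
#' Surveys that publish a median without any dispersion are assigned the
#' median of the log-scale SDs observed across all surveys that do report
#' one.
#'
#' @param log_sds Numeric vector of log-scale SDs; `NA`s allowed and dropped.
#' @return The median of the non-missing values.
#' @export
default_log_sd <- function(log_sds) {
  stopifnot(is.numeric(log_sds))
  x <- log_sds[!is.na(log_sds)]
  if (length(x) == 0) {
    stop("no log-scale SDs available to take the median of", call. = FALSE)
  }
  if (any(x < 0)) stop("log-scale SDs must be >= 0", call. = FALSE)
  stats::median(x)
}

#' Medians of k equal-probability bands of a folate distribution
#'
#' Divides the distribution into `k` bands of equal probability (quintiles
#' when `k = 5`) and returns the median of each band:
#' `m * exp(sigma * qnorm((2i - 1) / (2k)))` for `i = 1..k`.
#'
#' @param dist A [folate_distribution()].
#' @param k Number of bands, `>= 1`.
#' @return Increasing numeric vector of length `k` (constant when
#'   `sigma = 0`).
#' @examples
#' quantile_band_medians(folate_distribution(7.3, 0.48), 5)
#' @export
quantile_band_medians <- function(dist, k = 5L) {
  stopifnot(inherits(dist, "folate_distribution"))
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != floor(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  p <- (2 * seq_len(k) - 1) / (2 * k)
  dist$median_nmol_l * exp(dist$sigma_log * stats::qnorm(p))
}

#' Births-weighted median of country folate medians
#'
#' The pooled European serum-folate level is the weighted median of the
#' country medians, each country weighted by its births. Ties at the halfway
#' point use the midpoint of the two straddling medians.
#'
#' @param medians Named numeric vector of country medians (nmol/L).
#' @param weights Named nonnegative numeric vector of weights (births); every
#'   name in `weights` must have a median.
#' @return The weighted median concentration.
#' @export
pooled_median <- function(medians, weights) {
  stopifnot(is.numeric(medians), is.numeric(weights))
  if (is.null(names(weights)) || is.null(names(medians))) {
    stop("medians and weights must be named by country code", call. = FALSE)
  }
  if (any(weights < 0) || all(weights == 0)) {
    stop("weights must be nonnegative and not all zero", call. = FALSE)
  }
  missing_cc <- setdiff(names(weights)[weights > 0], names(medians))
  if (length(missing_cc) > 0) {
    stop("no folate median for weighted countries: ",
         paste(missing_cc, collapse = ", "), call. = FALSE)
  }
  w <- weights[weights > 0]
  x <- medians[names(w)]
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- unname(cumsum(w) / sum(w))
  i <- which(cw >= 0.5)[1]
  if (isTRUE(all.equal(cw[i], 0.5)) && i < length(x)) {
    unname(x[i] + x[i + 1]) / 2
  } else {
    unname(x[i])
  }
}
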