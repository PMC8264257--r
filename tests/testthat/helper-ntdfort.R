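# Shared across test files: the published survey parameter grid and the
# US-level serum-folate increment.

us_delta <- function() intake_to_increment(200)

# (median, log-SD) pairs for every country with a direct survey value;
# with `printed_sd_only`, restricted to the 21 surveys that report an SD
# (dropping the defaulted-SD countries, including the very-low Ukraine
# estimate).
survey_grid <- function(printed_sd_only = FALSE) {
  t2 <- load_fixture("table2")
  t2 <- t2[!is.na(t2$value), ]
  if (printed_sd_only) {
    t2 <- t2[!is.na(t2$log_sd), ]
  } else {
    t2$log_sd[is.na(t2$log_sd)] <- default_log_sd(t2$log_sd)
  }
  t2[, c("country_code", "value", "log_sd")]
}

# tiny two-registry record set used in assembly tests
toy_records <- function() {
  tibble::tibble(
    registry_name = c("A", "A", "B", "B"),
    country_code = "XX",
    year = c(2000L, 2001L, 2000L, 2001L),
    cases = c(3L, 4L, 2L, 1L),
    births_covered = c(1000L, 1000L, 4000L, 4000L))
}
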