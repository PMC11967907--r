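# Shared fixtures: a small hand-built two-country table and standard
# generator parameter vectors used across test files.

std_age_shares_start <- c(0.045, 0.17, 0.28, 0.29, 0.17, 0.045)
std_age_shares_end <- c(0.02, 0.10, 0.22, 0.32, 0.25, 0.09)
std_age_risk <- c(4.5, 3.2, 3.0, 3.4, 4.4, 6.5) / 1000
std_age_risk_end <- c(4.8, 3.2, 2.9, 3.2, 3.7, 5.0) / 1000

tiny_table <- function() {
  tibble::tribble(
    ~country, ~year, ~axis, ~stratum, ~stillbirths, ~live_births,
    "AA", 2010L, "maternal_age", "<35", 5, 995,
    "AA", 2010L, "maternal_age", "35+", 15, 985,
    "AA", 2021L, "maternal_age", "<35", 3, 797,
    "AA", 2021L, "maternal_age", "35+", 14, 1186,
    "BB", 2010L, "maternal_age", "<35", 10, 1990,
    "BB", 2010L, "maternal_age", "35+", 20, 1980)
}

small_config <- function(seed = 1, n = 1e5, years = c(2010, 2021),
                         frozen_risk = FALSE, ...) {
  synthetic_config(
    countries = c(X = n), years = years,
    age_shares_start = std_age_shares_start,
    age_shares_end = std_age_shares_end,
    age_risk_start = std_age_risk,
    age_risk_end = if (frozen_risk) std_age_risk else std_age_risk_end,
    multiple_share_start = 0.035,
    seed = seed, ...)
}

# Exhaustive pairwise enumeration of the Mann-Kendall S statistic.
brute_force_S <- function(y) {
  n <- length(y)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- s + sign(y[j] - y[i])
    }
  }
  s
}

# Random stratum-summary population over a fixed label set.
random_population <- function(n_strata = 4) {
  shares <- stats::rgamma(n_strata, 1) + 0.01
  tibble::tibble(
    stratum = paste0("s", seq_len(n_strata)),
    share = shares / sum(shares),
    rate = stats::runif(n_strata, 0, 12))
}
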