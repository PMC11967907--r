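# Synthetic stratified birth registry with known ground truth. Emulates a
# multi-country perinatal surveillance extract: per-country annual totals
# spanning three orders of magnitude, a maternal age distribution drifting
# toward 35+, multiple-birth shares of a few percent with mostly declining
# trends, J-shaped age-specific stillbirth risk flattening at advanced ages
# over time, ~3x risk for multiples, partially missing stratum labels,
# disclosure suppression of small cells, late series starts, and optional
# pandemic-year rate shocks.

#' Configuration for the synthetic birth registry
#'
#' All parameters of [generate_births()]. Start/end vectors are linearly
#' interpolated across the year span. Risks are per-1 probabilities;
#' `risk_scale` shifts whole countries' levels to spread national rates.
#'
#' @param countries Named numeric vector: annual total births per country.
#' @param years Year span, default 2010:2021.
#' @param age_bands Maternal age band labels (default
#'   [age_bands_default()]).
#' @param age_shares_start,age_shares_end Birth shares per age band at the
#'   first and last year (each sums to 1).
#' @param age_risk_start,age_risk_end Stillbirth probability per age band
#'   at the first and last year.
#' @param multiple_share_start,multiple_share_end Proportion of births from
#'   multiple pregnancies at the first and last year; scalar or one value
#'   per country.
#' @param multiple_risk_ratio Relative stillbirth risk of multiples vs
#'   singletons, default 3.
#' @param risk_scale Per-country multiplier on all stillbirth risks
#'   (scalar or one value per country), default 1.
#' @param age_multiplicity_coupling Log-odds-style tilt making multiples
#'   more likely at older ages (0 = independence, the default).
#' @param missing_frac Probability that a birth's stratum label is missing
#'   (moved to the `"unknown"` stratum per axis), default 0.
#' @param suppress_below Disclosure bound k: stillbirth cells with count
#'   < k are reported as suppressed. Scalar or per country; 0 disables.
#' @param covid_shock Optional multiplicative risk shock for specific
#'   years: a named numeric vector like `c("2020" = 1.5)` applied to all
#'   countries, or a named list of such vectors per country.
#' @param first_year Optional named integer vector of per-country series
#'   starts (years before are dropped, emulating late-joining registries).
#' @param sampling `"binomial"` (multinomial births, binomial stillbirths)
#'   or `"expected"` (deterministic expected counts, the infinite-n limit).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(countries,
                             years = 2010:2021,
                             age_bands = age_bands_default(),
                             age_shares_start,
                             age_shares_end = age_shares_start,
                             age_risk_start,
                             age_risk_end = age_risk_start,
                             multiple_share_start = 0.035,
                             multiple_share_end = multiple_share_start,
                             multiple_risk_ratio = 3,
                             risk_scale = 1,
                             age_multiplicity_coupling = 0,
                             missing_frac = 0,
                             suppress_below = 0,
                             covid_shock = NULL,
                             first_year = NULL,
                             sampling = c("binomial", "expected"),
                             seed = 1) {
  sampling <- match.arg(sampling)
  if (is.null(names(countries))) {
    abort("countries must be a named numeric vector of annual birth totals",
          class = "sbt_config_error")
  }
  nb <- length(age_bands)
  for (nm in c("age_shares_start", "age_shares_end")) {
    v <- get(nm)
    if (length(v) != nb || abs(sum(v) - 1) > 1e-8 || any(v < 0)) {
      abort(paste0(nm, " must be ", nb,
                   " non-negative shares summing to 1"),
            class = "sbt_config_error")
    }
  }
  for (nm in c("age_risk_start", "age_risk_end")) {
    v <- get(nm)
    if (length(v) != nb || any(v < 0) || any(v > 1)) {
      abort(paste0(nm, " must be ", nb, " probabilities"),
            class = "sbt_config_error")
    }
  }
  if (multiple_risk_ratio <= 0) {
    abort("multiple_risk_ratio must be positive", class = "sbt_config_error")
  }
  n_c <- length(countries)
  recycle <- function(v) {
    if (length(v) == 1) rep(v, n_c)
    else if (length(v) == n_c) v
    else abort("Per-country parameter has wrong length",
               class = "sbt_config_error")
  }
  if (any(multiple_share_start < 0 | multiple_share_start > 1) ||
      any(multiple_share_end < 0 | multiple_share_end > 1) ||
      missing_frac < 0 || missing_frac > 1) {
    abort("Shares and probabilities must lie in [0, 1]",
          class = "sbt_config_error")
  }
  structure(
    list(countries = countries, years = sort(unique(as.integer(years))),
         age_bands = age_bands,
         age_shares_start = age_shares_start,
         age_shares_end = age_shares_end,
         age_risk_start = age_risk_start, age_risk_end = age_risk_end,
         multiple_share_start = recycle(multiple_share_start),
         multiple_share_end = recycle(multiple_share_end),
         multiple_risk_ratio = multiple_risk_ratio,
         risk_scale = recycle(risk_scale),
         age_multiplicity_coupling = age_multiplicity_coupling,
         missing_frac = missing_frac,
         suppress_below = recycle(suppress_below),
         covid_shock = covid_shock, first_year = first_year,
         sampling = sampling, seed = as.integer(seed)),
    class = "synthetic_config")
}

# Expected age x multiplicity cross-tabulation (cell birth shares and
# stillbirth probabilities) for one country-year. w in [0,1] is the
# interpolation weight along the year span.
cross_tab_expectation <- function(config, country_idx, w, shock = 1) {
  p_age <- (1 - w) * config$age_shares_start + w * config$age_shares_end
  p_age <- p_age / sum(p_age)
  q <- (1 - w) * config$multiple_share_start[country_idx] +
    w * config$multiple_share_end[country_idx]
  nb <- length(config$age_bands)
  tilt <- exp(config$age_multiplicity_coupling *
                (seq_len(nb) - (nb + 1) / 2))
  q_age <- pmin(q * tilt / sum(p_age * tilt), 0.999)
  risk_age <- ((1 - w) * config$age_risk_start + w * config$age_risk_end) *
    config$risk_scale[country_idx] * shock
  tibble(
    age_band = rep(config$age_bands, 2),
    multiplicity = rep(c("singleton", "multiple"), each = nb),
    share = c(p_age * (1 - q_age), p_age * q_age),
    risk = pmin(c(risk_age, risk_age * config$multiple_risk_ratio), 1))
}

shock_for <- function(config, country, year) {
  cs <- config$covid_shock
  if (is.null(cs)) return(1)
  if (is.list(cs)) cs <- cs[[country]]
  if (is.null(cs)) return(1)
  s <- cs[as.character(year)]
  if (is.na(s)) 1 else unname(s)
}

#' Generate a synthetic stratified birth table with ground truth
#'
#' Simulates the registry described by a [synthetic_config()]: births are
#' drawn from the interpolated age-by-multiplicity cross-tabulation
#' (multinomial across cells), stillbirths binomially per cell with
#' probability `age risk x multiplicity risk ratio x shock`, and the
#' cross-tabulation is then marginalised into the two separate axis tables
#' (age-by-multiplicity detail is never released, mirroring real extracts).
#' Missing stratum labels and disclosure suppression are applied per axis
#' afterwards, so the two axes' totals agree exactly before those
#' distortions.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_births` with elements
#'   \describe{
#'     \item{table}{the birth table (both axes, with `"unknown"` rows and
#'       suppressed cells as configured);}
#'     \item{truth}{ground truth: `expected_rates` (per country-year
#'       expected national rate per 1000), `designed_decomposition`
#'       (first-to-last-year composition/rate components per country and
#'       axis computed from the configured expectations),
#'       `shock_years`, and the config itself.}
#'   }
#' @export
generate_births <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("config must come from synthetic_config()",
          class = "sbt_config_error")
  }
  years <- config$years
  span <- if (length(years) > 1) max(years) - min(years) else 1
  country_names <- names(config$countries)

  withr::with_seed(config$seed, {
    rows <- list()
    expected_rates <- list()
    for (ci in seq_along(country_names)) {
      cn <- country_names[ci]
      n_total <- config$countries[[ci]]
      yrs <- years
      if (!is.null(config$first_year) && cn %in% names(config$first_year)) {
        yrs <- yrs[yrs >= config$first_year[[cn]]]
      }
      for (yr in yrs) {
        w <- (yr - min(years)) / span
        shock <- shock_for(config, cn, yr)
        cells <- cross_tab_expectation(config, ci, w, shock)
        if (config$sampling == "expected") {
          births <- n_total * cells$share
          sb <- births * cells$risk
        } else {
          births <- as.double(
            stats::rmultinom(1, size = n_total, prob = cells$share))
          sb <- stats::rbinom(nrow(cells), size = births, prob = cells$risk)
        }
        cells$births <- births
        cells$sb <- sb
        age_tab <- cells |>
          group_by(stratum = .data$age_band) |>
          summarise(stillbirths = sum(.data$sb),
                    live_births = sum(.data$births - .data$sb),
                    .groups = "drop") |>
          mutate(axis = "maternal_age")
        mult_tab <- cells |>
          group_by(stratum = .data$multiplicity) |>
          summarise(stillbirths = sum(.data$sb),
                    live_births = sum(.data$births - .data$sb),
                    .groups = "drop") |>
          mutate(axis = "multiplicity")
        rows[[length(rows) + 1]] <- bind_rows(age_tab, mult_tab) |>
          mutate(country = cn, year = as.integer(yr))
        expected_rates[[length(expected_rates) + 1]] <- tibble(
          country = cn, year = as.integer(yr),
          expected_rate = 1000 * sum(cells$share * cells$risk),
          shock = shock)
      }
    }
    table <- bind_rows(rows) |>
      mutate(suppressed_bound = NA_real_) |>
      select(all_of(c(.sbt_required_cols, "suppressed_bound")))

    table <- inject_missingness(table, config)
    table <- apply_suppression(table, config)
  })

  truth <- list(
    expected_rates = bind_rows(expected_rates),
    designed_decomposition = designed_decomposition(config),
    shock_years = shock_years(config),
    config = config)
  structure(list(table = as_birth_table(table), truth = truth),
            class = "synthetic_births")
}

# Move a fraction of each axis record's counts to the "unknown" stratum,
# independently per axis and outcome (registries lose labels per reporting
# stream). Binomial thinning under binomial sampling; deterministic
# fractions in the expected-count limit.
inject_missingness <- function(table, config) {
  m <- config$missing_frac
  if (m <= 0) return(table)
  if (config$sampling == "expected") {
    moved_sb <- m * table$stillbirths
    moved_lb <- m * table$live_births
  } else {
    moved_sb <- stats::rbinom(nrow(table), table$stillbirths, m)
    moved_lb <- stats::rbinom(nrow(table), table$live_births, m)
  }
  unknown <- table |>
    mutate(stillbirths = moved_sb, live_births = moved_lb,
           stratum = "unknown") |>
    group_by(.data$country, .data$year, .data$axis, .data$stratum) |>
    summarise(stillbirths = sum(.data$stillbirths),
              live_births = sum(.data$live_births), .groups = "drop") |>
    mutate(suppressed_bound = NA_real_)
  table |>
    mutate(stillbirths = .data$stillbirths - moved_sb,
           live_births = .data$live_births - moved_lb) |>
    bind_rows(unknown) |>
    arrange(.data$country, .data$year, .data$axis)
}

# Disclosure control: stillbirth cells below the per-country bound k are
# reported as "< k": count withheld (NA), bound recorded.
apply_suppression <- function(table, config) {
  k <- config$suppress_below[match(table$country,
                                   names(config$countries))]
  hit <- k > 0 & table$stillbirths < k & table$stratum != "unknown"
  table$suppressed_bound[hit] <- k[hit]
  table$stillbirths[hit] <- NA_real_
  table
}

shock_years <- function(config) {
  cs <- config$covid_shock
  if (is.null(cs)) {
    return(tibble(country = character(), year = integer(),
                  shock = numeric()))
  }
  if (!is.list(cs)) {
    cs <- stats::setNames(rep(list(cs), length(config$countries)),
                          names(config$countries))
  }
  purrr::imap_dfr(cs, function(v, cn) {
    tibble(country = cn, year = as.integer(names(v)), shock = unname(v))
  })
}

# Design-side decomposition: the composition and rate components implied by
# the configured expectations between the first and last year, computed
# directly from the config (shares and risks), per country and axis.
designed_decomposition <- function(config) {
  years <- config$years
  purrr::map_dfr(seq_along(config$countries), function(ci) {
    cn <- names(config$countries)[ci]
    yr_a <- min(years)
    if (!is.null(config$first_year) && cn %in% names(config$first_year)) {
      yr_a <- max(yr_a, config$first_year[[cn]])
    }
    span <- if (length(years) > 1) max(years) - min(years) else 1
    w_a <- (yr_a - min(years)) / span
    cells_a <- cross_tab_expectation(config, ci, w_a,
                                     shock_for(config, cn, yr_a))
    cells_b <- cross_tab_expectation(config, ci, 1,
                                     shock_for(config, cn, max(years)))
    purrr::map_dfr(
      c(maternal_age = "age_band", multiplicity = "multiplicity"),
      function(col) {
        marg <- function(cells) {
          cells |>
            group_by(stratum = .data[[col]]) |>
            summarise(rate = 1000 * sum(.data$share * .data$risk) /
                        sum(.data$share),
                      share = sum(.data$share),
                      .groups = "drop")
        }
        a <- marg(cells_a)
        b <- marg(cells_b)
        stopifnot(identical(a$stratum, b$stratum))
        tibble(
          country = cn,
          year_a = as.integer(yr_a), year_b = as.integer(max(years)),
          composition = sum((b$share - a$share) * (a$rate + b$rate) / 2),
          rate_component = sum((b$rate - a$rate) * (a$share + b$share) / 2),
          delta = sum(b$share * b$rate) - sum(a$share * a$rate))
      }, .id = "axis")
  })
}

#' Default multi-country synthetic preset
#'
#' A 24-country registry spanning 2010-2021 with annual totals from 4e3 to
#' 8e5 births (log-spaced), multiple-birth shares between 2.4% and 5.4%
#' mostly declining over time, baseline national stillbirth rates of about
#' 2-5.5 per 1000, a maternal age distribution shifting toward 35+,
#' J-shaped age risk declining at advanced ages, risk ratio 3 for
#' multiples, 3% missing stratum labels, disclosure bound 3 for the three
#' smallest countries, and four countries whose series start 2013-2015.
#'
#' @param seed Integer seed.
#' @param covid_shock Optional shock specification passed through to
#'   [synthetic_config()].
#' @param missing_frac,suppress_small Override the missingness fraction or
#'   disable suppression.
#' @return A `synthetic_config`.
#' @export
synthetic_preset <- function(seed = 1, covid_shock = NULL,
                             missing_frac = 0.03, suppress_small = TRUE) {
  n <- 24
  countries <- stats::setNames(
    round(exp(seq(log(4e3), log(8e5), length.out = n))),
    sprintf("C%02d", seq_len(n)))
  ms_start <- seq(0.024, 0.054, length.out = n)
  ms_end <- ms_start * rep(c(0.82, 0.88, 0.95, 1.03), each = n / 4)
  suppress <- if (suppress_small) c(rep(3, 3), rep(0, n - 3)) else 0
  synthetic_config(
    countries = countries,
    years = 2010:2021,
    age_shares_start = c(0.045, 0.17, 0.28, 0.29, 0.17, 0.045),
    age_shares_end = c(0.02, 0.10, 0.22, 0.32, 0.25, 0.09),
    age_risk_start = c(4.5, 3.2, 3.0, 3.4, 4.4, 6.5) / 1000,
    age_risk_end = c(4.8, 3.2, 2.9, 3.2, 3.7, 5.0) / 1000,
    multiple_share_start = ms_start,
    multiple_share_end = ms_end,
    multiple_risk_ratio = 3,
    risk_scale = seq(0.58, 1.5, length.out = n),
    missing_frac = missing_frac,
    suppress_below = suppress,
    covid_shock = covid_shock,
    first_year = c(C21 = 2013L, C22 = 2013L, C23 = 2014L, C24 = 2015L),
    sampling = "binomial",
    seed = seed)
}
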