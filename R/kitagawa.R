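# Kitagawa two-population decomposition of crude stillbirth-rate
# differences: Delta = sum_i (C_iB - C_iA) * (M_iB + M_iA)/2
#                    + sum_i (M_iB - M_iA) * (C_iB + C_iA)/2
# with C_i the share of total births in stratum i and M_i the stratum
# stillbirth rate per 1000 total births. The first sum is the composition
# component (counterfactual rate change from shifting shares at averaged
# stratum rates), the second the rate component; they add exactly to the
# crude-rate difference.

#' Stratum shares and rates for one population
#'
#' Summarises one (country, year, axis) cell of a repaired birth table into
#' the inputs of the Kitagawa decomposition: each stratum's share of total
#' births and its stillbirth rate per 1000 total births. A stratum with no
#' births enters with share 0 and rate 0 (noted via a message).
#'
#' @param table A repaired birth table.
#' @param country Country identifier.
#' @param year Calendar year.
#' @param axis `"maternal_age"` or `"multiplicity"`.
#' @return A tibble with columns `stratum`, `births`, `stillbirths`,
#'   `share`, `rate`.
#' @export
summarize_population <- function(table, country, year, axis) {
  table <- as_birth_table(table)
  axis <- match.arg(axis, .sbt_axes)
  data <- table |>
    filter(.data$country == !!country, .data$year == !!year,
           .data$axis == !!axis)
  if (nrow(data) == 0) {
    abort(sprintf("No records for country=%s year=%d axis=%s",
                  country, year, axis), class = "sbt_lookup_error")
  }
  if (any(data$stratum == "unknown") || any(!is.na(data$suppressed_bound))) {
    abort("summarize_population() needs a repaired table",
          class = "sbt_validation_error")
  }
  births <- data$stillbirths + data$live_births
  total <- sum(births)
  if (total <= 0) {
    abort(sprintf("Zero total births for country=%s year=%d axis=%s",
                  country, year, axis), class = "sbt_rate_error")
  }
  if (any(births == 0)) {
    inform(paste0("Stratum with zero births gets share 0, rate 0: ",
                  paste(data$stratum[births == 0], collapse = ", ")))
  }
  tibble(
    stratum = data$stratum,
    births = births,
    stillbirths = data$stillbirths,
    share = births / total,
    rate = ifelse(births > 0, 1000 * data$stillbirths / births, 0))
}

# Align two stratum-summary tables on the union of stratum labels. A
# stratum absent on one side enters with share 0 and the rate copied from
# the side where it is defined, so it can only contribute through the
# composition channel while additivity is preserved.
reconcile_strata <- function(pop_a, pop_b) {
  joined <- full_join(
    pop_a |> select("stratum", share_a = "share", rate_a = "rate"),
    pop_b |> select("stratum", share_b = "share", rate_b = "rate"),
    by = "stratum")
  joined |>
    mutate(
      share_a = dplyr::coalesce(.data$share_a, 0),
      share_b = dplyr::coalesce(.data$share_b, 0),
      rate_a = dplyr::coalesce(.data$rate_a, .data$rate_b),
      rate_b = dplyr::coalesce(.data$rate_b, .data$rate_a))
}

#' Kitagawa decomposition of a rate difference
#'
#' Splits the difference between two populations' crude stillbirth rates
#' (B minus A, per 1000 total births) into an exactly additive composition
#' component `sum_i (C_iB - C_iA) (M_iB + M_iA)/2` and rate component
#' `sum_i (M_iB - M_iA) (C_iB + C_iA)/2`, with per-stratum contributions.
#' The composition component is the counterfactual rate change if only the
#' stratum shares differed between the populations; the rate component is
#' the change if only the within-stratum rates differed.
#'
#' @param pop_a,pop_b Stratum summaries (tibbles with `stratum`, `share`,
#'   `rate`; see [summarize_population()]). Strata present on one side only
#'   are entered with share 0 on the absent side and the rate copied from
#'   the present side.
#' @param label_a,label_b Descriptions of the two populations (e.g. years,
#'   or country vs pooled reference) carried into the result.
#' @return An object of class `kitagawa_decomposition`: a list with
#'   `total_difference`, `composition_component`, `rate_component`,
#'   a `per_stratum` tibble of contributions, and `role_labels`.
#' @examples
#' a <- tibble::tibble(stratum = c("s1", "s2"), share = c(0.9, 0.1),
#'                     rate = c(3, 9))
#' b <- tibble::tibble(stratum = c("s1", "s2"), share = c(0.8, 0.2),
#'                     rate = c(3, 9))
#' kitagawa_decompose(a, b) # Delta 0.6, all composition
#' @export
kitagawa_decompose <- function(pop_a, pop_b, label_a = "A", label_b = "B") {
  for (pop in list(pop_a, pop_b)) {
    if (!all(c("stratum", "share", "rate") %in% names(pop))) {
      abort("Populations need columns stratum, share, rate",
            class = "sbt_validation_error")
    }
    if (abs(sum(pop$share) - 1) > 1e-8) {
      abort("Stratum shares must sum to 1", class = "sbt_validation_error")
    }
    if (any(pop$share < 0) || any(pop$rate < 0) || any(pop$rate > 1000)) {
      abort("Shares must be >= 0 and rates in [0, 1000]",
            class = "sbt_validation_error")
    }
    if (anyDuplicated(pop$stratum)) {
      abort("Duplicate stratum labels in a population",
            class = "sbt_validation_error")
    }
  }
  g <- reconcile_strata(pop_a, pop_b)
  per_stratum <- g |>
    mutate(
      composition = (.data$share_b - .data$share_a) *
        (.data$rate_a + .data$rate_b) / 2,
      rate = (.data$rate_b - .data$rate_a) *
        (.data$share_a + .data$share_b) / 2)
  total <- sum(g$share_b * g$rate_b) - sum(g$share_a * g$rate_a)
  structure(
    list(total_difference = total,
         composition_component = sum(per_stratum$composition),
         rate_component = sum(per_stratum$rate),
         per_stratum = per_stratum,
         role_labels = c(A = label_a, B = label_b)),
    class = "kitagawa_decomposition")
}

#' Decompose a country's rate change between two years
#'
#' Kitagawa decomposition with population A the country in `year_a` and
#' population B the same country in `year_b`: a positive composition
#' component means the shift in stratum shares alone (e.g. toward advanced
#' maternal age) would have raised the national rate had stratum rates
#' stayed at their two-year average.
#'
#' @inheritParams summarize_population
#' @param year_a Baseline year; default the country's earliest available
#'   year on this axis (series starting after 2010 are common).
#' @param year_b Comparison year, default 2021.
#' @return A `kitagawa_decomposition` object (see [kitagawa_decompose()]).
#' @export
decompose_over_time <- function(table, country, axis, year_a = NULL,
                                year_b = 2021) {
  table <- as_birth_table(table)
  axis <- match.arg(axis, .sbt_axes)
  avail <- table$year[table$country == country & table$axis == axis]
  if (length(avail) == 0) {
    abort(paste0("Country not found for axis ", axis, ": ", country),
          class = "sbt_lookup_error")
  }
  year_a <- year_a %||% min(avail)
  for (yr in c(year_a, year_b)) {
    if (!yr %in% avail) {
      abort(sprintf("Year %d not available for %s (%s)", yr, country, axis),
            class = "sbt_lookup_error")
    }
  }
  out <- kitagawa_decompose(
    summarize_population(table, country, year_a, axis),
    summarize_population(table, country, year_b, axis),
    label_a = sprintf("%s %d", country, year_a),
    label_b = sprintf("%s %d", country, year_b))
  out$country <- country
  out$axis <- axis
  out$comparison <- "over_time"
  out$year_a <- as.integer(year_a)
  out$year_b <- as.integer(year_b)
  out
}

#' Pooled multi-country reference population
#'
#' Sums stillbirths and births across countries before computing shares and
#' rates, i.e. the birth-weighted pooled average -- not the mean of national
#' rates.
#'
#' @inheritParams summarize_population
#' @param countries Countries to pool; default all countries present for
#'   this axis. Every listed country must have the requested year.
#' @return A stratum-summary tibble as from [summarize_population()].
#' @export
pooled_reference <- function(table, year, axis, countries = NULL) {
  table <- as_birth_table(table)
  axis <- match.arg(axis, .sbt_axes)
  data <- table |> filter(.data$axis == !!axis)
  countries <- countries %||% sort(unique(data$country))
  have_year <- data |>
    filter(.data$year == !!year) |>
    dplyr::pull(.data$country) |>
    unique()
  missing_countries <- setdiff(countries, have_year)
  if (length(missing_countries) > 0) {
    abort(paste0("Year ", year, " missing for: ",
                 paste(missing_countries, collapse = ", ")),
          class = "sbt_lookup_error")
  }
  pooled <- data |>
    filter(.data$year == !!year, .data$country %in% countries) |>
    group_by(.data$stratum) |>
    summarise(stillbirths = sum(.data$stillbirths),
              live_births = sum(.data$live_births), .groups = "drop") |>
    mutate(country = "pooled", year = as.integer(!!year), axis = !!axis,
           suppressed_bound = NA_real_)
  summarize_population(pooled, "pooled", year, axis)
}

#' Decompose a country's gap to the pooled reference
#'
#' Kitagawa decomposition with population A the country and population B
#' the pooled reference in the same year, so a positive total difference
#' means the reference rate exceeds the country's. The country-minus-average
#' difference (the sign convention of "above/below average" reporting) is
#' carried as `country_minus_reference`, the negation of the total.
#'
#' @inheritParams pooled_reference
#' @param country Country to compare.
#' @param exclude_self Drop the country from the pooled reference
#'   (default `FALSE`: the country stays inside the pool).
#' @return A `kitagawa_decomposition` object with the extra field
#'   `country_minus_reference`.
#' @export
decompose_vs_reference <- function(table, country, axis, year = 2021,
                                   countries = NULL, exclude_self = FALSE) {
  table <- as_birth_table(table)
  axis <- match.arg(axis, .sbt_axes)
  countries <- countries %||%
    sort(unique(table$country[table$axis == axis]))
  pool <- if (exclude_self) setdiff(countries, country) else countries
  out <- kitagawa_decompose(
    summarize_population(table, country, year, axis),
    pooled_reference(table, year, axis, countries = pool),
    label_a = sprintf("%s %d", country, year),
    label_b = sprintf("pooled reference %d", year))
  out$country <- country
  out$axis <- axis
  out$comparison <- "vs_reference"
  out$year_a <- as.integer(year)
  out$year_b <- as.integer(year)
  out$country_minus_reference <- -out$total_difference
  out
}

#' @export
print.kitagawa_decomposition <- function(x, ...) {
  cat(sprintf("Kitagawa decomposition: %s -> %s\n",
              x$role_labels["A"], x$role_labels["B"]))
  cat(sprintf("  total difference: %+.4f per 1000\n", x$total_difference))
  cat(sprintf("  composition:      %+.4f\n", x$composition_component))
  cat(sprintf("  rate:             %+.4f\n", x$rate_component))
  invisible(x)
}

#' Tidy a Kitagawa decomposition
#'
#' One row per stratum with its shares, rates and contributions to the two
#' components.
#'
#' @param x A `kitagawa_decomposition` object.
#' @param ... Unused.
#' @return A tibble with columns `stratum`, `share_a`, `share_b`, `rate_a`,
#'   `rate_b`, `composition`, `rate`.
#' @export
tidy.kitagawa_decomposition <- function(x, ...) {
  x$per_stratum
}

#' Glance at a Kitagawa decomposition
#'
#' @inheritParams tidy.kitagawa_decomposition
#' @return A one-row tibble with the total difference and the two
#'   components.
#' @export
glance.kitagawa_decomposition <- function(x, ...) {
  tibble(
    country = x$country %||% NA_character_,
    axis = x$axis %||% NA_character_,
    comparison = x$comparison %||% NA_character_,
    year_a = x$year_a %||% NA_integer_,
    year_b = x$year_b %||% NA_integer_,
    delta = x$total_difference,
    composition = x$composition_component,
    rate_component = x$rate_component)
}

#' Plot a Kitagawa decomposition
#'
#' Bars for the total rate difference and its composition and rate
#' components, with per-stratum contributions stacked.
#'
#' @param object A `kitagawa_decomposition` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kitagawa_decomposition <- function(object, ...) {
  parts <- object$per_stratum |>
    tidyr::pivot_longer(c("composition", "rate"), names_to = "component",
                        values_to = "contribution")
  ggplot2::ggplot(parts,
                  ggplot2::aes(x = .data$component, y = .data$contribution,
                               fill = .data$stratum)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$total_difference,
                        linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = "Contribution to rate difference (per 1000)",
      title = sprintf("%s → %s", object$role_labels["A"],
                      object$role_labels["B"]),
      caption = "dashed line: total rate difference") +
    ggplot2::theme_minimal()
}
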