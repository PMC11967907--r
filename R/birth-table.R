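#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr group_by ungroup summarise mutate filter select arrange
#'   across bind_rows left_join full_join distinct n rename all_of
#' @importFrom tibble tibble as_tibble
NULL

# Canonical column set for stratified birth-count tables. `suppressed_bound`
# is optional on disk; internally it is always present (NA = not suppressed).
.sbt_required_cols <- c("country", "year", "axis", "stratum",
                        "stillbirths", "live_births")
.sbt_axes <- c("maternal_age", "multiplicity")

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Canonical maternal age bands
#'
#' Default closed-open age bands on completed years of maternal age at birth.
#' The bands are configurable throughout the package; these labels are the
#' convention used by the synthetic generator and the examples.
#'
#' @return Character vector of band labels.
#' @export
age_bands_default <- function() {
  c("<20", "20-24", "25-29", "30-34", "35-39", "40+")
}

#' Coerce and validate a stratified birth-count table
#'
#' A birth table is a long-format tibble with one row per
#' (country, year, axis, stratum) holding counts of stillbirths and live
#' births. `axis` is either `"maternal_age"` or `"multiplicity"`; the stratum
#' label `"unknown"` marks births whose stratum was not recorded and is
#' removed by [redistribute_unknown()]. Cells suppressed for disclosure
#' control carry their bound `k` in `suppressed_bound` (true count in
#' `0..k-1`) and `NA` in the suppressed count column until
#' [impute_suppressed()] fills them.
#'
#' @param data A data frame with columns `country`, `year`, `axis`,
#'   `stratum`, `stillbirths`, `live_births` and optionally
#'   `suppressed_bound`.
#' @return A validated tibble with the canonical columns, `suppressed_bound`
#'   included.
#' @seealso [read_birth_table()], [validate_birth_table()]
#' @export
as_birth_table <- function(data) {
  data <- as_tibble(data)
  missing_cols <- setdiff(.sbt_required_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "sbt_schema_error")
  }
  if (!"suppressed_bound" %in% names(data)) {
    data$suppressed_bound <- NA_real_
  }
  if ("suppressed" %in% names(data)) {
    flagged <- isTRUE_vec(data$suppressed)
    if (any(flagged & is.na(data$suppressed_bound))) {
      abort("Suppressed cell without a disclosure bound",
            class = "sbt_config_error")
    }
    data$suppressed <- NULL
  }
  data <- data |>
    mutate(
      country = as.character(.data$country),
      year = as.integer(.data$year),
      axis = as.character(.data$axis),
      stratum = as.character(.data$stratum),
      stillbirths = as.double(.data$stillbirths),
      live_births = as.double(.data$live_births),
      suppressed_bound = as.double(.data$suppressed_bound)
    ) |>
    select(all_of(c(.sbt_required_cols, "suppressed_bound")))
  validate_birth_table(data)
}

#' Validate a birth table
#'
#' Checks the structural invariants of a stratified birth-count table:
#' recognised axis labels, non-negative counts (missing counts allowed only
#' in suppressed cells), and uniqueness of the
#' (country, year, axis, stratum) key. Errors name the offending rows.
#'
#' @param table A birth table (see [as_birth_table()]).
#' @return The table, invisibly coerced to a tibble, if valid.
#' @export
validate_birth_table <- function(table) {
  table <- as_tibble(table)
  bad_axis <- setdiff(unique(table$axis), .sbt_axes)
  if (length(bad_axis) > 0) {
    abort(paste0("Unrecognised axis label(s): ",
                 paste(bad_axis, collapse = ", "),
                 ". Expected one of: ", paste(.sbt_axes, collapse = ", ")),
          class = "sbt_validation_error")
  }
  suppressed <- !is.na(table$suppressed_bound)
  if (any(suppressed & table$suppressed_bound < 1)) {
    abort("suppressed_bound must be a positive integer (true count in 0..k-1)",
          class = "sbt_validation_error")
  }
  for (col in c("stillbirths", "live_births")) {
    vals <- table[[col]]
    missing_ok <- suppressed & col == "stillbirths"
    if (any(is.na(vals) & !missing_ok)) {
      abort(paste0("NA in ", col, " outside suppressed cells (rows ",
                   paste(utils::head(which(is.na(vals) & !missing_ok), 5),
                         collapse = ", "), ")"),
            class = "sbt_validation_error")
    }
    neg <- !is.na(vals) & vals < 0
    if (any(neg)) {
      offending <- table[which(neg)[1], ]
      abort(sprintf(
        "Negative %s for country=%s year=%d axis=%s stratum=%s",
        col, offending$country, offending$year, offending$axis,
        offending$stratum), class = "sbt_validation_error")
    }
  }
  dup <- table |>
    dplyr::count(.data$country, .data$year, .data$axis, .data$stratum) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "Duplicate (country, year, axis, stratum) key: %s %d %s %s",
      dup$country[1], dup$year[1], dup$axis[1], dup$stratum[1]),
      class = "sbt_validation_error")
  }
  invisible(table)
}

#' Read a stratified birth-count table from CSV
#'
#' Reads a delimited text file with one row per
#' (country, year, axis, stratum) and validates it. Column names can be
#' remapped with `col_map` when the file uses different headers.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter, default `","`.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(stillbirths = "sb_count")`.
#' @return A validated birth table tibble.
#' @export
read_birth_table <- function(path, delim = ",", col_map = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "sbt_schema_error")
  }
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  if (!is.null(col_map)) {
    for (canonical in names(col_map)) {
      if (col_map[[canonical]] %in% names(data)) {
        names(data)[names(data) == col_map[[canonical]]] <- canonical
      }
    }
  }
  as_birth_table(data)
}

#' Write a birth table to CSV
#'
#' Writes the canonical schema (`country`, `year`, `axis`, `stratum`,
#' `stillbirths`, `live_births`, `suppressed_bound`) so that
#' `read_birth_table()` round-trips the file.
#'
#' @param table A birth table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_birth_table <- function(table, path) {
  table <- as_birth_table(table)
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Validation report for a birth table
#'
#' Summarises the state of a table before or after repair: row counts,
#' unknown-stratum and suppressed-cell counts, the per-country year span,
#' and whether the age-axis and multiplicity-axis totals agree.
#'
#' @param table A birth table.
#' @param tolerance Relative tolerance for the cross-axis total comparison.
#' @return A list suitable for serialisation as JSON.
#' @export
birth_table_report <- function(table, tolerance = 1e-6) {
  table <- as_birth_table(table)
  spans <- if (nrow(table) > 0) {
    table |>
      group_by(.data$country) |>
      summarise(first_year = min(.data$year), last_year = max(.data$year),
                .groups = "drop")
  } else {
    tibble(country = character(), first_year = integer(),
           last_year = integer())
  }
  totals <- table |>
    filter(.data$stratum != "unknown", is.na(.data$suppressed_bound)) |>
    group_by(.data$country, .data$year, .data$axis) |>
    summarise(total = sum(.data$stillbirths + .data$live_births),
              .groups = "drop") |>
    tidyr::pivot_wider(names_from = "axis", values_from = "total")
  axis_mismatch <- 0L
  if (all(.sbt_axes %in% names(totals))) {
    both <- totals |>
      filter(!is.na(.data$maternal_age), !is.na(.data$multiplicity))
    axis_mismatch <- sum(
      abs(both$maternal_age - both$multiplicity) >
        tolerance * pmax(both$maternal_age, 1))
  }
  list(
    n_records = nrow(table),
    n_countries = dplyr::n_distinct(table$country),
    year_range = if (nrow(table) > 0) range(table$year) else integer(),
    n_unknown_cells = sum(table$stratum == "unknown"),
    n_suppressed_cells = sum(!is.na(table$suppressed_bound)),
    n_axis_total_mismatches = axis_mismatch,
    country_spans = spans
  )
}

#' Redistribute unknown-stratum counts proportionally
#'
#' Births whose stratum label was not recorded appear under the stratum
#' `"unknown"`. Assuming the missingness is unrelated to the stratum, the
#' unknown counts are allocated to the known strata in proportion to each
#' stratum's share of the known total -- separately for stillbirths and
#' live births within each (country, year, axis). Totals are conserved and
#' the resulting counts may be fractional; no rounding is applied, which
#' keeps the allocation unbiased. `"unknown"` rows are removed.
#'
#' @param table A birth table with no remaining suppressed cells.
#' @param unknown_label Stratum label marking unrecorded strata.
#' @return The repaired birth table.
#' @export
redistribute_unknown <- function(table, unknown_label = "unknown") {
  table <- as_birth_table(table)
  if (any(!is.na(table$suppressed_bound))) {
    abort("Impute suppressed cells (impute_suppressed()) before redistribution",
          class = "sbt_validation_error")
  }
  is_unknown <- table$stratum == unknown_label
  if (!any(is_unknown)) {
    return(table)
  }
  unknown <- table |>
    filter(.data$stratum == unknown_label) |>
    select("country", "year", "axis",
           unknown_sb = "stillbirths", unknown_lb = "live_births")
  known <- table |>
    filter(.data$stratum != unknown_label) |>
    left_join(unknown, by = c("country", "year", "axis")) |>
    mutate(unknown_sb = dplyr::coalesce(.data$unknown_sb, 0),
           unknown_lb = dplyr::coalesce(.data$unknown_lb, 0)) |>
    group_by(.data$country, .data$year, .data$axis) |>
    mutate(known_sb = sum(.data$stillbirths),
           known_lb = sum(.data$live_births)) |>
    ungroup()
  bad_sb <- known$unknown_sb > 0 & known$known_sb <= 0
  bad_lb <- known$unknown_lb > 0 & known$known_lb <= 0
  if (any(bad_sb) || any(bad_lb)) {
    offending <- known[which(bad_sb | bad_lb)[1], ]
    abort(sprintf(
      "Unresolvable missingness: unknown %s with zero known total for country=%s year=%d axis=%s",
      if (any(bad_sb)) "stillbirths" else "live births",
      offending$country, offending$year, offending$axis),
      class = "sbt_missingness_error")
  }
  known |>
    mutate(
      stillbirths = .data$stillbirths +
        ifelse(.data$known_sb > 0,
               .data$unknown_sb * .data$stillbirths / .data$known_sb, 0),
      live_births = .data$live_births +
        ifelse(.data$known_lb > 0,
               .data$unknown_lb * .data$live_births / .data$known_lb, 0)
    ) |>
    select(all_of(c(.sbt_required_cols, "suppressed_bound")))
}

#' Impute disclosure-suppressed cells
#'
#' Registries report very small stillbirth counts as "< k" rather than
#' exactly. Each suppressed cell is replaced by an integer drawn uniformly
#' from `{0, ..., k - 1}` (the maximum-entropy choice given only the bound),
#' using a seeded generator so that runs are reproducible. The suppression
#' marker is cleared.
#'
#' @param table A birth table; suppressed cells have their bound `k` in
#'   `suppressed_bound` and `NA` stillbirths.
#' @param seed Integer seed for the draws (mandatory).
#' @return The table with suppressed stillbirth counts imputed.
#' @export
impute_suppressed <- function(table, seed) {
  table <- as_birth_table(table)
  if (missing(seed) || is.null(seed)) {
    abort("impute_suppressed() requires a seed", class = "sbt_config_error")
  }
  suppressed <- !is.na(table$suppressed_bound)
  if (!any(suppressed)) {
    return(table)
  }
  if (any(is.na(table$stillbirths[suppressed]) &
          is.na(table$suppressed_bound[suppressed]))) {
    abort("Suppressed cell without a disclosure bound",
          class = "sbt_config_error")
  }
  k <- table$suppressed_bound[suppressed]
  draws <- withr::with_seed(as.integer(seed), {
    floor(stats::runif(length(k)) * k)  # uniform on {0, ..., k-1}
  })
  table$stillbirths[suppressed] <- draws
  table$suppressed_bound[suppressed] <- NA_real_
  table
}

#' Repair a birth table
#'
#' Convenience wrapper running the two repair steps in order: seeded
#' imputation of suppressed cells, then proportional redistribution of
#' unknown-stratum counts.
#'
#' @inheritParams impute_suppressed
#' @inheritParams redistribute_unknown
#' @return The repaired birth table (no suppressed cells, no unknown rows).
#' @export
repair_birth_table <- function(table, seed, unknown_label = "unknown") {
  table |>
    impute_suppressed(seed = seed) |>
    redistribute_unknown(unknown_label = unknown_label)
}

#' Stillbirth rate per 1000 total births
#'
#' The denominator is total births (stillbirths + live births), the
#' convention for stillbirth rates in perinatal surveillance.
#'
#' @param stillbirths,live_births Non-negative counts (vectorised; may be
#'   fractional after redistribution).
#' @return Rate(s) per 1000 total births.
#' @examples
#' compute_rate(5, 995) # 5.0
#' @export
compute_rate <- function(stillbirths, live_births) {
  total <- stillbirths + live_births
  if (any(is.na(total)) || any(total <= 0)) {
    abort("Rate undefined: zero total births", class = "sbt_rate_error")
  }
  if (any(stillbirths < 0) || any(live_births < 0)) {
    abort("Counts must be non-negative", class = "sbt_validation_error")
  }
  1000 * stillbirths / total
}

#' Annual national stillbirth-rate series
#'
#' Pools stratum counts within each (country, year) of the chosen axis and
#' computes the rate per 1000 total births. The table must be repaired
#' (no unknown strata, no suppressed cells) so that the pooled counts are
#' complete. Years are restricted to each country's available span; series
#' starting after 2010 are legal.
#'
#' @param table A repaired birth table.
#' @param country Country identifier, or `NULL` for all countries.
#' @param axis `"maternal_age"` or `"multiplicity"`.
#' @return A tibble with columns `country`, `year`, `stillbirths`,
#'   `live_births`, `total_births`, `rate`, ordered by country and year.
#' @export
rate_series <- function(table, country = NULL, axis = "maternal_age") {
  table <- as_birth_table(table)
  axis <- match.arg(axis, .sbt_axes)
  if (any(table$stratum == "unknown") || any(!is.na(table$suppressed_bound))) {
    abort("rate_series() needs a repaired table (see repair_birth_table())",
          class = "sbt_validation_error")
  }
  data <- table |> filter(.data$axis == !!axis)
  if (!is.null(country)) {
    if (!country %in% data$country) {
      abort(paste0("Country not found for axis ", axis, ": ", country),
            class = "sbt_lookup_error")
    }
    data <- data |> filter(.data$country == !!country)
  }
  data |>
    group_by(.data$country, .data$year) |>
    summarise(stillbirths = sum(.data$stillbirths),
              live_births = sum(.data$live_births), .groups = "drop") |>
    mutate(total_births = .data$stillbirths + .data$live_births,
           rate = compute_rate(.data$stillbirths, .data$live_births)) |>
    arrange(.data$country, .data$year)
}
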