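# Orchestration: repair -> rates -> trends -> anomalies -> decompositions,
# emitting the surveillance report tables (per-country trend
# classification, composition of births, over-time and vs-reference
# decompositions, anomaly z-scores) plus a machine-readable run manifest.

#' Run the full surveillance pipeline
#'
#' Repairs the input table (seeded imputation of suppressed cells,
#' proportional redistribution of unknown strata), computes national rate
#' series, runs the trend battery (autocorrelation-corrected Mann-Kendall,
#' linear/segmented slopes) and anomaly detection per country, and performs
#' Kitagawa decompositions over time and against the pooled reference for
#' each requested axis. Failures in one country are recorded and the run
#' continues for the others.
#'
#' @param input A birth table data frame, a path to a birth-table CSV, a
#'   [synthetic_config()], or the result of [generate_births()].
#' @param axes Stratification axes to decompose (default both).
#' @param year_b Comparison year for decompositions (default 2021).
#' @param year_a Baseline year for the over-time decomposition; default
#'   each country's earliest available year.
#' @param alpha Significance level for the slope-change test.
#' @param anomaly_years Years tested for anomalously high rates.
#' @param threshold Robust z-score flagging threshold.
#' @param min_segment Minimum observations per segmented-regression regime.
#' @param seed Seed for suppressed-cell imputation.
#' @param out_dir Optional directory; when given, all tables are written as
#'   CSV plus a `run_manifest.json` echoing the configuration. Outputs are
#'   deterministic given the input and seed.
#' @return Invisibly, a list of class `sbt_run`: `trends`, `anomalies`,
#'   `rates`, `composition`, `decomposition_over_time`,
#'   `decomposition_vs_reference`, `report`, `errors` (per-country failure
#'   records) and `status` (0 = success, 3 = partial failure).
#' @export
run_pipeline <- function(input,
                         axes = c("maternal_age", "multiplicity"),
                         year_b = 2021, year_a = NULL,
                         alpha = 0.05,
                         anomaly_years = c(2020L, 2021L), threshold = 2,
                         min_segment = 3, seed = 1, out_dir = NULL) {
  axes <- match.arg(axes, .sbt_axes, several.ok = TRUE)
  if (inherits(input, "synthetic_config")) {
    input <- generate_births(input)
  }
  if (inherits(input, "synthetic_births")) {
    raw <- input$table
  } else if (is.character(input) && length(input) == 1) {
    raw <- read_birth_table(input)
  } else {
    raw <- as_birth_table(input)
  }
  report <- birth_table_report(raw)
  repaired <- repair_birth_table(raw, seed = seed)
  countries <- sort(unique(repaired$country))
  errors <- list()
  note <- function(country, stage, e) {
    errors[[length(errors) + 1]] <<- tibble(
      country = country, stage = stage, message = conditionMessage(e))
    NULL
  }

  if (length(countries) == 0) {
    rlang::warn("Input table contains no countries; emitting empty tables")
  }

  rate_axis <- axes[1]
  rates <- if (length(countries) > 0) {
    rate_series(repaired, axis = rate_axis)
  } else {
    tibble(country = character(), year = integer(),
           stillbirths = numeric(), live_births = numeric(),
           total_births = numeric(), rate = numeric())
  }

  trends <- purrr::map_dfr(countries, function(cn) {
    tryCatch({
      series <- rates |> filter(.data$country == cn)
      mk <- mk_test(series)
      fit <- fit_segmented(series, alpha = alpha, min_segment = min_segment)
      direction <- if (fit$fitted$fit[nrow(fit$fitted)] >=
                         fit$fitted$fit[1]) "increase" else "decrease"
      dplyr::bind_cols(
        tibble(country = cn, n_years = nrow(series)),
        tidy.mk_test(mk) |> select(mk_S = "S", mk_p = "p.value",
                                   mk_stars = "stars",
                                   n_eff_ratio = "n_eff_ratio"),
        glance.trend_fit(fit) |> select(-"country"),
        tibble(trend_class = paste(fit$kind, direction, sep = "_")))
    }, error = function(e) note(cn, "trends", e))
  })

  anomalies <- purrr::map_dfr(countries, function(cn) {
    tryCatch({
      robust_anomaly(rates |> filter(.data$country == cn),
                     target_years = anomaly_years, threshold = threshold) |>
        as_tibble()
    }, error = function(e) note(cn, "anomalies", e))
  })

  composition <- repaired |>
    filter(.data$axis %in% axes) |>
    group_by(.data$country, .data$year, .data$axis) |>
    mutate(share = (.data$stillbirths + .data$live_births) /
             sum(.data$stillbirths + .data$live_births)) |>
    ungroup() |>
    select("country", "year", "axis", "stratum", "share")

  decomp_rows <- function(decomp) {
    glance.kitagawa_decomposition(decomp) |>
      dplyr::cross_join(
        decomp$per_stratum |>
          select("stratum", stratum_composition = "composition",
                 stratum_rate = "rate"))
  }
  decomp_time <- purrr::map_dfr(countries, function(cn) {
    purrr::map_dfr(axes, function(ax) {
      tryCatch(
        decomp_rows(decompose_over_time(repaired, cn, ax,
                                        year_a = year_a, year_b = year_b)),
        error = function(e) note(cn, paste0("decompose_over_time_", ax), e))
    })
  })
  decomp_ref <- purrr::map_dfr(countries, function(cn) {
    purrr::map_dfr(axes, function(ax) {
      tryCatch({
        d <- decompose_vs_reference(repaired, cn, ax, year = year_b)
        decomp_rows(d) |>
          mutate(country_minus_reference = d$country_minus_reference)
      }, error = function(e) note(cn, paste0("decompose_vs_reference_", ax), e))
    })
  })

  errors <- if (length(errors) > 0) bind_rows(errors) else
    tibble(country = character(), stage = character(), message = character())
  result <- structure(
    list(trends = trends, anomalies = anomalies, rates = rates,
         composition = composition,
         decomposition_over_time = decomp_time,
         decomposition_vs_reference = decomp_ref,
         repaired = repaired, report = report, errors = errors,
         status = if (nrow(errors) > 0) 3L else 0L,
         config = list(axes = axes, year_a = year_a, year_b = year_b,
                       alpha = alpha, anomaly_years = anomaly_years,
                       threshold = threshold, min_segment = min_segment,
                       seed = seed)),
    class = "sbt_run")

  if (!is.null(out_dir)) {
    write_run_bundle(result, out_dir)
  }
  invisible(result)
}

# Write the report bundle: one CSV per table plus a JSON manifest echoing
# the configuration and validation report. Deterministic given the run.
write_run_bundle <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("trends", "anomalies", "rates", "composition",
              "decomposition_over_time", "decomposition_vs_reference",
              "repaired", "errors")
  for (nm in tables) {
    readr::write_csv(run[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     progress = FALSE)
  }
  manifest <- list(config = run$config, status = run$status,
                   validation = run$report[c(
                     "n_records", "n_countries", "year_range",
                     "n_unknown_cells", "n_suppressed_cells",
                     "n_axis_total_mismatches")])
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_pipeline()] (`input`, `axes`,
#' `year_a`, `year_b`, `alpha`, `anomaly_years`, `threshold`,
#' `min_segment`, `seed`, `out_dir`); call-site arguments override file
#' values.
#'
#' @param path Path to a YAML file.
#' @param ... Overrides for individual keys.
#' @return A named list of arguments for [run_pipeline()].
#' @export
load_run_config <- function(path, ...) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path),
          class = "sbt_config_error")
  }
  config <- yaml::read_yaml(path)
  overrides <- list(...)
  config[names(overrides)] <- overrides
  known <- c("input", "axes", "year_a", "year_b", "alpha", "anomaly_years",
             "threshold", "min_segment", "seed", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "sbt_config_error")
  }
  config
}

#' @export
print.sbt_run <- function(x, ...) {
  cat("Stillbirth surveillance run\n")
  cat(sprintf("  countries: %d, status: %d (%s)\n",
              dplyr::n_distinct(x$rates$country), x$status,
              if (x$status == 0) "success" else "partial failure"))
  cat(sprintf("  trends: %d rows; anomalies: %d rows; decompositions: %d + %d rows\n",
              nrow(x$trends), nrow(x$anomalies),
              nrow(x$decomposition_over_time),
              nrow(x$decomposition_vs_reference)))
  if (nrow(x$errors) > 0) {
    cat("  failures:\n")
    print(x$errors)
  }
  invisible(x)
}

#' Plot national rate series with trend classification
#'
#' Small-multiple panels of annual rates per country, coloured by the
#' fitted trend kind (linear vs segmented).
#'
#' @param run An `sbt_run` object.
#' @return A ggplot object.
#' @export
plot_rate_trends <- function(run) {
  data <- run$rates |>
    left_join(run$trends |> select("country", "kind", "trend_class"),
              by = "country")
  ggplot2::ggplot(data, ggplot2::aes(x = .data$year, y = .data$rate)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_smooth(ggplot2::aes(colour = .data$kind),
                         method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~country, scales = "free_y") +
    ggplot2::labs(x = "Year", y = "Stillbirths per 1000 births",
                  colour = "Trend fit") +
    ggplot2::theme_minimal()
}

#' Arrow-style decomposition table plot
#'
#' Displays each country's total rate difference with its composition and
#' rate components, one bar pair per country, in the spirit of
#' arrow-decomposition charts.
#'
#' @param decomp A decomposition table from [run_pipeline()]
#'   (`decomposition_over_time` or `decomposition_vs_reference`).
#' @param axis Which stratification axis to show.
#' @return A ggplot object.
#' @export
plot_decomposition <- function(decomp, axis = "maternal_age") {
  data <- decomp |>
    filter(.data$axis == !!axis) |>
    distinct(.data$country, .data$delta, .data$composition,
             .data$rate_component) |>
    tidyr::pivot_longer(c("composition", "rate_component"),
                        names_to = "component", values_to = "value")
  ggplot2::ggplot(data, ggplot2::aes(y = .data$country)) +
    ggplot2::geom_col(ggplot2::aes(x = .data$value, fill = .data$component),
                      position = "dodge") +
    ggplot2::geom_point(ggplot2::aes(x = .data$delta)) +
    ggplot2::labs(x = "Rate difference (per 1000)", y = NULL,
                  fill = "Component",
                  caption = "points: total rate difference") +
    ggplot2::theme_minimal()
}
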