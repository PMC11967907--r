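test_that("reading a CSV returns the validated records", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tiny_table(), path)
  table <- read_birth_table(path)
  expect_equal(nrow(table), 6)
  expect_setequal(unique(table$country), c("AA", "BB"))
  expect_true(all(is.na(table$suppressed_bound)))
})

test_that("schema and validation errors are raised with context", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(tiny_table(), -stillbirths), path)
  expect_error(read_birth_table(path), class = "sbt_schema_error")
  expect_error(read_birth_table(tempfile()), class = "sbt_schema_error")

  dup <- dplyr::bind_rows(tiny_table(), tiny_table()[1, ])
  expect_error(as_birth_table(dup), class = "sbt_validation_error",
               regexp = "Duplicate")

  neg <- tiny_table()
  neg$live_births[3] <- -1
  expect_error(as_birth_table(neg), class = "sbt_validation_error",
               regexp = "Negative")

  bad_axis <- tiny_table()
  bad_axis$axis[1] <- "gestational_age"
  expect_error(as_birth_table(bad_axis), class = "sbt_validation_error")
})

test_that("column remapping handles nonstandard headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  renamed <- dplyr::rename(tiny_table(), sb = stillbirths, lb = live_births)
  readr::write_csv(renamed, path)
  table <- read_birth_table(path,
                            col_map = c(stillbirths = "sb",
                                        live_births = "lb"))
  expect_equal(table$stillbirths, tiny_table()$stillbirths)
})

test_that("unknown counts are redistributed proportionally", {
  table <- tibble::tribble(
    ~country, ~year, ~axis, ~stratum, ~stillbirths, ~live_births,
    "AA", 2010L, "maternal_age", "a", 30, 45,
    "AA", 2010L, "maternal_age", "b", 60, 45,
    "AA", 2010L, "maternal_age", "unknown", 9, 10)
  out <- redistribute_unknown(as_birth_table(table))
  expect_equal(nrow(out), 2)
  expect_equal(sort(out$stillbirths), c(33, 66))   # 1:2 split of 9
  expect_equal(sort(out$live_births), c(50, 50))   # equal split of 10
})

test_that("redistribution is an identity without unknown rows", {
  table <- as_birth_table(tiny_table())
  expect_equal(redistribute_unknown(table), table)
})

test_that("redistribution conserves totals and known-stratum proportions", {
  set.seed(41)
  for (rep in 1:20) {
    n_strata <- sample(2:6, 1)
    known_sb <- rpois(n_strata, 20)
    known_sb[1] <- known_sb[1] + 1  # known total > 0
    known_lb <- rpois(n_strata, 5000) + 1
    table <- tibble::tibble(
      country = "AA", year = 2010L, axis = "maternal_age",
      stratum = c(paste0("s", seq_len(n_strata)), "unknown"),
      stillbirths = c(known_sb, rpois(1, 10)),
      live_births = c(known_lb, rpois(1, 500)))
    out <- redistribute_unknown(as_birth_table(table))
    expect_equal(sum(out$stillbirths), sum(table$stillbirths))
    expect_equal(sum(out$live_births), sum(table$live_births))
    # shares among known strata unchanged
    expect_equal(out$stillbirths / sum(out$stillbirths),
                 known_sb / sum(known_sb))
    expect_equal(out$live_births / sum(out$live_births),
                 known_lb / sum(known_lb))
  }
})

test_that("unknown counts with no known stratum are unresolvable", {
  table <- tibble::tibble(
    country = "AA", year = 2010L, axis = "maternal_age",
    stratum = c("a", "unknown"),
    stillbirths = c(0, 3), live_births = c(100, 10))
  expect_error(redistribute_unknown(as_birth_table(table)),
               class = "sbt_missingness_error")
})

test_that("suppressed cells are imputed uniformly below the bound, seeded", {
  table <- tiny_table()
  table$suppressed_bound <- c(3, NA, NA, NA, 5, NA)
  table$stillbirths[c(1, 5)] <- NA
  table <- as_birth_table(table)

  out1 <- impute_suppressed(table, seed = 9)
  out2 <- impute_suppressed(table, seed = 9)
  expect_identical(out1, out2)
  expect_true(all(is.na(out1$suppressed_bound)))
  expect_true(all(out1$stillbirths[c(1, 5)] >= 0))
  expect_true(out1$stillbirths[1] < 3)
  expect_true(out1$stillbirths[5] < 5)
  expect_true(out1$stillbirths[1] == floor(out1$stillbirths[1]))

  # bound 1 forces zero
  forced <- table
  forced$suppressed_bound[c(1, 5)] <- 1
  expect_equal(impute_suppressed(forced, seed = 1)$stillbirths[c(1, 5)],
               c(0, 0))

  # identity without suppression, seed still required
  plain <- as_birth_table(tiny_table())
  expect_equal(impute_suppressed(plain, seed = 1), plain)
  expect_error(impute_suppressed(plain), class = "sbt_config_error")

  # suppressed flag without a bound is a configuration error
  flagged <- tiny_table()
  flagged$suppressed <- c(TRUE, rep(FALSE, 5))
  expect_error(as_birth_table(flagged), class = "sbt_config_error")
})

test_that("rates are stillbirths per 1000 total births", {
  expect_equal(compute_rate(5, 995), 5)
  expect_equal(compute_rate(0, 1000), 0)
  expect_equal(compute_rate(3, 997), 3)
  expect_equal(compute_rate(c(5, 0), c(995, 1000)), c(5, 0))
  expect_error(compute_rate(0, 0), class = "sbt_rate_error")
})

test_that("rate series pools strata and respects country spans", {
  series <- rate_series(as_birth_table(tiny_table()), "AA")
  expect_equal(series$year, c(2010L, 2021L))
  expect_equal(series$rate[1], compute_rate(20, 1980))
  expect_equal(series$rate[2], compute_rate(17, 1983))
  # pooled rate: (5 of 1000) + (15 of 1000) -> 10 per 1000
  expect_equal(series$rate[1], 10)
  # pooled rate lies between stratum rates
  strata <- dplyr::filter(tiny_table(), country == "AA", year == 2010)
  stratum_rates <- compute_rate(strata$stillbirths, strata$live_births)
  expect_gte(series$rate[1], min(stratum_rates))
  expect_lte(series$rate[1], max(stratum_rates))

  expect_error(rate_series(as_birth_table(tiny_table()), "ZZ"),
               class = "sbt_lookup_error")
})

test_that("national rates agree across stratification axes", {
  g <- generate_births(small_config(seed = 3, years = 2010:2013))
  age <- rate_series(g$table, "X", axis = "maternal_age")
  mult <- rate_series(g$table, "X", axis = "multiplicity")
  expect_equal(age$rate, mult$rate, tolerance = 1e-12)
})

test_that("repaired tables round-trip through CSV bit-identically", {
  g <- generate_births(small_config(seed = 5, n = 2e4,
                                    missing_frac = 0.05))
  repaired <- repair_birth_table(g$table, seed = 2)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_birth_table(repaired, p1)
  write_birth_table(read_birth_table(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the validation report summarises repair state", {
  g <- generate_births(small_config(seed = 5, n = 2e4, missing_frac = 0.05,
                                    suppress_below = 3))
  before <- birth_table_report(g$table)
  expect_gt(before$n_unknown_cells, 0)
  expect_gt(before$n_suppressed_cells, 0)
  # imputation draws independently per axis, so cross-axis totals agree
  # only up to the disclosure bound: use a tolerance on that scale
  after <- birth_table_report(repair_birth_table(g$table, seed = 1),
                              tolerance = 1e-3)
  expect_equal(after$n_unknown_cells, 0)
  expect_equal(after$n_suppressed_cells, 0)
  expect_equal(after$n_axis_total_mismatches, 0)

  # without suppression the repaired totals agree to machine precision
  g2 <- generate_births(small_config(seed = 5, n = 2e4,
                                     missing_frac = 0.05))
  after2 <- birth_table_report(repair_birth_table(g2$table, seed = 1))
  expect_equal(after2$n_axis_total_mismatches, 0)
})
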