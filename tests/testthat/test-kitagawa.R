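test_that("population summaries give shares and stratum rates", {
  table <- as_birth_table(tiny_table())
  s <- summarize_population(table, "AA", 2010, "maternal_age")
  expect_equal(sum(s$share), 1)
  expect_equal(s$share, c(0.5, 0.5))
  expect_equal(s$rate, compute_rate(c(5, 15), c(995, 985)))

  one <- summarize_population(table, "BB", 2010, "maternal_age")
  expect_equal(sum(one$share * one$rate),
               rate_series(table, "BB")$rate[1])

  expect_error(summarize_population(table, "ZZ", 2010, "maternal_age"),
               class = "sbt_lookup_error")
})

test_that("summaries after redistribution still sum to 1", {
  table <- tibble::tibble(
    country = "AA", year = 2010L, axis = "maternal_age",
    stratum = c("a", "b", "unknown"),
    stillbirths = c(3, 6, 2), live_births = c(500, 700, 40))
  repaired <- redistribute_unknown(as_birth_table(table))
  s <- summarize_population(repaired, "AA", 2010, "maternal_age")
  expect_equal(sum(s$share), 1, tolerance = 1e-12)
})

test_that("hand-evaluated decompositions are reproduced", {
  # composition-only change: shares 0.9/0.1 -> 0.8/0.2, rates fixed (3, 9)
  a <- tibble::tibble(stratum = c("s1", "s2"), share = c(0.9, 0.1),
                      rate = c(3, 9))
  b <- tibble::tibble(stratum = c("s1", "s2"), share = c(0.8, 0.2),
                      rate = c(3, 9))
  d <- kitagawa_decompose(a, b)
  expect_equal(d$total_difference, 0.6)        # 4.2 - 3.6
  expect_equal(d$composition_component, 0.6)
  expect_equal(d$rate_component, 0)

  # rate changes cancel in the aggregate but not per stratum
  a2 <- tibble::tibble(stratum = c("s1", "s2"), share = c(0.5, 0.5),
                       rate = c(3, 9))
  b2 <- tibble::tibble(stratum = c("s1", "s2"), share = c(0.5, 0.5),
                       rate = c(4, 8))
  d2 <- kitagawa_decompose(a2, b2)
  expect_equal(d2$total_difference, 0)
  expect_equal(d2$composition_component, 0)
  expect_equal(d2$rate_component, 0)
  expect_equal(d2$per_stratum$rate, c(0.5, -0.5))

  # identical populations decompose to zero
  d3 <- kitagawa_decompose(a, a)
  expect_equal(d3$total_difference, 0)
  expect_equal(d3$composition_component, 0)
  expect_equal(d3$rate_component, 0)
})

test_that("additivity, antisymmetry and null components hold on random pairs", {
  set.seed(17)
  for (rep in 1:200) {
    a <- random_population()
    b <- random_population()
    d <- kitagawa_decompose(a, b)
    expect_lt(abs(d$composition_component + d$rate_component -
                    d$total_difference), 1e-9)
    expect_lt(abs(sum(d$per_stratum$composition) - d$composition_component),
              1e-9)
    expect_lt(abs(sum(d$per_stratum$rate) - d$rate_component), 1e-9)
    back <- kitagawa_decompose(b, a)
    expect_equal(back$total_difference, -d$total_difference)
    expect_equal(back$composition_component, -d$composition_component)
    expect_equal(back$rate_component, -d$rate_component)
    # equal shares kill the composition channel
    null_c <- kitagawa_decompose(a, dplyr::mutate(b, share = a$share))
    expect_equal(null_c$composition_component, 0)
    # equal rates kill the rate channel
    null_r <- kitagawa_decompose(a, dplyr::mutate(b, rate = a$rate))
    expect_equal(null_r$rate_component, 0)
  }
})

test_that("strata absent on one side act through composition only", {
  a <- tibble::tibble(stratum = c("s1", "s2"), share = c(0.6, 0.4),
                      rate = c(3, 5))
  b <- tibble::tibble(stratum = c("s1", "s2", "s3"),
                      share = c(0.5, 0.3, 0.2), rate = c(3, 5, 8))
  d <- kitagawa_decompose(a, b)
  s3 <- dplyr::filter(d$per_stratum, stratum == "s3")
  expect_equal(s3$rate, 0)              # rate copied, no rate contribution
  expect_equal(s3$composition, 0.2 * 8) # share 0 -> 0.2 at rate 8
  expect_lt(abs(d$composition_component + d$rate_component -
                  d$total_difference), 1e-12)
})

test_that("invalid populations are rejected", {
  a <- tibble::tibble(stratum = c("s1", "s2"), share = c(0.7, 0.2),
                      rate = c(3, 5))
  b <- tibble::tibble(stratum = c("s1", "s2"), share = c(0.5, 0.5),
                      rate = c(3, 5))
  expect_error(kitagawa_decompose(a, b), class = "sbt_validation_error")
  dup <- tibble::tibble(stratum = c("s1", "s1"), share = c(0.5, 0.5),
                        rate = c(3, 5))
  expect_error(kitagawa_decompose(dup, b), class = "sbt_validation_error")
})

test_that("the decomposition is invariant to rescaling all counts", {
  base <- tibble::tibble(
    country = "AA", year = rep(c(2010L, 2021L), each = 2),
    axis = "maternal_age", stratum = rep(c("a", "b"), 2),
    stillbirths = c(4, 9, 3, 11), live_births = c(900, 420, 700, 800))
  scaled <- dplyr::mutate(base,
                          stillbirths = stillbirths * 7.5,
                          live_births = live_births * 7.5)
  d1 <- decompose_over_time(as_birth_table(base), "AA", "maternal_age")
  d2 <- decompose_over_time(as_birth_table(scaled), "AA", "maternal_age")
  expect_equal(d1$total_difference, d2$total_difference)
  expect_equal(d1$composition_component, d2$composition_component)
  expect_equal(d1$rate_component, d2$rate_component)
})

test_that("over-time decomposition recovers a constructed table", {
  # build counts from chosen shares and rates; the construction is the oracle
  shares_a <- c(0.7, 0.3); rates_a <- c(2.5, 6.0)   # per 1000
  shares_b <- c(0.55, 0.45); rates_b <- c(2.0, 5.0)
  n <- 1e6
  mk_rows <- function(year, shares, rates) {
    births <- n * shares
    sb <- births * rates / 1000
    tibble::tibble(country = "AA", year = year, axis = "maternal_age",
                   stratum = c("a", "b"), stillbirths = sb,
                   live_births = births - sb)
  }
  table <- as_birth_table(dplyr::bind_rows(mk_rows(2010L, shares_a, rates_a),
                                           mk_rows(2021L, shares_b, rates_b)))
  d <- decompose_over_time(table, "AA", "maternal_age")
  comp <- sum((shares_b - shares_a) * (rates_a + rates_b) / 2)
  rate <- sum((rates_b - rates_a) * (shares_a + shares_b) / 2)
  expect_equal(d$composition_component, comp, tolerance = 1e-9)
  expect_equal(d$rate_component, rate, tolerance = 1e-9)
  expect_equal(d$total_difference, comp + rate, tolerance = 1e-9)

  same <- decompose_over_time(table, "AA", "maternal_age",
                              year_a = 2010, year_b = 2010)
  expect_equal(same$total_difference, 0)
  expect_error(decompose_over_time(table, "AA", "maternal_age",
                                   year_a = 2015),
               class = "sbt_lookup_error")
})

test_that("the pooled reference is the birth-weighted average", {
  mk_country <- function(cn, n, rate) {
    tibble::tibble(country = cn, year = 2021L, axis = "maternal_age",
                   stratum = "all", stillbirths = n * rate / 1000,
                   live_births = n - n * rate / 1000)
  }
  equal <- as_birth_table(dplyr::bind_rows(mk_country("AA", 1e5, 2),
                                           mk_country("BB", 1e5, 4)))
  expect_equal(pooled_reference(equal, 2021, "maternal_age")$rate, 3)
  weighted <- as_birth_table(dplyr::bind_rows(mk_country("AA", 1e5, 2),
                                              mk_country("BB", 3e5, 4)))
  expect_equal(pooled_reference(weighted, 2021, "maternal_age")$rate, 3.5)

  solo <- pooled_reference(equal, 2021, "maternal_age", countries = "AA")
  expect_equal(solo$rate,
               summarize_population(equal, "AA", 2021, "maternal_age")$rate)
  expect_error(pooled_reference(equal, 2020, "maternal_age"),
               class = "sbt_lookup_error", regexp = "AA")
})

test_that("vs-reference decomposition vanishes for a uniform world", {
  one <- tibble::tibble(country = "AA", year = 2021L, axis = "maternal_age",
                        stratum = c("a", "b"), stillbirths = c(2, 6),
                        live_births = c(698, 1294))
  world <- as_birth_table(
    dplyr::bind_rows(one, dplyr::mutate(one, country = "BB"),
                     dplyr::mutate(one, country = "CC")))
  d <- decompose_vs_reference(world, "AA", "maternal_age")
  expect_equal(d$total_difference, 0)
  expect_equal(d$composition_component, 0)
  expect_equal(d$rate_component, 0)
  # a single-country reference containing only the country itself
  solo <- decompose_vs_reference(world, "AA", "maternal_age",
                                 countries = "AA")
  expect_equal(solo$total_difference, 0)
})

test_that("vs-reference components match a hand evaluation", {
  # two-country world; country AA has an older age structure
  mk <- function(cn, shares, rates, n) {
    births <- n * shares
    sb <- births * rates / 1000
    tibble::tibble(country = cn, year = 2021L, axis = "maternal_age",
                   stratum = c("young", "old"), stillbirths = sb,
                   live_births = births - sb)
  }
  rates <- c(3, 6)
  world <- as_birth_table(dplyr::bind_rows(
    mk("AA", c(0.6, 0.4), rates, 2e5),
    mk("BB", c(0.8, 0.2), rates, 2e5)))
  d <- decompose_vs_reference(world, "AA", "maternal_age")
  # pooled shares are (0.7, 0.3); rates equal everywhere
  comp_hand <- sum((c(0.7, 0.3) - c(0.6, 0.4)) * rates)
  expect_equal(d$composition_component, comp_hand, tolerance = 1e-9)
  expect_equal(d$rate_component, 0, tolerance = 1e-9)
  expect_equal(d$country_minus_reference, -d$total_difference)
})
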