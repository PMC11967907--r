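# Robust standardized residuals for designated years (pandemic-era
# surveillance): Theil-Sen trend on the reference years, MAD-scaled
# residuals for the target years.

# Theil-Sen estimator: median of all pairwise slopes, median-based
# intercept. Breakdown point ~29%, so a shocked year left in the reference
# set would barely move the fit -- but targets are excluded anyway so the
# anomaly cannot mask itself.
theil_sen <- function(x, y) {
  n <- length(x)
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  keep <- dx != 0
  slope <- stats::median((y[ij[2, ]] - y[ij[1, ]])[keep] / dx[keep])
  intercept <- stats::median(y - slope * x)
  c(intercept = intercept, slope = slope)
}

#' Flag anomalously high rates in designated years
#'
#' Fits a robust linear trend (Theil-Sen slope with a median-based
#' intercept) to the series excluding all target years, then standardises
#' each target year's departure from the trend by 1.4826 times the median
#' absolute deviation of the reference-year residuals. A year is flagged
#' when its robust z-score exceeds `threshold`; the flag is one-sided
#' because the question is whether rates were unusually *high*.
#'
#' Excluding the target years from the reference fit prevents a genuine
#' shock from inflating the dispersion estimate and masking itself.
#' If the reference residuals have zero MAD (an exact line), a nonzero
#' departure is reported as `Inf`/`-Inf`.
#'
#' @inheritParams mk_test
#' @param target_years Years to test (default 2020 and 2021). Target years
#'   absent from the series are dropped with a warning.
#' @param threshold Flagging threshold on the robust z-score (default 2).
#' @return A tibble of class `sbt_anomaly` with columns `country`, `year`,
#'   `observed`, `predicted`, `robust_z`, `flagged`; the robust fit
#'   (`slope`, `intercept`, `scale`) is attached as attributes.
#' @export
robust_anomaly <- function(series, target_years = c(2020L, 2021L),
                           threshold = 2) {
  s <- series_xy(series)
  is_target <- s$x %in% target_years
  if (sum(!is_target) < 5) {
    rlang::abort("Anomaly detection needs at least 5 non-target years",
                 class = "sbt_insufficient_data_error")
  }
  missing_targets <- setdiff(target_years, s$x)
  if (length(missing_targets) > 0) {
    rlang::warn(paste0("Target year(s) absent from series: ",
                       paste(missing_targets, collapse = ", ")))
  }
  fit <- theil_sen(s$x[!is_target], s$y[!is_target])
  ref_resid <- s$y[!is_target] - (fit["intercept"] + fit["slope"] * s$x[!is_target])
  scale <- stats::mad(ref_resid)  # 1.4826 * median |r - median(r)|
  observed <- s$y[is_target]
  predicted <- fit["intercept"] + fit["slope"] * s$x[is_target]
  resid <- observed - predicted
  # snap numerical noise from an exactly-linear series to zero so the
  # zero-dispersion sentinel is well defined
  eps <- 1e-10 * max(abs(s$y), 1)
  resid[abs(resid) < eps] <- 0
  if (scale < eps) scale <- 0
  z <- if (scale > 0) resid / scale else sign(resid) * Inf
  z[resid == 0] <- 0
  out <- tibble::tibble(
    country = s$country, year = as.integer(s$x[is_target]),
    observed = observed, predicted = unname(predicted),
    robust_z = unname(z), flagged = unname(z) > threshold)
  attr(out, "slope") <- unname(fit["slope"])
  attr(out, "intercept") <- unname(fit["intercept"])
  attr(out, "scale") <- scale
  attr(out, "threshold") <- threshold
  class(out) <- c("sbt_anomaly", class(out))
  out
}
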