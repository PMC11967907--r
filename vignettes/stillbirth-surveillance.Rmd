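---
title: "Methods: trend testing and decomposition of stillbirth rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trend testing and decomposition of stillbirth rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stillbirthtrends)
library(dplyr)
```

## The surveillance problem

National stillbirth rates are monitored from aggregated birth-registry
counts: for each country and year, stillbirths and live births stratified
by maternal age band or by multiplicity (singleton vs multiple pregnancy).
Two demographic risk factors have shifted markedly across Europe since
2010 — childbearing has moved toward ages 35 and over, while multiple
births (about three times the stillbirth risk of singletons) have declined
in most countries as assisted-reproduction practice changed. A country's
crude rate trend therefore mixes two things: changes in *who* is giving
birth (composition) and changes in the risk *within* each group (rates).
This package separates the two and supplies the supporting trend and
anomaly machinery, working entirely from aggregated counts, since
individual-level registry data is generally confidential.

Rates throughout are stillbirths per 1000 **total** births
(stillbirths + live births), the standard convention in perinatal
surveillance.

## Data model and repair

The input is a long table with one row per
(country, year, axis, stratum). Two repair steps precede analysis:

* **Unknown-stratum redistribution.** Births with an unrecorded stratum
  label are allocated to the known strata proportionally to each stratum's
  share of the known total, separately for stillbirths and live births
  within each (country, year, axis). Under the assumption that the
  missingness is unrelated to the stratum this is unbiased, conserves
  totals exactly, and — unlike dropping the rows — keeps every stillbirth
  in the numerator. The allocation is left fractional deliberately:
  rounding would re-introduce small allocation biases and break exact
  conservation.
* **Suppressed-cell imputation.** Disclosure control reports very small
  cells as "< k". Each such cell is replaced by a uniform draw on
  {0, ..., k−1}: given only the bound, the uniform is the maximum-entropy
  choice. The seed is mandatory so that a repair is reproducible. The
  bound is a required input because publishers use different k and the
  data do not encode it. After imputation the two axes' national totals
  agree only up to the suppressed amounts — an irreducible consequence of
  the information destroyed by suppression, which the validation report
  makes visible via its tolerance argument.

Countries enter with their native year spans; series beginning after 2010
(late-joining registries) are legal everywhere, and over-time comparisons
default to each country's earliest available year.

## Trend battery

**Mann–Kendall test.** `mk_test()` computes
\(S = \sum_{j>i} \operatorname{sign}(x_j - x_i)\) with the tie-corrected
variance and a ±1 continuity correction. Annual rate series are short
(typically 12 points) and often serially dependent, which inflates the
naive test's false-positive rate. The correction multiplies
\(\operatorname{Var}(S)\) by the Hamed–Rao variance-inflation factor
computed from the autocorrelation of the *ranks*, including only lags
(1 through n−3) whose autocorrelation exceeds the 5% significance band
\(\pm 1.96/\sqrt{n}\). When no lag is significant the factor is exactly 1
and the corrected and uncorrected tests coincide. A strongly negative
screened autocorrelation can push the factor non-positive at small n; the
implementation then falls back to 1 rather than reporting a negative
variance. Note one consequence of rank-based screening: a *deterministic*
monotone series has strongly autocorrelated ranks, so the corrected test
is more conservative there than the uncorrected one — a property, not a
defect.

**Slopes.** The headline annual change is the OLS slope of rate on year
(`fit_linear()`), with a 95% interval for the mean prediction.

**Slope changes.** `fit_segmented()` considers one continuous broken-line
(hinge) alternative, \(y = \beta_0 + \beta_1 x + \beta_2 (x-\psi)_+\).
Whether a change point exists is decided by a score test of the added
hinge covariate: for each candidate knot on a grid the score statistic is
computed under the straight-line null, and the grid maximum is converted
to a p-value with the Davies upper bound
\(p \le 2\Phi(-M) + V e^{-M^2/2}/\sqrt{8\pi}\), where V is the total
variation of the statistic along the grid. The bound is slightly
conservative, which we accept: on pure-line data the segmented
classification rate stays at or below the nominal 5%. Only if the test is
significant is the hinge model fitted, by profiling the residual sum of
squares over the same knot grid. The grid runs from the
`min_segment`-th to the (n−`min_segment`)-th observation at 0.1-year
resolution with `min_segment = 3` by default, so each regime keeps at
least three points and the knot cannot drift to the boundary; at this
resolution an iterative knot refinement would change nothing, so the
profile search is the whole estimator. At most one breakpoint is
considered — short annual series cannot support more.

**Anomalous years.** `robust_anomaly()` asks whether designated years
(2020 and 2021 by default, the pandemic years) were unusually *high*.
A robust trend — Theil–Sen slope, median-based intercept — is fitted to
the series *excluding* the target years, and each target year's departure
from it is standardised by 1.4826 × MAD of the reference residuals. The
leave-target-out choice matters: a genuine shock left in the reference
set would inflate the dispersion estimate and partially mask itself.
Flagging is one-sided (z > 2 by default) because unusually low rates are
not the surveillance question. If the reference years lie exactly on a
line the MAD is zero and a nonzero departure is reported as `Inf`;
residuals and scale below 1e−10 × the series magnitude are snapped to
zero first so this sentinel is well defined under floating point.

## Kitagawa decomposition

For two populations A and B with stratum shares \(C_i\) and stratum rates
\(M_i\),

\[
\Delta = \sum_i (C_{iB} - C_{iA})\,\frac{M_{iB}+M_{iA}}{2}
       + \sum_i (M_{iB} - M_{iA})\,\frac{C_{iB}+C_{iA}}{2},
\]

an exact split of the crude-rate difference into a **composition
component** (the counterfactual change if only the stratum shares
differed, rates held at the two-population average) and a **rate
component** (the converse). The implementation preserves additivity to
machine precision and is antisymmetric under swapping A and B.

Decisions where the definition leaves room:

* Maternal age and multiplicity are decomposed **separately**. Registry
  extracts do not release the full age × multiplicity cross-tabulation,
  so a joint decomposition is not identifiable from the data this package
  targets (the synthetic generator builds a cross-tab internally but
  releases only the margins, mirroring that constraint).
* A stratum present in only one population enters with share 0 on the
  absent side and the rate copied from the present side: the term then
  contributes only through the composition channel and no 0/0 rate
  arises.
* A stratum with births but no stillbirths has rate 0 — a legal value; no
  smoothing or continuity correction is applied anywhere.
* The pooled reference is built by summing stillbirths and births across
  countries before computing shares and rates — the birth-weighted
  average, not the mean of national rates — and the country under
  comparison stays inside the pool by default (`exclude_self = FALSE`).
  With population B the pooled reference, a positive \(\Delta\) means the
  reference exceeds the country; results also carry the negation as the
  country-minus-average difference for "above/below average" reporting.

## The synthetic registry

`synthetic_config()` / `generate_births()` simulate the kind of extract
the pipeline consumes, with full ground truth. Births are drawn
multinomially from an age × multiplicity cross-tabulation interpolated
linearly between start-year and end-year parameters; stillbirths are
binomial per cell with probability
(age-band risk) × (risk ratio if multiple) × (optional year shock); the
cross-tab is then marginalised into the two released axis tables, after
which label missingness and disclosure suppression are injected per axis.
The `"expected"` sampling mode replaces every draw by its expectation —
the infinite-n limit in which the estimated decomposition must equal the
designed one exactly, which is the sharpest available correctness check.

The default preset (`synthetic_preset()`) encodes the study conditions of
published cross-country surveillance: 24 countries with annual totals
log-spaced over 4×10³–8×10⁵ births; multiple-birth shares between 2.4%
and 5.4%, mostly declining over 2010–2021; baseline national rates
spanning roughly 2–5.5 per 1000; age shares shifting from
(4.5, 17, 28, 29, 17, 4.5)% toward (2, 10, 22, 32, 25, 9)% across the
bands <20, 20–24, 25–29, 30–34, 35–39, 40+; J-shaped age risk
(4.5, 3.2, 3.0, 3.4, 4.4, 6.5 per 1000) whose advanced-age arm declines
by 2021 (…, 3.7, 5.0) while the youngest band worsens slightly; risk
ratio 3 for multiples; 3% missing stratum labels; disclosure bound 3 for
the three smallest countries; and four countries starting 2013–2015.
Values not fixed by published ranges (the age-share trajectories, the
missingness fraction, which countries are suppressed or late) were chosen
once as field-realistic defaults.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: registries differ in definitions and
completeness in ways beyond a uniform missingness fraction; age and
multiplicity are independent by default (a positive coupling option
exists but real confounding with assisted reproduction is richer);
within-cell risk is homogeneous binomial, so real overdispersion
(clustering, within-band age gradients) is absent; there is no
gestational-age dimension and no TOP adjustment (`includes_TOP` is
metadata only, as harmonisation happens upstream of tables like these).

## Problem sizes and numerical conventions

The test-suite simulations use sizes chosen to make Monte-Carlo error
small relative to the assertions: 2000 replicates for test-level
calibration (MK type-I error, segmented false-positive rate), 500 series
for the exhaustive Mann–Kendall oracle, 200 replicates at 100 000
births/year for decomposition parameter recovery (assertions at 3
Monte-Carlo standard errors), and 100 seeds at 500 000 births/year for
anomaly-detection power. Decomposition additivity and conservation
invariants are asserted at 1e−9; exact constructions (noise-free hinge,
expected-count generation) at machine-precision tolerances. All
randomness is seeded; repair, trend, decomposition and pipeline outputs
are deterministic functions of their inputs and seeds, and a pipeline run
with a fixed configuration writes byte-identical bundles.

## Known limitations

* The Hamed–Rao lag-screening variant is one canonical choice among
  several in the literature; with 12-point series the corrected test's
  small-sample behaviour depends on that choice.
* The Davies bound makes the slope-change test conservative; weak slope
  changes near the series ends will often be reported as a single slope
  (`min_segment` also forbids knots in the outer two years by default).
* Robust anomaly z-scores from ~10 reference years are noisy; the
  one-sided 5% nominal level is approximate at that length, and the
  package reports the z-scores themselves so users are not bound to the
  default threshold.
* The decomposition attributes no uncertainty to its components; with
  aggregated national counts the dominant uncertainty is usually the
  small stillbirth numerators of small countries, visible in the rate
  series rather than quantified per component.
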