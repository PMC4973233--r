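#' Statistical power of a two-sample MR analysis with a binary outcome
#'
#' Normal-approximation power for detecting a causal odds ratio per 1 SD of
#' exposure in a case-control design instrumented by a genetic score
#' explaining a fraction `r2` of the exposure variance. The non-centrality
#' is `|log OR| * sqrt(N * r2 * phi * (1 - phi))` with `N` the total sample
#' and `phi` the case fraction; power is the upper-tail probability
#' `pnorm(ncp - z_(1 - alpha/2))` (one-tailed approximation, no continuity
#' correction). At OR = 1 this returns `alpha / 2`, the one-sided rejection
#' floor of the approximation.
#'
#' @param n_cases,n_controls positive case and control counts.
#' @param r2 instrument-explained exposure variance fraction in (0, 1).
#' @param odds_ratio causal odds ratio per exposure SD (> 0); power is
#'   symmetric in `OR` and `1/OR`.
#' @param alpha two-sided significance level in (0, 1), default 0.05.
#' @return power as a fraction in (0, 1). Vectorized over `odds_ratio`.
#' @export
#' @examples
#' mr_power(904, 21480, r2 = 0.027, odds_ratio = 1.81)
mr_power <- function(n_cases, n_controls, r2, odds_ratio, alpha = 0.05) {
  .check_power_args(n_cases, n_controls, r2, alpha)
  stopifnot(all(odds_ratio > 0))
  n <- n_cases + n_controls
  phi <- n_cases / n
  ncp <- abs(log(odds_ratio)) * sqrt(n * r2 * phi * (1 - phi))
  stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
}

#' Minimum detectable odds ratio at a target power
#'
#' Inverts [mr_power()]: the smallest harmful odds ratio (> 1) per exposure
#' SD detectable at the target power, `exp((z_(1-alpha/2) + z_power) /
#' sqrt(N * r2 * phi * (1 - phi)))`. The detectable protective OR is its
#' reciprocal. Round-trips through [mr_power()] to the target power within
#' 1e-9.
#'
#' @inheritParams mr_power
#' @param power target power fraction in (0, 1), default 0.80.
#' @return odds ratio > 1.
#' @export
#' @examples
#' min_detectable_or(16572, 21480, r2 = 0.027)
min_detectable_or <- function(n_cases, n_controls, r2, power = 0.80,
                              alpha = 0.05) {
  .check_power_args(n_cases, n_controls, r2, alpha)
  stopifnot(power > 0, power < 1)
  n <- n_cases + n_controls
  phi <- n_cases / n
  exp((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) /
        sqrt(n * r2 * phi * (1 - phi)))
}

.check_power_args <- function(n_cases, n_controls, r2, alpha) {
  stopifnot(n_cases > 0, n_controls > 0, r2 > 0, r2 < 1,
            alpha > 0, alpha < 1)
}

#' Power table across analysis strata
#'
#' Minimum detectable OR (at the target power) and, optionally, power at a
#' hypothesized OR, for each stratum of a case-control analysis.
#'
#' @param strata data frame with columns `stratum`, `n_cases`,
#'   `n_controls`, and optionally `odds_ratio` (hypothesized effect).
#' @inheritParams min_detectable_or
#' @return data frame: stratum, counts, `detectable_or`, and `power_at_or`
#'   where an `odds_ratio` was given.
#' @export
power_table <- function(strata, r2, power = 0.80, alpha = 0.05) {
  stopifnot(all(c("stratum", "n_cases", "n_controls") %in% names(strata)))
  out <- strata
  out$detectable_or <- mapply(min_detectable_or, strata$n_cases,
                              strata$n_controls,
                              MoreArgs = list(r2 = r2, power = power,
                                              alpha = alpha))
  if ("odds_ratio" %in% names(strata)) {
    out$power_at_or <- ifelse(
      is.na(strata$odds_ratio), NA_real_,
      mapply(function(ca, co, or) {
        if (is.na(or)) NA_real_ else mr_power(ca, co, r2, or, alpha)
      }, strata$n_cases, strata$n_controls, strata$odds_ratio))
  }
  out
}
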