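#' Construct a causal-estimate record
#'
#' One row holding a causal effect of the exposure on the outcome, expressed
#' as log-odds per 1 SD of exposure, together with its standard error, 95%
#' confidence interval, p-value, SNP count and the odds-ratio scale
#' transform. All estimators in the package return this shape so results can
#' be row-bound into forest tables.
#'
#' @param method estimator label (`wald`, `ivw`, `likelihood`,
#'   `weighted_median`, `egger_slope`, ...).
#' @param theta causal log-odds per exposure SD.
#' @param se standard error of `theta`.
#' @param n_snps number of instruments used.
#' @param ci_low,ci_high 95% interval on the log scale; default Wald
#'   `theta +/- 1.96 se`.
#' @param pvalue two-sided p; default from the normal z statistic.
#' @return one-row `causal_estimate` data frame.
#' @export
causal_estimate <- function(method, theta, se, n_snps,
                            ci_low = theta - stats::qnorm(0.975) * se,
                            ci_high = theta + stats::qnorm(0.975) * se,
                            pvalue = 2 * stats::pnorm(-abs(theta / se))) {
  stopifnot(ci_low <= theta + 1e-12, theta <= ci_high + 1e-12)
  structure(
    data.frame(method = method, n_snps = as.integer(n_snps), theta = theta,
               se = se, ci_low = ci_low, ci_high = ci_high, pvalue = pvalue,
               or = exp(theta), or_ci_low = exp(ci_low),
               or_ci_high = exp(ci_high), stringsAsFactors = FALSE),
    class = c("causal_estimate", "data.frame")
  )
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat(sprintf(
    "%s estimate (%d SNPs): OR %.3f [%.3f-%.3f] per exposure SD, p = %.3g\n",
    x$method, x$n_snps, x$or, x$or_ci_low, x$or_ci_high, x$pvalue))
  invisible(x)
}

# per-SNP Wald ratios and delta-method SEs; order 1: se_gd/|beta_gp|,
# order 2 adds the beta_gp measurement-error term
.wald_ratios <- function(instruments, delta_order = 1) {
  b <- instruments
  if (any(b$beta_gp == 0)) {
    stop("undefined ratio: beta_gp = 0 for ",
         paste(b$rsid[b$beta_gp == 0], collapse = ", "))
  }
  ratio <- b$beta_gd / b$beta_gp
  se <- if (delta_order == 1) {
    b$se_gd / abs(b$beta_gp)
  } else {
    sqrt(b$se_gd^2 / b$beta_gp^2 + b$beta_gd^2 * b$se_gp^2 / b$beta_gp^4)
  }
  data.frame(rsid = b$rsid, ratio = ratio, se = se,
             stringsAsFactors = FALSE)
}

#' Per-SNP Wald ratio estimate
#'
#' The single-instrument causal estimate: the ratio of the SNP-outcome
#' effect to the SNP-exposure effect, with a delta-method standard error
#' (first order by default; second order additionally propagates the
#' exposure-effect uncertainty).
#'
#' @param inst one-row `harmonized_instruments` data frame (or several rows:
#'   one estimate per row is returned, row-bound).
#' @param delta_order 1 or 2.
#' @return `causal_estimate` rows, one per SNP.
#' @export
wald_ratio <- function(inst, delta_order = 1) {
  w <- .wald_ratios(inst, delta_order)
  out <- do.call(rbind, lapply(seq_len(nrow(w)), function(j) {
    causal_estimate("wald", w$ratio[j], w$se[j], 1L)
  }))
  out$rsid <- w$rsid
  out
}

#' Inverse-variance weighted (IVW) causal estimate
#'
#' Fixed-effect precision-weighted average of the per-SNP Wald ratios, with
#' weights the inverse squared first-order delta-method standard errors.
#' Algebraically identical to weighted least squares of `beta_gd` on
#' `beta_gp` through the origin with weights `1/se_gd^2`.
#'
#' @param instruments `harmonized_instruments`, at least one SNP.
#' @param delta_order delta-method order for the ratio SEs.
#' @return `causal_estimate` row with `method = "ivw"`.
#' @export
ivw_estimate <- function(instruments, delta_order = 1) {
  if (nrow(instruments) < 1L) stop("input error: no instruments")
  w <- .wald_ratios(instruments, delta_order)
  wt <- 1 / w$se^2
  theta <- sum(wt * w$ratio) / sum(wt)
  causal_estimate("ivw", theta, 1 / sqrt(sum(wt)), nrow(w))
}

# profile log-likelihood of theta: per-SNP exposure effect xi_j profiled out
# in closed form, leaving -0.5 * sum (bgd - theta*bgp)^2/(se_gd^2+theta^2 se_gp^2)
.profile_loglik <- function(theta, b) {
  -0.5 * sum((b$beta_gd - theta * b$beta_gp)^2 /
               (b$se_gd^2 + theta^2 * b$se_gp^2))
}

#' Profile-likelihood causal estimate
#'
#' Maximum-likelihood estimate of the causal effect under the bivariate
#' normal measurement model for two-sample summary data: the observed
#' SNP-exposure effect is normal about a true effect `xi_j`, the observed
#' SNP-outcome effect is normal about `theta * xi_j`, independently across
#' and within SNPs (no sample overlap). The nuisance `xi_j` have a closed
#' form at each `theta` and are profiled out; `theta` is then maximized by
#' bounded one-dimensional search (tolerance 1e-10).
#'
#' The 95% interval is by profile likelihood (`2 * delta log-lik = 3.841`,
#' the default) or by the observed-information Wald standard error. The
#' reported p-value is from the likelihood-ratio test against `theta = 0`
#' for `ci_method = "profile"`, and from the Wald z statistic otherwise; the
#' observed-information SE is reported in both cases.
#'
#' @param instruments `harmonized_instruments`, at least 2 SNPs.
#' @param ci_method `"profile"` (default) or `"wald"`.
#' @return `causal_estimate` row with `method = "likelihood"`.
#' @export
likelihood_estimate <- function(instruments, ci_method = c("profile", "wald")) {
  ci_method <- match.arg(ci_method)
  b <- instruments
  if (nrow(b) < 2L) stop("input error: need >= 2 instruments")
  if (any(b$beta_gp == 0)) b <- b[b$beta_gp != 0, , drop = FALSE]
  ratios <- b$beta_gd / b$beta_gp
  lo <- min(ratios) - 1
  hi <- max(ratios) + 1
  opt <- stats::optimize(.profile_loglik, interval = c(lo, hi), b = b,
                         maximum = TRUE, tol = 1e-10)
  theta <- opt$maximum
  ll0 <- opt$objective
  if (min(theta - lo, hi - theta) < 1e-6) {
    stop("estimation error: profile maximum at search boundary [",
         signif(lo, 4), ", ", signif(hi, 4), "]; theta = ", signif(theta, 6))
  }

  # observed-information SE from the numerical curvature of the profile
  h <- 1e-4 * max(1, abs(theta))
  curv <- -(.profile_loglik(theta + h, b) - 2 * ll0 +
              .profile_loglik(theta - h, b)) / h^2
  if (!is.finite(curv) || curv <= 0) {
    stop("estimation error: non-positive observed information at theta = ",
         signif(theta, 6))
  }
  se <- 1 / sqrt(curv)

  if (ci_method == "wald") {
    return(causal_estimate("likelihood", theta, se, nrow(b)))
  }
  crit <- stats::qchisq(0.95, df = 1) / 2
  gfun <- function(x) ll0 - .profile_loglik(x, b) - crit
  ci_low <- .profile_root(gfun, theta, -se)
  ci_high <- .profile_root(gfun, theta, se)
  lrt <- 2 * (ll0 - .profile_loglik(0, b))
  pval <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  causal_estimate("likelihood", theta, se, nrow(b),
                  ci_low = ci_low, ci_high = ci_high, pvalue = pval)
}

# walk out from theta-hat in steps of `step` until the profile drop exceeds
# the chi-square criterion, then bisect
.profile_root <- function(gfun, theta, step) {
  x <- theta + step
  for (i in 1:60) {
    if (gfun(x) > 0) break
    x <- x + step * 2^i
  }
  if (gfun(x) <= 0) stop("estimation error: profile CI bound not bracketed")
  stats::uniroot(gfun, sort(c(theta, x)), tol = 1e-10)$root
}

# weighted median of ratio estimates: order statistics as percentiles
# p_j = cumsum(w)_j - w_j/2 of the normalized weights, linear interpolation
# at p = 1/2, boundary ratio returned outside [p_1, p_J]
.weighted_median <- function(ratio, weight, rsid = seq_along(ratio)) {
  o <- order(ratio, rsid)                 # stable tie-break on (ratio, rsid)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(r[1])
  if (p[length(p)] <= 0.5) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median causal estimate
#'
#' The 50th percentile of the inverse-variance-weighted empirical
#' distribution of ordered per-SNP Wald ratios. Consistent when valid
#' instruments carry more than half of the total weight, making it robust to
#' up to 50% invalid (pleiotropic) instruments by weight. The standard error
#' is by seeded parametric bootstrap: both summary effects are redrawn from
#' normal distributions at their reported SEs and the estimate recomputed.
#'
#' @param instruments `harmonized_instruments`, at least 3 SNPs.
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed integer seed for the bootstrap (mandatory: the SE is
#'   stochastic and must be reproducible).
#' @param delta_order delta-method order for the ratio weights.
#' @return `causal_estimate` row with `method = "weighted_median"`.
#' @export
weighted_median_estimate <- function(instruments, n_boot = 10000, seed,
                                     delta_order = 1) {
  if (nrow(instruments) < 3L) stop("input error: need >= 3 instruments")
  if (missing(seed)) stop("configuration error: bootstrap seed is required")
  stopifnot(n_boot >= 1)
  w <- .wald_ratios(instruments, delta_order)
  wt <- 1 / w$se^2
  if (max(wt) / sum(wt) > 1 - 1e-12) {
    warning("all weight concentrated on one SNP; returning its ratio")
  }
  theta <- .weighted_median(w$ratio, wt, w$rsid)

  b <- instruments
  J <- nrow(b)
  set.seed(seed)
  bgp <- matrix(stats::rnorm(J * n_boot, b$beta_gp, b$se_gp), nrow = J)
  bgd <- matrix(stats::rnorm(J * n_boot, b$beta_gd, b$se_gd), nrow = J)
  reps <- vapply(seq_len(n_boot), function(k) {
    r <- bgd[, k] / bgp[, k]
    s <- if (delta_order == 1) {
      b$se_gd / abs(bgp[, k])
    } else {
      sqrt(b$se_gd^2 / bgp[, k]^2 + bgd[, k]^2 * b$se_gp^2 / bgp[, k]^4)
    }
    .weighted_median(r, 1 / s^2, b$rsid)
  }, numeric(1))
  se <- stats::sd(reps)
  if (se == 0) se <- .Machine$double.eps  # degenerate: all SEs ~ 0
  causal_estimate("weighted_median", theta, se, J)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of the SNP-outcome effects on the
#' SNP-exposure effects with a free intercept and weights `1/se_gd^2`,
#' fitted on instruments oriented so every `beta_gp >= 0` (the orientation
#' [harmonize()] guarantees). The slope is a pleiotropy-adjusted causal
#' estimate; the intercept estimates average directional pleiotropy, and its
#' two-sided test is the directional-pleiotropy test. Standard errors use
#' the model residual standard error floored at 1 (no under-dispersion
#' below the fixed-effect model) and t reference distributions with J - 2
#' degrees of freedom.
#'
#' @param instruments `harmonized_instruments`, at least 3 SNPs with
#'   non-constant `beta_gp`.
#' @return an `egger_result` list: `slope` (a `causal_estimate` with
#'   `method = "egger_slope"`) and `intercept` (value, se, ci_low, ci_high,
#'   pvalue).
#' @export
egger_regression <- function(instruments) {
  b <- instruments
  if (nrow(b) < 3L) stop("input error: need >= 3 instruments")
  if (any(b$beta_gp < 0)) {
    stop("input error: instruments must be oriented so beta_gp >= 0")
  }
  if (stats::sd(b$beta_gp) < 1e-12) {
    stop("estimation error: beta_gp constant across SNPs (collinear design)")
  }
  fit <- stats::lm(beta_gd ~ beta_gp, data = b, weights = 1 / b$se_gd^2)
  sm <- summary(fit)
  co <- sm$coefficients
  # residual dispersion floored at 1: never more precise than fixed effects
  se <- sqrt(diag(sm$cov.unscaled)) * max(1, sm$sigma)
  df <- nrow(b) - 2L
  tq <- stats::qt(0.975, df)
  pv <- 2 * stats::pt(-abs(co[, "Estimate"] / se), df)
  slope <- causal_estimate(
    "egger_slope", co["beta_gp", "Estimate"], se[["beta_gp"]], nrow(b),
    ci_low = co["beta_gp", "Estimate"] - tq * se[["beta_gp"]],
    ci_high = co["beta_gp", "Estimate"] + tq * se[["beta_gp"]],
    pvalue = pv[["beta_gp"]]
  )
  structure(list(
    slope = slope,
    intercept = list(
      value = co["(Intercept)", "Estimate"], se = se[["(Intercept)"]],
      ci_low = co["(Intercept)", "Estimate"] - tq * se[["(Intercept)"]],
      ci_high = co["(Intercept)", "Estimate"] + tq * se[["(Intercept)"]],
      pvalue = pv[["(Intercept)"]]
    )
  ), class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept %.4g (se %.3g, p = %.3g)\n",
              x$intercept$value, x$intercept$se, x$intercept$pvalue))
  invisible(x)
}

.heterogeneity_result <- function(q, df) {
  structure(list(
    q = q, df = as.integer(df),
    pvalue = stats::pchisq(q, df, lower.tail = FALSE),
    i_squared = if (q > 0) max(0, (q - df) / q) * 100 else 0
  ), class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %d df (p = %.3g), I^2 = %.1f%%\n",
              x$q, x$df, x$pvalue, x$i_squared))
  invisible(x)
}

#' Heterogeneity among per-SNP causal estimates
#'
#' Cochran's Q of the per-SNP Wald ratios about the IVW estimate, with the
#' IVW weights; `df = J - 1`; I-squared is the percentage of variation
#' attributed to heterogeneity rather than chance, floored at 0.
#'
#' @param instruments `harmonized_instruments`, at least 2 SNPs.
#' @param delta_order delta-method order for the ratio SEs.
#' @return `heterogeneity_result` list: `q`, `df`, `pvalue`, `i_squared`.
#' @export
snp_heterogeneity <- function(instruments, delta_order = 1) {
  if (nrow(instruments) < 2L) stop("input error: need >= 2 instruments")
  w <- .wald_ratios(instruments, delta_order)
  wt <- 1 / w$se^2
  theta <- sum(wt * w$ratio) / sum(wt)
  .heterogeneity_result(sum(wt * (w$ratio - theta)^2), nrow(w) - 1L)
}

#' Heterogeneity across stratum-level causal estimates
#'
#' Cochran's Q across independent stratum estimates (e.g. histological
#' subtypes, or never vs ever smokers) weighted by `1/se^2`.
#'
#' @param estimates data frame with columns `theta` and `se` (rows of
#'   [causal_estimate()] row-bound), at least 2 strata.
#' @return `heterogeneity_result`.
#' @export
strata_heterogeneity <- function(estimates) {
  stopifnot(is.data.frame(estimates), all(c("theta", "se") %in% names(estimates)))
  if (nrow(estimates) < 2L) stop("input error: need >= 2 stratum estimates")
  wt <- 1 / estimates$se^2
  pooled <- sum(wt * estimates$theta) / sum(wt)
  .heterogeneity_result(sum(wt * (estimates$theta - pooled)^2),
                        nrow(estimates) - 1L)
}
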