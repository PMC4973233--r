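#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools k independent study estimates by inverse-variance weighting:
#' pooled effect `sum(theta/se^2)/sum(1/se^2)`, pooled SE
#' `1/sqrt(sum(1/se^2))`, with Cochran's Q (df = k - 1) and I-squared.
#'
#' @param estimates numeric vector of study effects, or a data frame with
#'   columns `theta`/`estimate` and `se`.
#' @param se numeric vector of standard errors (all > 0) when `estimates`
#'   is a vector.
#' @return a `meta_result` list: `pooled`, `se`, `ci_low`, `ci_high`,
#'   `pvalue`, `q`, `df`, `i_squared`, `k`.
#' @export
fixed_effects_pool <- function(estimates, se = NULL) {
  if (is.data.frame(estimates)) {
    eff_col <- intersect(c("theta", "estimate", "slope"), names(estimates))[1]
    if (is.na(eff_col) || !"se" %in% names(estimates)) {
      stop("input error: need effect and se columns")
    }
    se <- estimates$se
    estimates <- estimates[[eff_col]]
  }
  k <- length(estimates)
  if (k < 1L) stop("input error: no studies to pool")
  if (length(se) != k) stop("input error: estimate/se length mismatch")
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("input error: all standard errors must be positive")
  }
  wt <- 1 / se^2
  pooled <- sum(wt * estimates) / sum(wt)
  pse <- 1 / sqrt(sum(wt))
  q <- sum(wt * (estimates - pooled)^2)
  df <- k - 1L
  structure(list(
    pooled = pooled, se = pse,
    ci_low = pooled - stats::qnorm(0.975) * pse,
    ci_high = pooled + stats::qnorm(0.975) * pse,
    pvalue = 2 * stats::pnorm(-abs(pooled / pse)),
    q = q, df = df,
    pvalue_q = if (df >= 1) stats::pchisq(q, df, lower.tail = FALSE) else NA_real_,
    i_squared = if (q > 0 && df >= 1) max(0, (q - df) / q) * 100 else 0,
    k = k
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "fixed-effects pool of %d studies: %.4g [%.4g, %.4g], p = %.3g, I^2 = %.1f%%\n",
    x$k, x$pooled, x$ci_low, x$ci_high, x$pvalue, x$i_squared))
  invisible(x)
}

#' Meta-analyze per-SNP effects across outcome studies
#'
#' Given per-study summary-statistics tables, aligns every study's record
#' for each rsID to a common effect allele (the orientation of the first
#' study reporting the SNP; label swaps negate the beta and complement the
#' frequency, strand flips relabel alleles) and pools the aligned betas by
#' fixed-effects inverse-variance meta-analysis. A SNP passing QC in only
#' one study passes through unchanged. SNPs whose allele pairs conflict
#' irreconcilably across studies are dropped with a reason.
#'
#' @param per_study named list of `variant_assoc` data frames, one per
#'   outcome study (already filtered for imputation quality as desired).
#' @return `variant_assoc` data frame of pooled records; `n_cases` and
#'   `n_controls` are summed over contributing studies and the per-SNP
#'   contributing-study count is in column `n_studies`. Attribute `dropped`
#'   lists conflicted SNPs.
#' @export
pool_snp_effects <- function(per_study) {
  stopifnot(is.list(per_study), length(per_study) >= 1)
  per_study <- lapply(per_study, as.data.frame)
  comp <- function(a) chartr("ACGT", "TGCA", a)
  all_rsids <- unique(unlist(lapply(per_study, `[[`, "rsid")))
  dropped <- character(0)
  rows <- lapply(all_rsids, function(id) {
    recs <- do.call(rbind, lapply(per_study, function(s) {
      s[s$rsid == id, , drop = FALSE]
    }))
    ref <- recs[1, ]
    betas <- ses <- eafs <- numeric(0)
    ncase <- nctrl <- 0
    for (i in seq_len(nrow(recs))) {
      r <- recs[i, ]
      if (r$effect_allele == ref$effect_allele &&
          r$other_allele == ref$other_allele) {
        sgn <- 1; ef <- r$eaf
      } else if (r$effect_allele == ref$other_allele &&
                 r$other_allele == ref$effect_allele) {
        sgn <- -1; ef <- 1 - r$eaf
      } else if (comp(r$effect_allele) == ref$effect_allele &&
                 comp(r$other_allele) == ref$other_allele) {
        sgn <- 1; ef <- r$eaf
      } else if (comp(r$effect_allele) == ref$other_allele &&
                 comp(r$other_allele) == ref$effect_allele) {
        sgn <- -1; ef <- 1 - r$eaf
      } else {
        dropped <<- c(dropped, id)
        return(NULL)
      }
      betas <- c(betas, sgn * r$beta)
      ses <- c(ses, r$se)
      eafs <- c(eafs, ef)
      ncase <- ncase + ifelse(is.na(r$n_cases), 0, r$n_cases)
      nctrl <- nctrl + ifelse(is.na(r$n_controls), 0, r$n_controls)
    }
    m <- fixed_effects_pool(betas, ses)
    data.frame(
      rsid = id, effect_allele = ref$effect_allele,
      other_allele = ref$other_allele,
      eaf = if (all(is.na(eafs))) NA_real_ else mean(eafs, na.rm = TRUE),
      beta = m$pooled, se = m$se,
      pvalue = m$pvalue, info = NA_real_,
      n_cases = ncase, n_controls = nctrl,
      n_studies = length(betas), stringsAsFactors = FALSE
    )
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  rownames(out) <- NULL
  structure(out,
            dropped = data.frame(rsid = unique(dropped),
                                 reason = rep("conflicting allele pairs",
                                              length(unique(dropped))),
                                 stringsAsFactors = FALSE),
            rejected = data.frame(row = integer(), rsid = character(),
                                  reason = character()),
            class = c("variant_assoc", "data.frame"))
}
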