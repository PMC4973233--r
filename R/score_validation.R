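#' Build the weighted allele score
#'
#' Per-subject weighted sum of allele dosages, `score_i = sum_j d_ij *
#' w_j`, with weights the per-allele SNP-exposure effects (exposure-SD
#' units). The raw weighted sum is returned: no frequency centering, no
#' rescaling. Weighted SNPs absent from the dosage matrix are dropped with a
#' warning; missing dosages are mean-imputed per SNP before summing.
#'
#' @param data `individual_data` data frame (dosage columns named by rsID).
#' @param weights named numeric vector, rsID -> per-allele exposure effect.
#' @return numeric vector of scores, one per subject.
#' @export
build_score <- function(data, weights) {
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  have <- intersect(names(weights), names(data))
  if (!length(have)) stop("input error: no weighted SNP present in data")
  miss <- setdiff(names(weights), have)
  if (length(miss)) {
    warning(length(miss), " weighted SNP(s) absent from dosage data, ",
            "dropped: ", paste(utils::head(miss, 5), collapse = ", "),
            if (length(miss) > 5) ", ..." else "")
  }
  d <- as.matrix(as.data.frame(data)[, have, drop = FALSE])
  for (j in seq_len(ncol(d))) {
    na <- is.na(d[, j])
    if (any(na)) d[na, j] <- mean(d[, j], na.rm = TRUE)
  }
  unname(drop(d %*% weights[have]))
}

#' Regress a phenotype on the allele score with covariate adjustment
#'
#' Ordinary least squares of the phenotype on the score plus covariates
#' (default age, sex and the leading principal components), the
#' instrument-validity check: the score must predict the exposure and must
#' not predict phenotypes on confounding pathways (e.g. tobacco exposure).
#' Subjects with a missing phenotype or covariate are excluded listwise.
#'
#' @param data `individual_data` data frame.
#' @param phenotype column name to model (`bmi`, `cpd`, `pack_years`,
#'   `cotinine`, ...).
#' @param weights named rsID -> effect vector passed to [build_score()];
#'   ignored when `score` is supplied.
#' @param score optional precomputed score vector aligned with `data` rows.
#' @param covariates character vector of adjustment columns present in
#'   `data` (default `c("age", "sex")`).
#' @param n_pcs number of principal-component columns (`pc1`, `pc2`, ...)
#'   to adjust for, capped at those present (default 5).
#' @param study optional study label carried into the result.
#' @return a `score_association` one-row data frame: `phenotype`, `slope`
#'   (phenotype change per unit score), `se`, `ci_low`, `ci_high`,
#'   `pvalue`, `n`, `study`.
#' @export
score_phenotype_association <- function(data, phenotype, weights = NULL,
                                        score = NULL,
                                        covariates = c("age", "sex"),
                                        n_pcs = 5, study = NA_character_) {
  df <- as.data.frame(data)
  if (!phenotype %in% names(df)) {
    stop("input error: phenotype column '", phenotype, "' not found")
  }
  if (is.null(score)) {
    if (is.null(weights)) stop("input error: supply weights or score")
    score <- build_score(data, weights)
  }
  pcs <- intersect(paste0("pc", seq_len(n_pcs)), names(df))
  covs <- c(intersect(covariates, names(df)), pcs)
  mdf <- data.frame(.y = df[[phenotype]], .score = score,
                    df[, covs, drop = FALSE], check.names = FALSE)
  mdf <- mdf[stats::complete.cases(mdf), , drop = FALSE]
  if (stats::sd(mdf$.y) == 0) {
    stop("input error: phenotype '", phenotype, "' is constant")
  }
  if (nrow(mdf) < length(covs) + 3L) {
    stop("input error: too few complete observations")
  }
  fml <- stats::as.formula(paste(
    ".y ~ .score", if (length(covs)) paste("+", paste(sprintf("`%s`", covs),
                                                      collapse = " + ")) else ""))
  fit <- stats::lm(fml, data = mdf)
  if (any(is.na(stats::coef(fit)))) {
    stop("estimation error: rank-deficient design; collinear column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  co <- summary(fit)$coefficients
  est <- co[".score", "Estimate"]
  se <- co[".score", "Std. Error"]
  tq <- stats::qt(0.975, fit$df.residual)
  structure(
    data.frame(phenotype = phenotype, slope = est, se = se,
               ci_low = est - tq * se, ci_high = est + tq * se,
               pvalue = co[".score", "Pr(>|t|)"], n = nrow(mdf),
               study = study, stringsAsFactors = FALSE),
    class = c("score_association", "data.frame")
  )
}
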