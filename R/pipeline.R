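#' Read a declarative analysis configuration
#'
#' YAML with keys: `exposure` (summary-statistics path), `strata` (map of
#' stratum label -> list of outcome-study file paths), `info_threshold`,
#' `palindromic_policy`, `exclusion_list` (path or rsID vector, applied as
#' a sensitivity re-run), `estimators` (`ci_method`, `delta_order`,
#' `n_boot`, `seed`), `power` (`r2`, `alpha`, `target_power`, optional
#' `strata` table with hypothesized odds ratios), `strata_groups` (named
#' lists of stratum labels to test for between-stratum heterogeneity) and
#' `output_dir`. Relative paths are resolved against the config file's
#' directory.
#'
#' @param path YAML file path.
#' @return an `mr_analysis_config` list.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  cfg$exposure <- rel(cfg$exposure)
  cfg$strata <- lapply(cfg$strata, function(s) vapply(unlist(s), rel, ""))
  if (!is.null(cfg$exclusion_list) && length(cfg$exclusion_list) == 1L &&
      file.exists(rel(cfg$exclusion_list))) {
    cfg$exclusion_list <- rel(cfg$exclusion_list)
  }
  if (!is.null(cfg$output_dir)) cfg$output_dir <- rel(cfg$output_dir)
  as_analysis_config(cfg)
}

#' Validate and default-fill an analysis configuration
#' @param cfg named list (see [read_analysis_config()] for keys).
#' @return an `mr_analysis_config` list with defaults filled in.
#' @export
as_analysis_config <- function(cfg) {
  stopifnot(!is.null(cfg$exposure), length(cfg$strata) >= 1)
  cfg$info_threshold <- cfg$info_threshold %||% 0.6
  cfg$palindromic_policy <- cfg$palindromic_policy %||% "align_freq"
  est <- cfg$estimators %||% list()
  est$ci_method <- est$ci_method %||% "profile"
  est$delta_order <- est$delta_order %||% 1
  est$n_boot <- est$n_boot %||% 10000
  if (is.null(est$seed)) {
    stop("configuration error: estimators$seed is required ",
         "(weighted-median bootstrap)")
  }
  cfg$estimators <- est
  pw <- cfg$power %||% list()
  pw$r2 <- pw$r2 %||% 0.027
  pw$alpha <- pw$alpha %||% 0.05
  pw$target_power <- pw$target_power %||% 0.80
  cfg$power <- pw
  cfg$strata_groups <- cfg$strata_groups %||%
    list(histology = c("AD", "SQ", "SC"), smoking = c("never", "ever"))
  structure(cfg, class = "mr_analysis_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full two-sample MR analysis
#'
#' For every stratum: reads the outcome studies, drops SNPs at or below the
#' imputation-quality threshold per study, meta-analyzes per-SNP effects
#' across studies, harmonizes against the exposure study, and computes the
#' profile-likelihood estimate (labelled primary), IVW, weighted median,
#' MR-Egger (slope and intercept) and per-SNP heterogeneity. Across
#' strata, Cochran's Q is computed for each configured stratum group on
#' the primary estimates. When an exclusion list is configured, every
#' stratum is re-estimated without the listed SNPs (sensitivity analysis).
#' A power table is attached, and when `output_dir` is set all tables plus
#' a run manifest (config echo, seeds, exclusion log) and a structured log
#' are written as TSV/YAML.
#'
#' @param config an `mr_analysis_config` (or a YAML path, or a plain list
#'   passed through [as_analysis_config()]).
#' @return invisibly, a results bundle: `estimates` (data frame of stratum
#'   x method rows), `heterogeneity` (per-stratum), `strata_heterogeneity`
#'   (per group), `egger_intercepts`, `power`, `instrument_log`, `log`.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  if (!inherits(config, "mr_analysis_config")) {
    config <- as_analysis_config(config)
  }
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  exposure <- read_summary_stats(config$exposure)
  note("stage=read_exposure file=%s records=%d", config$exposure,
       nrow(exposure))
  excl_rsids <- character(0)
  if (!is.null(config$exclusion_list)) {
    excl_rsids <- config$exclusion_list
    if (length(excl_rsids) == 1L && file.exists(excl_rsids)) {
      excl_rsids <- trimws(readLines(excl_rsids, warn = FALSE))
      excl_rsids <- excl_rsids[nzchar(excl_rsids)]
    }
  }

  estimates <- list()
  heterogeneity <- list()
  intercepts <- list()
  instrument_log <- list()
  power_rows <- list()

  for (stratum in names(config$strata)) {
    res <- tryCatch({
      files <- config$strata[[stratum]]
      studies <- lapply(files, read_summary_stats)
      kept <- lapply(studies, function(s) {
        keep <- is.na(s$info) | s$info > config$info_threshold
        s[keep, , drop = FALSE]
      })
      for (i in seq_along(files)) {
        note("stage=info_filter stratum=%s study=%s in=%d out=%d",
             stratum, basename(files[i]), nrow(studies[[i]]),
             nrow(kept[[i]]))
      }
      pooled <- if (length(kept) > 1L) pool_snp_effects(kept) else kept[[1]]
      note("stage=pool stratum=%s studies=%d snps=%d", stratum,
           length(kept), nrow(pooled))
      inst <- harmonize(exposure, pooled,
                        palindromic_policy = config$palindromic_policy)
      note("stage=harmonize stratum=%s in=%d out=%d excluded=%d", stratum,
           nrow(pooled), nrow(inst), nrow(attr(inst, "excluded")))
      nca <- suppressWarnings(max(pooled$n_cases, na.rm = TRUE))
      nco <- suppressWarnings(max(pooled$n_controls, na.rm = TRUE))
      list(inst = inst, n_cases = nca, n_controls = nco)
    }, error = function(e) {
      note("stage=prepare stratum=%s ERROR %s", stratum,
           conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    instrument_log[[stratum]] <- attr(res$inst, "excluded")
    if (is.finite(res$n_cases) && is.finite(res$n_controls)) {
      power_rows[[stratum]] <- data.frame(
        stratum = stratum, n_cases = res$n_cases,
        n_controls = res$n_controls, stringsAsFactors = FALSE)
    }
    for (analysis in c("main", if (length(excl_rsids)) "sensitivity")) {
      inst <- res$inst
      if (analysis == "sensitivity") {
        inst <- suppressWarnings(exclude_snps(inst, excl_rsids))
        note("stage=exclude stratum=%s removed=%d remaining=%d", stratum,
             nrow(res$inst) - nrow(inst), nrow(inst))
      }
      out <- tryCatch(
        .estimate_stratum(inst, config$estimators),
        error = function(e) {
          note("stage=estimate stratum=%s analysis=%s ERROR %s", stratum,
               analysis, conditionMessage(e))
          NULL
        })
      if (is.null(out)) next
      out$estimates$stratum <- stratum
      out$estimates$analysis <- analysis
      estimates[[paste(stratum, analysis)]] <- out$estimates
      heterogeneity[[paste(stratum, analysis)]] <- data.frame(
        stratum = stratum, analysis = analysis, q = out$het$q,
        df = out$het$df, pvalue = out$het$pvalue,
        i_squared = out$het$i_squared, stringsAsFactors = FALSE)
      intercepts[[paste(stratum, analysis)]] <- data.frame(
        stratum = stratum, analysis = analysis,
        intercept = out$egger$intercept$value,
        se = out$egger$intercept$se,
        pvalue = out$egger$intercept$pvalue, stringsAsFactors = FALSE)
      note("stage=estimate stratum=%s analysis=%s snps=%d", stratum,
           analysis, out$estimates$n_snps[1])
    }
  }
  if (!length(estimates)) stop("estimation error: no stratum succeeded")
  estimates <- do.call(rbind, c(estimates, make.row.names = FALSE))
  heterogeneity <- do.call(rbind, c(heterogeneity, make.row.names = FALSE))
  intercepts <- do.call(rbind, c(intercepts, make.row.names = FALSE))

  strata_het <- list()
  primary <- estimates[estimates$method == "likelihood" &
                         estimates$analysis == "main", ]
  for (gname in names(config$strata_groups)) {
    members <- intersect(config$strata_groups[[gname]], primary$stratum)
    if (length(members) >= 2) {
      h <- strata_heterogeneity(primary[primary$stratum %in% members, ])
      strata_het[[gname]] <- data.frame(
        group = gname, strata = paste(members, collapse = ","), q = h$q,
        df = h$df, pvalue = h$pvalue, i_squared = h$i_squared,
        stringsAsFactors = FALSE)
      note("stage=strata_heterogeneity group=%s p=%.3g", gname, h$pvalue)
    }
  }
  strata_het <- if (length(strata_het)) {
    do.call(rbind, c(strata_het, make.row.names = FALSE))
  }

  power <- NULL
  pw_strata <- config$power$strata
  if (is.null(pw_strata) && length(power_rows)) {
    pw_strata <- do.call(rbind, c(power_rows, make.row.names = FALSE))
  }
  if (!is.null(pw_strata)) {
    if (!is.data.frame(pw_strata)) {
      pw_strata <- do.call(rbind, lapply(pw_strata, as.data.frame))
    }
    power <- power_table(pw_strata, r2 = config$power$r2,
                         power = config$power$target_power,
                         alpha = config$power$alpha)
  }

  bundle <- structure(list(
    estimates = estimates, heterogeneity = heterogeneity,
    strata_heterogeneity = strata_het, egger_intercepts = intercepts,
    power = power, instrument_log = instrument_log, config = config,
    log = log_lines
  ), class = "mr_results_bundle")

  if (!is.null(config$output_dir)) .write_bundle(bundle, config$output_dir)
  invisible(bundle)
}

.estimate_stratum <- function(inst, est) {
  lik <- likelihood_estimate(inst, ci_method = est$ci_method)
  ivw <- ivw_estimate(inst, delta_order = est$delta_order)
  wm <- weighted_median_estimate(inst, n_boot = est$n_boot,
                                 seed = est$seed,
                                 delta_order = est$delta_order)
  egger <- egger_regression(inst)
  rows <- rbind(lik, ivw, wm, egger$slope)
  rows$primary <- rows$method == "likelihood"
  list(estimates = rows, het = snp_heterogeneity(inst, est$delta_order),
       egger = egger)
}

#' Flatten a results bundle into a forest-plot table
#'
#' One row per stratum x analysis x method with the odds ratio per exposure
#' SD, 95% CI, p-value, SNP count and the per-SNP heterogeneity p — the
#' columns needed to redraw a forest plot of the results.
#'
#' @param bundle result of [run_analysis()].
#' @return data frame.
#' @export
forest_table <- function(bundle) {
  stopifnot(inherits(bundle, "mr_results_bundle"),
            nrow(bundle$estimates) > 0)
  est <- bundle$estimates
  het <- bundle$heterogeneity
  key <- paste(est$stratum, est$analysis)
  est$p_het <- het$pvalue[match(key, paste(het$stratum, het$analysis))]
  cols <- c("stratum", "analysis", "method", "primary", "n_snps", "theta",
            "se", "ci_low", "ci_high", "or", "or_ci_low", "or_ci_high",
            "pvalue", "p_het")
  out <- as.data.frame(est)[, cols]
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out
}

.write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_results_table(forest_table(bundle), file.path(dir, "estimates.tsv"))
  .write_tsv(bundle$heterogeneity, file.path(dir, "heterogeneity.tsv"))
  if (!is.null(bundle$strata_heterogeneity)) {
    .write_tsv(bundle$strata_heterogeneity,
               file.path(dir, "strata_heterogeneity.tsv"))
  }
  .write_tsv(bundle$egger_intercepts, file.path(dir, "egger_intercepts.tsv"))
  if (!is.null(bundle$power)) {
    .write_tsv(bundle$power, file.path(dir, "power.tsv"))
  }
  excl <- do.call(rbind, lapply(names(bundle$instrument_log), function(s) {
    x <- bundle$instrument_log[[s]]
    if (is.null(x) || !nrow(x)) return(NULL)
    cbind(stratum = s, x)
  }))
  if (!is.null(excl)) .write_tsv(excl, file.path(dir, "snp_exclusions.tsv"))
  cfg <- bundle$config
  attributes(cfg) <- list(names = names(cfg))
  yaml::write_yaml(cfg, file.path(dir, "manifest.yaml"))
  writeLines(bundle$log, file.path(dir, "run.log"))
  invisible(dir)
}
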