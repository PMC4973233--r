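#' Default column dialect for summary-statistics tables
#'
#' Maps the canonical field names used throughout the package to the column
#' headers found in a particular file. GWAS consortia disagree on headers
#' (GIANT-style vs METAL-style), so every reader takes a dialect argument;
#' this function returns the package's documented default, optionally
#' overridden field by field.
#'
#' Canonical fields: `rsid`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#' `se`, `pvalue`, `info`, `n_cases`, `n_controls`. The first five plus `se`
#' are mandatory in a file only insofar as a record needs them: `rsid`,
#' `effect_allele`, `other_allele`, `beta` and `se` must be present; the rest
#' are optional columns.
#'
#' @param ... named overrides, e.g. `summary_dialect(rsid = "MarkerName",
#'   effect_allele = "A1")`.
#' @return named character vector mapping canonical field -> file column.
#' @export
#' @examples
#' summary_dialect()
#' summary_dialect(rsid = "SNP", beta = "b")
summary_dialect <- function(...) {
  d <- c(
    rsid = "rsid", effect_allele = "effect_allele",
    other_allele = "other_allele", eaf = "eaf", beta = "beta", se = "se",
    pvalue = "pvalue", info = "info", n_cases = "n_cases",
    n_controls = "n_controls"
  )
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(d))
    if (length(bad)) {
      stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    }
    d[names(over)] <- over
  }
  d
}

.mandatory_fields <- c("rsid", "effect_allele", "other_allele", "beta", "se")
.numeric_fields <- c("eaf", "beta", "se", "pvalue", "info",
                     "n_cases", "n_controls")

#' Construct a table of per-variant association records
#'
#' Validates and classes a data frame of per-SNP summary statistics. One row
#' per variant; `beta` is the per-allele effect (exposure-SD units for
#' exposure studies, log-odds for case-control outcome studies) on
#' `effect_allele`. Rows violating a record invariant (non-ACGT or identical
#' alleles, `se <= 0`, frequencies or imputation-quality scores outside
#' [0, 1], p-values outside (0, 1]) are dropped and enumerated in the
#' `rejected` attribute together with their input row numbers.
#'
#' @param df data frame with canonical columns (see [summary_dialect()]).
#' @param source optional label recorded in the `source` attribute.
#' @return a `variant_assoc` data frame with attributes `rejected`
#'   (data frame of row/rsid/reason) and `source`.
#' @export
variant_assoc <- function(df, source = NA_character_) {
  stopifnot(is.data.frame(df))
  for (f in setdiff(.mandatory_fields, names(df))) {
    stop("missing mandatory column: ", f)
  }
  out <- data.frame(rsid = as.character(df$rsid), stringsAsFactors = FALSE)
  out$effect_allele <- toupper(as.character(df$effect_allele))
  out$other_allele <- toupper(as.character(df$other_allele))
  for (f in .numeric_fields) {
    out[[f]] <- if (f %in% names(df)) suppressWarnings(as.numeric(df[[f]])) else NA_real_
  }
  row_in <- if (!is.null(df$.row)) df$.row else seq_len(nrow(df))

  reasons <- character(nrow(out))
  flag <- function(bad, why) {
    bad <- which(bad & !nzchar(reasons))
    reasons[bad] <<- why
  }
  bases <- c("A", "C", "G", "T")
  flag(is.na(out$rsid) | !nzchar(out$rsid), "missing rsid")
  flag(!(out$effect_allele %in% bases) | !(out$other_allele %in% bases),
       "allele not a single A/C/G/T base")
  flag(out$effect_allele == out$other_allele, "identical alleles")
  flag(is.na(out$beta), "unparseable beta")
  flag(is.na(out$se) | out$se <= 0, "missing or non-positive se")
  flag(!is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1), "eaf outside [0,1]")
  flag(!is.na(out$info) & (out$info < 0 | out$info > 1), "info outside [0,1]")
  flag(!is.na(out$pvalue) & (out$pvalue <= 0 | out$pvalue > 1),
       "pvalue outside (0,1]")

  rejected <- data.frame(
    row = row_in[nzchar(reasons)],
    rsid = out$rsid[nzchar(reasons)],
    reason = reasons[nzchar(reasons)],
    stringsAsFactors = FALSE
  )
  out <- out[!nzchar(reasons), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            rejected = rejected, source = source,
            class = c("variant_assoc", "data.frame"))
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-delimited file with a header row, renames columns through the
#' dialect mapping, and validates records via [variant_assoc()]. Rejected
#' rows are reported (with input row numbers) as a message and kept in the
#' `rejected` attribute of the result; empty cells denote missing optional
#' values.
#'
#' @param path file path.
#' @param dialect column mapping from [summary_dialect()].
#' @return a `variant_assoc` data frame.
#' @export
read_summary_stats <- function(path, dialect = summary_dialect()) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"))
  if (nrow(raw) == 0L) stop("input error: no data rows in ", path)
  for (f in .mandatory_fields) {
    if (!dialect[[f]] %in% names(raw)) {
      stop("configuration error: mandatory column '", dialect[[f]],
           "' (field ", f, ") absent from ", path)
    }
  }
  present <- names(dialect)[dialect %in% names(raw)]
  df <- stats::setNames(raw[, dialect[present], drop = FALSE], present)
  df$.row <- seq_len(nrow(raw)) + 1L  # 1-based file line, after the header
  va <- variant_assoc(df, source = path)
  rej <- attr(va, "rejected")
  if (nrow(rej)) {
    message(sprintf("read_summary_stats: rejected %d row(s) of %s: %s",
                    nrow(rej), basename(path),
                    paste(sprintf("line %d (%s)", rej$row, rej$reason),
                          collapse = "; ")))
  }
  va
}

#' Write a summary-statistics table
#'
#' Inverse of [read_summary_stats()]: writes the canonical columns
#' tab-delimited under the dialect's headers, missing values as empty cells
#' (never 0 — zero is a legal frequency and effect). Numeric fields carry 15
#' significant digits so a read-back round trip is exact well beyond 6
#' significant digits.
#'
#' @param x a `variant_assoc` data frame.
#' @param path output path.
#' @param dialect column mapping.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path, dialect = summary_dialect()) {
  stopifnot(is.data.frame(x))
  keep <- names(dialect)[vapply(names(dialect), function(f) {
    f %in% .mandatory_fields || (f %in% names(x) && any(!is.na(x[[f]])))
  }, logical(1))]
  out <- x[, keep, drop = FALSE]
  for (f in intersect(keep, .numeric_fields)) {
    v <- out[[f]]
    out[[f]] <- ifelse(is.na(v), "", formatC(v, digits = 15, format = "g"))
  }
  names(out) <- dialect[keep]
  .write_tsv(out, path)
}

.write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read an individual-level genotype/phenotype table
#'
#' Tab-delimited, one subject per row. Dosage columns are named by rsID
#' (values in [0, 2], empty = missing); principal components are `pc1`,
#' `pc2`, ...; recognized phenotype/covariate columns are `bmi`, `cpd`,
#' `pack_years`, `cotinine`, `case_status`, `age`, `sex`.
#'
#' @param path file path.
#' @param snp_cols optional explicit character vector of dosage columns;
#'   default: every column whose name starts with "rs".
#' @return an `individual_data` data frame; attribute `snps` holds the
#'   dosage column names.
#' @export
read_individual_data <- function(path, snp_cols = NULL) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, na.strings = c("", "NA"))
  if (nrow(df) == 0L) stop("input error: no data rows in ", path)
  if (is.null(snp_cols)) snp_cols <- grep("^rs", names(df), value = TRUE)
  if (!length(snp_cols)) stop("input error: no dosage columns found")
  for (s in snp_cols) {
    d <- df[[s]]
    if (any(!is.na(d) & (d < 0 | d > 2))) {
      stop("input error: dosages outside [0,2] in column ", s)
    }
  }
  structure(df, snps = snp_cols,
            class = c("individual_data", "data.frame"))
}

#' Write an individual-level table
#' @param x data frame from [read_individual_data()] or
#'   [simulate_individual_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_individual_data <- function(x, path) .write_tsv(as.data.frame(x), path)

#' Write causal-estimate / meta-analysis results as TSV
#'
#' Emits one row per estimate with method, stratum, SNP count, the causal
#' effect on the log-odds scale and the odds-ratio scale, 95% CI bounds on
#' both scales, and the p-value. Values are written with 15 significant
#' digits; a read-back reproduces them to at least 6 significant digits.
#'
#' @param records a data frame of estimates (rows from [causal_estimate()]
#'   or [fixed_effects_pool()], e.g. a [forest_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("input error: no records to write")
  out <- as.data.frame(records)
  if (is.null(out$stratum)) out$stratum <- NA_character_
  if (is.null(out$or) && !is.null(out$theta)) {
    out$or <- exp(out$theta)
    out$or_ci_low <- exp(out$ci_low)
    out$or_ci_high <- exp(out$ci_high)
  }
  lead <- intersect(c("stratum", "method", "n_snps", "theta", "se",
                      "ci_low", "ci_high", "or", "or_ci_low", "or_ci_high",
                      "pvalue"), names(out))
  out <- out[, c(lead, setdiff(names(out), lead)), drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), "", formatC(v, digits = 15, format = "g"))
  })
  .write_tsv(out, path)
}

#' Read back a results table written by [write_results_table()]
#' @param path file path.
#' @return data frame with numeric columns restored.
#' @export
read_results_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, na.strings = c("", "NA"))
  df
}
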