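#' Harmonize exposure and outcome summary statistics
#'
#' Pairs exposure and outcome records by rsID and expresses both effects on
#' a single effect allele per SNP: the allele that increases the exposure.
#' Resolves allele-label swaps (outcome beta negated, frequency
#' complemented) and strand flips (allele letters complemented); palindromic
#' variants (A/T, C/G), whose strand cannot be read off the allele letters,
#' are handled per `palindromic_policy`:
#'
#' * `"align_freq"` (default): keep the SNP when both studies report an
#'   allele frequency outside the ambiguity window, and flip the outcome
#'   strand when the frequencies disagree about which allele is the minor
#'   one; drop when either frequency is missing or inside the window.
#' * `"drop"`: exclude all palindromic SNPs.
#' * `"keep"`: take allele labels at face value (assume same strand).
#'
#' SNPs whose allele pairs cannot be reconciled under any of the four
#' strand/label configurations are excluded with a reason; exclusions are
#' returned in the `excluded` attribute.
#'
#' @param exposure,outcome `variant_assoc` data frames (see
#'   [read_summary_stats()]); exposure betas in exposure-SD units, outcome
#'   betas in log-odds.
#' @param palindromic_policy one of `"align_freq"`, `"drop"`, `"keep"`.
#' @param eaf_window numeric length 2: the allele-frequency ambiguity window
#'   for `"align_freq"` (default 0.42-0.58).
#' @return a `harmonized_instruments` data frame with columns `rsid`,
#'   `effect_allele`, `other_allele`, `beta_gp`, `se_gp`, `beta_gd`,
#'   `se_gd`, `eaf_exposure`, `eaf_outcome`, `info`, `palindromic`,
#'   `allele_flipped`; `beta_gp >= 0` for every row. Attribute `excluded`
#'   enumerates dropped SNPs with reasons.
#' @export
harmonize <- function(exposure, outcome,
                      palindromic_policy = c("align_freq", "drop", "keep"),
                      eaf_window = c(0.42, 0.58)) {
  palindromic_policy <- match.arg(palindromic_policy)
  exposure <- .dedupe_rsid(exposure, "exposure")
  outcome <- .dedupe_rsid(outcome, "outcome")
  shared <- intersect(exposure$rsid, outcome$rsid)
  if (!length(shared)) stop("input error: no shared rsids between studies")
  ex <- exposure[match(shared, exposure$rsid), ]
  ou <- outcome[match(shared, outcome$rsid), ]

  comp <- function(a) chartr("ACGT", "TGCA", a)
  pal <- ex$effect_allele == comp(ex$other_allele)

  # classify the outcome record's configuration relative to the exposure's
  same <- ou$effect_allele == ex$effect_allele &
    ou$other_allele == ex$other_allele
  swap <- ou$effect_allele == ex$other_allele &
    ou$other_allele == ex$effect_allele
  fsame <- comp(ou$effect_allele) == ex$effect_allele &
    comp(ou$other_allele) == ex$other_allele
  fswap <- comp(ou$effect_allele) == ex$other_allele &
    comp(ou$other_allele) == ex$effect_allele

  reason <- character(length(shared))
  reason[!(same | swap | fsame | fswap)] <- "irreconcilable allele pair"

  # label orientation: does the outcome effect allele map onto the exposure
  # effect allele (possibly through a strand flip)?
  flip_label <- (swap | fswap) & !pal
  beta_gd <- ifelse(flip_label, -ou$beta, ou$beta)
  eaf_out <- ifelse(flip_label, 1 - ou$eaf, ou$eaf)
  flipped <- flip_label

  if (palindromic_policy == "drop") {
    reason[pal & !nzchar(reason)] <- "palindromic (policy: drop)"
  } else if (palindromic_policy == "keep") {
    lab_swap <- pal & ou$effect_allele == ex$other_allele
    beta_gd[lab_swap] <- -ou$beta[lab_swap]
    eaf_out[lab_swap] <- 1 - ou$eaf[lab_swap]
    flipped[lab_swap] <- TRUE
  } else { # align_freq
    amb <- pal & (is.na(ex$eaf) | is.na(ou$eaf) |
                    (ex$eaf >= eaf_window[1] & ex$eaf <= eaf_window[2]) |
                    (ou$eaf >= eaf_window[1] & ou$eaf <= eaf_window[2]))
    reason[amb & !nzchar(reason)] <-
      "palindromic with ambiguous or missing allele frequency"
    res <- pal & !amb
    # orient by label first, then flip strand if frequencies disagree
    lab_swap <- res & ou$effect_allele == ex$other_allele
    beta_gd[lab_swap] <- -ou$beta[lab_swap]
    eaf_out[lab_swap] <- 1 - ou$eaf[lab_swap]
    flipped[lab_swap] <- TRUE
    disc <- res & (ex$eaf - 0.5) * (eaf_out - 0.5) < 0
    beta_gd[disc] <- -beta_gd[disc]
    eaf_out[disc] <- 1 - eaf_out[disc]
    flipped[disc] <- xor(flipped[disc], TRUE)
  }

  # orient to the exposure-increasing allele
  neg <- ex$beta < 0
  h <- data.frame(
    rsid = shared,
    effect_allele = ifelse(neg, ex$other_allele, ex$effect_allele),
    other_allele = ifelse(neg, ex$effect_allele, ex$other_allele),
    beta_gp = abs(ex$beta),
    se_gp = ex$se,
    beta_gd = ifelse(neg, -beta_gd, beta_gd),
    se_gd = ou$se,
    eaf_exposure = ifelse(neg, 1 - ex$eaf, ex$eaf),
    eaf_outcome = ifelse(neg, 1 - eaf_out, eaf_out),
    info = ou$info,
    palindromic = pal,
    allele_flipped = xor(flipped, neg),
    stringsAsFactors = FALSE
  )
  excluded <- data.frame(rsid = shared[nzchar(reason)],
                         reason = reason[nzchar(reason)],
                         stringsAsFactors = FALSE)
  h <- h[!nzchar(reason), , drop = FALSE]
  rownames(h) <- NULL
  structure(h, excluded = excluded,
            class = c("harmonized_instruments", "data.frame"))
}

.dedupe_rsid <- function(x, what) {
  dup <- duplicated(x$rsid)
  if (any(dup)) {
    warning(sum(dup), " duplicated rsid(s) in ", what,
            " study; keeping first occurrence")
    x <- x[!dup, , drop = FALSE]
  }
  x
}

.append_excluded <- function(h, rsid, reason) {
  ex <- attr(h, "excluded")
  if (is.null(ex)) {
    ex <- data.frame(rsid = character(), reason = character(),
                     stringsAsFactors = FALSE)
  }
  attr(h, "excluded") <- rbind(ex, data.frame(rsid = rsid, reason = reason,
                                              stringsAsFactors = FALSE))
  h
}

#' Filter instruments by imputation quality
#'
#' Retains SNPs whose imputation-quality (info) score is strictly greater
#' than the threshold. SNPs with no info score are treated as directly
#' genotyped and kept. Exclusions are appended to the `excluded` attribute.
#'
#' @param instruments `harmonized_instruments` data frame.
#' @param info optional named numeric vector (rsid -> info) overriding the
#'   `info` column carried from the outcome study.
#' @param threshold info threshold in [0, 1]; comparison is strict
#'   (`info > threshold`). Default 0.6.
#' @return filtered `harmonized_instruments`.
#' @export
filter_by_info <- function(instruments, info = NULL, threshold = 0.6) {
  stopifnot(threshold >= 0, threshold <= 1)
  sc <- if (is.null(info)) instruments$info else unname(info[instruments$rsid])
  drop <- !is.na(sc) & sc <= threshold
  out <- instruments[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out <- .restore_class(out, instruments)
  if (any(drop)) {
    out <- .append_excluded(out, instruments$rsid[drop],
                            sprintf("info %.3g <= %.3g", sc[drop], threshold))
  }
  out
}

#' Remove named SNPs from an instrument set
#'
#' Used for leave-out sensitivity analyses (e.g. removing a variant with a
#' reported direct association with the outcome's major risk factor).
#' Requesting an absent rsID raises a warning, not an error.
#'
#' @param instruments `harmonized_instruments` data frame.
#' @param rsids character vector of rsIDs to drop, or a path to a plain-text
#'   file of rsIDs, one per line.
#' @return filtered `harmonized_instruments`.
#' @export
exclude_snps <- function(instruments, rsids) {
  if (length(rsids) == 1L && file.exists(rsids)) {
    rsids <- readLines(rsids, warn = FALSE)
    rsids <- trimws(rsids)[nzchar(trimws(rsids))]
  }
  if (!length(rsids)) return(instruments)
  absent <- setdiff(rsids, instruments$rsid)
  if (length(absent)) {
    warning("rsid(s) not present, ignored: ", paste(absent, collapse = ", "))
  }
  drop <- instruments$rsid %in% rsids
  out <- instruments[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out <- .restore_class(out, instruments)
  if (any(drop)) {
    out <- .append_excluded(out, instruments$rsid[drop], "excluded by request")
  }
  if (nrow(out) == 0L) warning("exclusion removed every instrument")
  out
}

.restore_class <- function(out, template) {
  attr(out, "excluded") <- attr(template, "excluded")
  class(out) <- class(template)
  out
}
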