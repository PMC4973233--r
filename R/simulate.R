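#' Configuration for a synthetic two-sample MR dataset
#'
#' Bundles every knob of the generator. Defaults emulate the study design
#' the package targets: a 97-SNP instrument explaining 2.7% of exposure
#' variance estimated in a 339,224-subject exposure GWAS, evaluated against
#' a case-control outcome GWAS of 16,572 cases and 21,480 controls.
#'
#' @param j_snps number of instrument SNPs (default 97).
#' @param theta true causal log-odds per exposure SD (default 0).
#' @param r2_target exposure variance explained by the instrument, in
#'   (0, 1) (default 0.027).
#' @param n_exposure exposure-GWAS sample size (default 339224).
#' @param n_cases,n_controls outcome-GWAS counts (defaults 16572 / 21480).
#' @param pleiotropy scenario: `"none"`, `"balanced"` (direct effects
#'   N(0, tau^2)), `"directional"` (N(mu, tau^2)), or `"inside_violated"`
#'   (direct effect `rho * xi_j`, correlating instrument strength with
#'   pleiotropy).
#' @param mu,tau,rho pleiotropy parameters (see `pleiotropy`).
#' @param invalid_fraction share of SNPs receiving a direct effect, in
#'   [0, 1].
#' @param maf_range effect-allele frequency bounds (default 0.05-0.5).
#' @param palindromic_fraction share of SNPs given A/T or C/G alleles
#'   (default 0.2).
#' @param swap_fraction probability a study reports a record with allele
#'   labels exchanged (default 0.3).
#' @param flip_fraction probability an outcome record is reported on the
#'   opposite strand (default 0.3).
#' @param low_info_fraction share of outcome SNPs assigned an imputation
#'   quality in (0.3, 0.6] (default 0; the rest get info in (0.8, 1)).
#' @param seed integer RNG seed (mandatory: every draw is seeded).
#' @param panel_seed optional separate seed for the instrument panel
#'   (frequencies, true effects, alleles); defaults to `seed`. Fixing it
#'   while varying `seed` draws noise replicates over one panel.
#' @return a `mr_sim_config` list.
#' @export
sim_config <- function(j_snps = 97, theta = 0, r2_target = 0.027,
                       n_exposure = 339224, n_cases = 16572,
                       n_controls = 21480,
                       pleiotropy = c("none", "balanced", "directional",
                                      "inside_violated"),
                       mu = 0, tau = 0, rho = 0, invalid_fraction = 0,
                       maf_range = c(0.05, 0.5), palindromic_fraction = 0.2,
                       swap_fraction = 0.3, flip_fraction = 0.3,
                       low_info_fraction = 0, seed, panel_seed = NULL) {
  pleiotropy <- match.arg(pleiotropy)
  if (missing(seed)) stop("configuration error: seed is required")
  stopifnot(j_snps >= 1, r2_target > 0, r2_target < 1,
            n_exposure >= 1, n_cases >= 1, n_controls >= 1,
            invalid_fraction >= 0, invalid_fraction <= 1, tau >= 0,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            palindromic_fraction >= 0, palindromic_fraction <= 1)
  structure(list(
    j_snps = as.integer(j_snps), theta = theta, r2_target = r2_target,
    n_exposure = n_exposure, n_cases = n_cases, n_controls = n_controls,
    pleiotropy = pleiotropy, mu = mu, tau = tau, rho = rho,
    invalid_fraction = invalid_fraction, maf_range = maf_range,
    palindromic_fraction = palindromic_fraction,
    swap_fraction = swap_fraction, flip_fraction = flip_fraction,
    low_info_fraction = low_info_fraction, seed = as.integer(seed),
    panel_seed = as.integer(if (is.null(panel_seed)) seed else panel_seed)
  ), class = "mr_sim_config")
}

# the instrument panel shared by summary- and individual-level generators:
# frequencies, true per-allele effects (rescaled so sum 2f(1-f)xi^2 equals
# r2_target), canonical alleles, rsids. Deterministic given the config seed.
.sim_panel <- function(config) {
  set.seed(config$panel_seed)
  j <- config$j_snps
  f <- stats::runif(j, config$maf_range[1], config$maf_range[2])
  xi_raw <- 0.3 + abs(stats::rnorm(j))  # floor keeps every instrument usable
  xi <- xi_raw * sqrt(config$r2_target / sum(2 * f * (1 - f) * xi_raw^2))
  pal <- stats::runif(j) < config$palindromic_fraction
  ea <- oa <- character(j)
  pal_pairs <- matrix(c("A", "T", "C", "G"), 2)
  for (k in seq_len(j)) {
    if (pal[k]) {
      p <- pal_pairs[, sample(2, 1)]
      if (sample(2, 1) == 2) p <- rev(p)
    } else {
      repeat {
        p <- sample(c("A", "C", "G", "T"), 2)
        if (chartr("ACGT", "TGCA", p[1]) != p[2]) break
      }
    }
    ea[k] <- p[1]; oa[k] <- p[2]
  }
  invalid <- rep(FALSE, j)
  n_inv <- round(config$invalid_fraction * j)
  if (n_inv > 0) invalid[sample(j, n_inv)] <- TRUE
  alpha <- numeric(j)
  if (config$pleiotropy == "balanced") {
    alpha[invalid] <- stats::rnorm(sum(invalid), 0, config$tau)
  } else if (config$pleiotropy == "directional") {
    alpha[invalid] <- stats::rnorm(sum(invalid), config$mu, config$tau)
  } else if (config$pleiotropy == "inside_violated") {
    alpha[invalid] <- config$rho * xi[invalid]
  }
  list(rsid = sprintf("rs%07d", 1000000L + seq_len(j)), f = f, xi = xi,
       ea = ea, oa = oa, pal = pal, alpha = alpha, invalid = invalid)
}

#' Simulate two-sample MR summary statistics
#'
#' Draws a synthetic exposure GWAS and outcome GWAS over a shared
#' instrument panel. True per-SNP exposure effects are rescaled so the
#' instrument explains exactly `r2_target` of exposure variance; observed
#' effects are normal about the truth with the standard GWAS standard-error
#' approximations `se_gp = 1/sqrt(2 f (1-f) N_exposure)` and
#' `se_gd = 1/sqrt(2 f (1-f) N phi (1-phi))`. The true outcome effect is
#' `theta * xi_j` plus a direct (pleiotropic) effect under the configured
#' scenario. Reported allele labels, strands and the effect-allele
#' orientation are randomized per study to exercise [harmonize()]; reported
#' frequencies get small sampling noise.
#'
#' @param config a [sim_config()].
#' @return list with `exposure` and `outcome` (`variant_assoc` data
#'   frames) and `truth` (theta, per-SNP xi, alpha, f, the canonical
#'   exposure-increasing allele, and the invalid-SNP flags).
#' @export
simulate_summary_mr <- function(config) {
  stopifnot(inherits(config, "mr_sim_config"))
  panel <- .sim_panel(config)
  set.seed(config$seed + 9973L)  # noise stream, separable from the panel
  j <- config$j_snps
  f <- panel$f
  se_gp <- 1 / sqrt(2 * f * (1 - f) * config$n_exposure)
  n <- config$n_cases + config$n_controls
  phi <- config$n_cases / n
  se_gd <- 1 / sqrt(2 * f * (1 - f) * n * phi * (1 - phi))
  bgp <- stats::rnorm(j, panel$xi, se_gp)
  bgd <- stats::rnorm(j, config$theta * panel$xi + panel$alpha, se_gd)
  eaf_x <- pmin(pmax(f + stats::rnorm(j, 0, 0.004), 0.001), 0.999)
  eaf_y <- pmin(pmax(f + stats::rnorm(j, 0, 0.004), 0.001), 0.999)

  info <- stats::runif(j, 0.8, 1)
  low <- stats::runif(j) < config$low_info_fraction
  info[low] <- stats::runif(sum(low), 0.3, 0.6)

  exposure <- .present_record(panel, bgp, se_gp, eaf_x,
                              swap = stats::runif(j) < config$swap_fraction,
                              flip = rep(FALSE, j))
  outcome <- .present_record(panel, bgd, se_gd, eaf_y,
                             swap = stats::runif(j) < config$swap_fraction,
                             flip = stats::runif(j) < config$flip_fraction)
  outcome$info <- info
  outcome$n_cases <- config$n_cases
  outcome$n_controls <- config$n_controls
  list(
    exposure = variant_assoc(exposure, source = "simulated exposure GWAS"),
    outcome = variant_assoc(outcome, source = "simulated outcome GWAS"),
    truth = list(theta = config$theta, rsid = panel$rsid, xi = panel$xi,
                 alpha = panel$alpha, f = f, effect_allele = panel$ea,
                 invalid = panel$invalid)
  )
}

# express a study's records with randomized label swaps and strand flips;
# beta/eaf are stated on the canonical effect allele panel$ea
.present_record <- function(panel, beta, se, eaf, swap, flip) {
  ea <- panel$ea; oa <- panel$oa
  b <- beta; fr <- eaf
  # label swap: report the other allele as effect allele
  ea[swap] <- panel$oa[swap]; oa[swap] <- panel$ea[swap]
  b[swap] <- -b[swap]; fr[swap] <- 1 - fr[swap]
  # strand flip: non-palindromic letters complement (same physical allele);
  # palindromic letters are unchanged but now name the complementary allele
  npal <- flip & !panel$pal
  ea[npal] <- chartr("ACGT", "TGCA", ea[npal])
  oa[npal] <- chartr("ACGT", "TGCA", oa[npal])
  ppal <- flip & panel$pal
  b[ppal] <- -b[ppal]; fr[ppal] <- 1 - fr[ppal]
  data.frame(rsid = panel$rsid, effect_allele = ea, other_allele = oa,
             eaf = fr, beta = b, se = se,
             # floor against underflow for very strong associations
             pvalue = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300),
             stringsAsFactors = FALSE)
}

#' Simulate an individual-level cohort over the instrument panel
#'
#' Genotypes are Hardy-Weinberg binomial draws at the panel frequencies
#' (SNPs independent, matching an instrument pruned of linkage
#' disequilibrium). The exposure in SD units is the true weighted genotype
#' sum plus age, sex and principal-component effects plus normal noise
#' calibrated so the genetic score explains `r2_target` of its variance;
#' it is reported in raw units via the SD calibration (1 SD = 4.65 kg/m^2
#' around a mean of 27.4). Smoking phenotypes (cigarettes per day,
#' pack-years, cotinine) are generated independently of the score when
#' `smoking_independent` (the validity scenario), else with a linear leak
#' of the genetic score into smoking intensity. Case status follows a
#' logistic model on smoking and, through `theta`, the exposure.
#'
#' @param config a [sim_config()]; the SNP panel (frequencies, effects,
#'   alleles) is shared with [simulate_summary_mr()] for the same config.
#' @param n_subjects cohort size (>= 100).
#' @param smoking_independent logical (default TRUE).
#' @param smoking_leak score-to-smoking-intensity coefficient used when
#'   `smoking_independent = FALSE` (default 0.5 CPD per unit score SD).
#' @return an `individual_data` data frame: one dosage column per rsID,
#'   `bmi`, `cpd`, `pack_years`, `cotinine`, `case_status`, `age`, `sex`,
#'   `pc1`..`pc5`. Attribute `truth` carries the generating panel.
#' @export
simulate_individual_cohort <- function(config, n_subjects,
                                       smoking_independent = TRUE,
                                       smoking_leak = 0.5) {
  stopifnot(inherits(config, "mr_sim_config"), n_subjects >= 100)
  panel <- .sim_panel(config)
  set.seed(config$seed + 104729L)  # distinct stream from the summary draws
  j <- config$j_snps
  g <- vapply(seq_len(j),
              function(k) stats::rbinom(n_subjects, 2, panel$f[k]),
              numeric(n_subjects))
  colnames(g) <- panel$rsid
  s <- drop(g %*% panel$xi)                     # genetic value, exposure-SD units

  age <- stats::rnorm(n_subjects, 60, 8)
  sex <- stats::rbinom(n_subjects, 1, 0.5)
  pcs <- matrix(stats::rnorm(n_subjects * 5), n_subjects, 5,
                dimnames = list(NULL, paste0("pc", 1:5)))
  b_age <- 0.10; b_sex <- 0.10; b_pc <- 0.02
  cov_eff <- b_age * scale(age)[, 1] + b_sex * sex + drop(pcs %*% rep(b_pc, 5))
  var_cov <- b_age^2 + b_sex^2 * 0.25 + 5 * b_pc^2
  var_eps <- max(1 - config$r2_target - var_cov, 0.05)
  bmi_sd <- s - mean(s) + cov_eff + stats::rnorm(n_subjects, 0, sqrt(var_eps))
  bmi <- 27.4 + 4.65 * bmi_sd

  ever <- stats::rbinom(n_subjects, 1, 0.66)
  leak <- if (smoking_independent) 0 else smoking_leak * scale(s)[, 1]
  cpd <- ever * pmax(stats::rnorm(n_subjects, 18, 9) + leak, 0)
  pack_years <- ever * pmax(stats::rnorm(n_subjects, 25, 15) + 1.2 * leak, 0)
  cotinine <- ever * pmax(stats::rnorm(n_subjects, 250, 120) + 10 * leak, 0)

  lp <- -1.4 + 1.3 * ever + config$theta * bmi_sd
  case_status <- stats::rbinom(n_subjects, 1, stats::plogis(lp))

  out <- data.frame(g, bmi = bmi, cpd = cpd, pack_years = pack_years,
                    cotinine = cotinine, case_status = case_status,
                    age = age, sex = sex, pcs, check.names = FALSE)
  structure(out, snps = panel$rsid, truth = panel,
            class = c("individual_data", "data.frame"))
}

#' Write a ready-made synthetic study directory
#'
#' Emits a complete fixture for the full pipeline: one exposure
#' summary-statistics file, three outcome-study files (sample sizes split
#' roughly as a large consortium plus two smaller genotyping efforts, each
#' with its own imputation-quality pattern), an individual-level table and
#' a JSON truth record, all in the TSV dialects [read_summary_stats()]
#' reads back.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param n_subjects individual-level cohort size (default 2000).
#' @param low_info_counts integer vector: how many SNPs per outcome study
#'   get imputation quality <= 0.6 (default `c(5, 1, 32)`).
#' @return named list of the file paths written.
#' @export
write_study_fixture <- function(config, dir, n_subjects = 2000,
                                low_info_counts = c(5, 1, 32)) {
  stopifnot(inherits(config, "mr_sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  panel <- .sim_panel(config)
  j <- config$j_snps
  case_split <- c(0.70, 0.09, 0.21)
  ctrl_split <- c(0.74, 0.07, 0.19)
  study <- c("consortium", "oncoarray", "axiom")
  paths <- list()

  sim <- simulate_summary_mr(config)
  paths$exposure <- file.path(dir, "exposure.tsv")
  write_summary_stats(sim$exposure, paths$exposure)

  set.seed(config$seed + 7919L)
  n <- config$n_cases + config$n_controls
  for (i in seq_along(study)) {
    nca <- max(1L, round(config$n_cases * case_split[i]))
    nco <- max(1L, round(config$n_controls * ctrl_split[i]))
    phi <- nca / (nca + nco)
    se_gd <- 1 / sqrt(2 * panel$f * (1 - panel$f) * (nca + nco) *
                        phi * (1 - phi))
    bgd <- stats::rnorm(j, config$theta * panel$xi + panel$alpha, se_gd)
    eaf <- pmin(pmax(panel$f + stats::rnorm(j, 0, 0.004), 0.001), 0.999)
    rec <- .present_record(panel, bgd, se_gd, eaf,
                           swap = stats::runif(j) < config$swap_fraction,
                           flip = stats::runif(j) < config$flip_fraction)
    info <- stats::runif(j, 0.8, 1)
    k <- min(low_info_counts[i], j)
    if (k > 0) info[sample(j, k)] <- stats::runif(k, 0.3, 0.6)
    rec$info <- info
    rec$n_cases <- nca
    rec$n_controls <- nco
    paths[[paste0("outcome_", study[i])]] <-
      file.path(dir, paste0("outcome_", study[i], ".tsv"))
    write_summary_stats(variant_assoc(rec),
                        paths[[paste0("outcome_", study[i])]])
  }

  cohort <- simulate_individual_cohort(config, n_subjects)
  paths$individual <- file.path(dir, "individual.tsv")
  write_individual_data(cohort, paths$individual)

  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(theta = config$theta, r2_target = config$r2_target,
         seed = config$seed, rsid = panel$rsid, xi = panel$xi, f = panel$f,
         alpha = panel$alpha, effect_allele = panel$ea,
         invalid = panel$invalid),
    paths$truth, auto_unbox = TRUE, digits = NA)
  paths
}
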