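# in-code fixture builders shared across test files

# a harmonized instrument set from raw vectors (already oriented beta_gp >= 0)
make_instruments <- function(beta_gp, se_gp, beta_gd, se_gd,
                             rsid = sprintf("rs%04d", seq_along(beta_gp))) {
  structure(
    data.frame(rsid = rsid,
               effect_allele = "A", other_allele = "G",
               beta_gp = beta_gp, se_gp = se_gp,
               beta_gd = beta_gd, se_gd = se_gd,
               eaf_exposure = 0.3, eaf_outcome = 0.3, info = NA_real_,
               palindromic = FALSE, allele_flipped = FALSE,
               stringsAsFactors = FALSE),
    class = c("harmonized_instruments", "data.frame"))
}

# random harmonized set with realistic GWAS-scale effects and SEs
random_instruments <- function(j, seed, theta = 0.2) {
  set.seed(seed)
  beta_gp <- 0.01 + abs(rnorm(j, 0.02, 0.01))
  se_gp <- runif(j, 0.002, 0.004)
  se_gd <- runif(j, 0.01, 0.03)
  beta_gd <- theta * beta_gp + rnorm(j, 0, se_gd)
  make_instruments(beta_gp, se_gp, beta_gd, se_gd)
}

# a minimal variant_assoc table from vectors
make_va <- function(rsid, ea, oa, beta, se, eaf = NA_real_,
                    info = NA_real_) {
  variant_assoc(data.frame(
    rsid = rsid, effect_allele = ea, other_allele = oa, beta = beta,
    se = se, eaf = eaf, info = info, stringsAsFactors = FALSE))
}
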