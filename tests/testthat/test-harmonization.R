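test_that("outcome effects are re-expressed on the exposure-increasing allele", {
  # outcome reported on the opposite allele: beta negated
  ex <- make_va("rs1", "A", "G", beta = 0.03, se = 0.003, eaf = 0.3)
  ou <- make_va("rs1", "G", "A", beta = 0.10, se = 0.02, eaf = 0.7)
  h <- harmonize(ex, ou)
  expect_equal(h$effect_allele, "A")
  expect_equal(h$beta_gd, -0.10)
  expect_equal(h$eaf_outcome, 0.3)

  # negative exposure effect: allele roles swap so beta_gp >= 0
  ex <- make_va("rs2", "C", "T", beta = -0.02, se = 0.003, eaf = 0.6)
  ou <- make_va("rs2", "C", "T", beta = 0.05, se = 0.02, eaf = 0.6)
  h <- harmonize(ex, ou)
  expect_equal(h$effect_allele, "T")
  expect_equal(h$beta_gp, 0.02)
  expect_equal(h$beta_gd, -0.05)
  expect_equal(h$eaf_exposure, 0.4)

  # strand flip only: same physical allele, letters complemented
  ex <- make_va("rs3", "A", "G", beta = 0.03, se = 0.003, eaf = 0.3)
  ou <- make_va("rs3", "T", "C", beta = 0.07, se = 0.02, eaf = 0.3)
  h <- harmonize(ex, ou)
  expect_equal(h$beta_gd, 0.07)
  expect_false(h$allele_flipped)
})

test_that("irreconcilable and absent SNPs are excluded with reasons", {
  ex <- make_va(c("rs1", "rs2"), c("A", "A"), c("C", "G"),
                beta = c(0.03, 0.02), se = c(0.003, 0.003))
  ou <- make_va(c("rs1", "rs9"), c("A", "A"), c("G", "G"),
                beta = c(0.1, 0.1), se = c(0.02, 0.02))
  h <- harmonize(ex, ou)
  expect_equal(nrow(h), 0L)
  expect_equal(attr(h, "excluded")$rsid, "rs1")
  expect_match(attr(h, "excluded")$reason, "irreconcilable")
  expect_error(harmonize(make_va("rsX", "A", "G", 0.1, 0.1), ou),
               "no shared rsids")
})

test_that("palindromic SNPs follow the configured policy", {
  ex <- make_va("rs1", "A", "T", beta = 0.03, se = 0.003, eaf = 0.10)
  # frequencies disagree -> outcome record is on the other strand
  ou <- make_va("rs1", "A", "T", beta = 0.08, se = 0.02, eaf = 0.88)
  h <- harmonize(ex, ou, palindromic_policy = "align_freq")
  expect_equal(nrow(h), 1L)
  expect_equal(h$beta_gd, -0.08)
  expect_equal(h$eaf_outcome, 0.12)
  expect_true(h$palindromic)

  expect_equal(nrow(harmonize(ex, ou, palindromic_policy = "drop")), 0L)
  hk <- harmonize(ex, ou, palindromic_policy = "keep")
  expect_equal(hk$beta_gd, 0.08)   # labels taken at face value

  # ambiguous frequency inside the window -> dropped under align_freq
  ou2 <- make_va("rs1", "A", "T", beta = 0.08, se = 0.02, eaf = 0.50)
  h2 <- harmonize(ex, ou2, palindromic_policy = "align_freq")
  expect_equal(nrow(h2), 0L)
  expect_match(attr(h2, "excluded")$reason, "ambiguous")
})

test_that("harmonize agrees with brute-force configuration enumeration", {
  # oracle: try the 4 strand/label configurations of the outcome record,
  # keep those whose alleles match; for palindromic SNPs pick the
  # frequency-consistent configuration; then orient to positive beta_gp
  comp1 <- function(a) chartr("ACGT", "TGCA", a)
  oracle <- function(ex, ou, window = c(0.42, 0.58)) {
    cfgs <- list(
      list(ea = ou$effect_allele, oa = ou$other_allele,
           b = ou$beta, f = ou$eaf),
      list(ea = ou$other_allele, oa = ou$effect_allele,
           b = -ou$beta, f = 1 - ou$eaf),
      list(ea = comp1(ou$effect_allele), oa = comp1(ou$other_allele),
           b = ou$beta, f = ou$eaf),
      list(ea = comp1(ou$other_allele), oa = comp1(ou$effect_allele),
           b = -ou$beta, f = 1 - ou$eaf))
    hit <- Filter(function(k) k$ea == ex$effect_allele &&
                    k$oa == ex$other_allele, cfgs)
    if (!length(hit)) return(NULL)              # irreconcilable
    pal <- ex$effect_allele == comp1(ex$other_allele)
    if (pal) {
      if (is.na(ex$eaf) || is.na(ou$eaf) ||
          (ex$eaf >= window[1] && ex$eaf <= window[2]) ||
          (ou$eaf >= window[1] && ou$eaf <= window[2])) {
        return(NULL)                            # ambiguous
      }
      ok <- Filter(function(k) (ex$eaf - 0.5) * (k$f - 0.5) > 0, hit)
      if (!length(ok)) return(NULL)
      hit <- ok
    }
    k <- hit[[1]]
    if (ex$beta < 0) {
      list(ea = ex$other_allele, bgp = -ex$beta, bgd = -k$b)
    } else {
      list(ea = ex$effect_allele, bgp = ex$beta, bgd = k$b)
    }
  }

  cfg <- sim_config(j_snps = 1000, theta = 0.3, seed = 2718,
                    palindromic_fraction = 0.25, swap_fraction = 0.5,
                    flip_fraction = 0.5)
  sim <- simulate_summary_mr(cfg)
  h <- harmonize(sim$exposure, sim$outcome, palindromic_policy = "align_freq")
  expect_gt(nrow(h), 600)
  for (i in seq_len(nrow(sim$exposure))) {
    id <- sim$exposure$rsid[i]
    o <- oracle(sim$exposure[i, ], sim$outcome[sim$outcome$rsid == id, ])
    row <- h[h$rsid == id, ]
    if (is.null(o)) {
      expect_equal(nrow(row), 0L, label = id)
    } else {
      expect_equal(nrow(row), 1L, label = id)
      expect_equal(row$effect_allele, o$ea, label = id)
      expect_equal(row$beta_gp, o$bgp, label = id)
      expect_equal(row$beta_gd, o$bgd, label = id)
    }
  }
  expect_true(all(h$beta_gp >= 0))
})

test_that("harmonization is idempotent and conserves the Wald ratio", {
  cfg <- sim_config(j_snps = 60, theta = 0.2, seed = 99,
                    palindromic_fraction = 0.2)
  sim <- simulate_summary_mr(cfg)
  h1 <- harmonize(sim$exposure, sim$outcome)
  ex2 <- make_va(h1$rsid, h1$effect_allele, h1$other_allele, h1$beta_gp,
                 h1$se_gp, eaf = h1$eaf_exposure)
  ou2 <- make_va(h1$rsid, h1$effect_allele, h1$other_allele, h1$beta_gd,
                 h1$se_gd, eaf = h1$eaf_outcome)
  h2 <- harmonize(ex2, ou2)
  expect_equal(h2$beta_gp, h1$beta_gp)
  expect_equal(h2$beta_gd, h1$beta_gd)
  expect_equal(h2$effect_allele, h1$effect_allele)

  # relabeling both studies' alleles leaves the ratio invariant
  flip_va <- function(v) {
    make_va(v$rsid, v$other_allele, v$effect_allele, -v$beta, v$se,
            eaf = 1 - v$eaf)
  }
  h3 <- harmonize(flip_va(sim$exposure), flip_va(sim$outcome))
  common <- intersect(h1$rsid, h3$rsid)
  r1 <- with(h1[match(common, h1$rsid), ], beta_gd / beta_gp)
  r3 <- with(h3[match(common, h3$rsid), ], beta_gd / beta_gp)
  expect_equal(r1, r3, tolerance = 1e-12)
})

test_that("info filtering is strict and spares genotyped SNPs", {
  inst <- make_instruments(rep(0.02, 10), rep(0.003, 10),
                           rep(0.01, 10), rep(0.02, 10))
  inst$info <- c(0.5, 0.6, 0.61, rep(1, 6), NA)  # NA = directly genotyped
  out <- filter_by_info(inst, threshold = 0.6)
  expect_equal(nrow(out), 8L)                     # 0.5 and exactly 0.6 out
  expect_false(any(out$rsid %in% inst$rsid[1:2]))
  expect_equal(nrow(attr(out, "excluded")), 2L)
  expect_equal(nrow(filter_by_info(inst, info = setNames(rep(1, 10),
                                                         inst$rsid))), 10L)
})

test_that("named-SNP exclusion logs removals and warns on absences", {
  inst <- random_instruments(97, seed = 5)
  out <- exclude_snps(inst, inst$rsid[13])
  expect_equal(nrow(out), 96L)
  expect_equal(nrow(exclude_snps(inst, character(0))), 97L)
  expect_warning(out2 <- exclude_snps(inst, "rs_nonexistent"),
                 "not present")
  expect_equal(nrow(out2), 97L)
  expect_warning(out3 <- exclude_snps(inst, inst$rsid),
                 "removed every instrument")
  expect_equal(nrow(out3), 0L)
})
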