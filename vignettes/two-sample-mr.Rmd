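---
title: "Two-sample Mendelian randomization with mriv: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mriv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mriv)
```

## The causal question and the measurement model

Mendelian randomization treats germline variants as instrumental variables
for a modifiable exposure: because alleles are assorted at random at
conception, a variant that changes the exposure is (under the instrumental
assumptions) unconfounded with respect to the outcome, and its association
with disease measures the causal path through the exposure. `mriv`
implements the two-sample flavor: SNP-exposure effects
$\hat\beta_{GP,j}$ (per allele, in exposure-SD units) are estimated in one
population, SNP-outcome effects $\hat\beta_{GD,j}$ (per allele, log-odds)
in another, and only summary statistics cross the boundary. The motivating
design is a 97-SNP body-mass-index instrument — independent genome-wide
significant SNPs jointly explaining 2.7% of BMI variance, with 1 SD of BMI
equal to 4.65 kg/m² — evaluated against lung-cancer case-control GWAS
strata, but nothing in the code is specific to that pair of traits.

The measurement model behind the primary estimator is

$$\hat\beta_{GP,j} \sim N(\xi_j,\ \sigma_{GP,j}^2), \qquad
  \hat\beta_{GD,j} \sim N(\theta\,\xi_j,\ \sigma_{GD,j}^2),$$

independent across SNPs and between the two studies (zero sample overlap —
the defining feature of the two-sample design; a nonzero cross-study
correlation is deliberately out of scope). $\theta$ is the causal log-odds
per 1 SD of exposure; $\exp(\theta)$ the odds ratio the package reports.

Assumptions, and where they are tested rather than assumed:

1. *Relevance*: the instrument must predict the exposure.
   `score_phenotype_association()` checks this on individual-level data.
2. *No confounding path*: the score must not predict known confounders
   (here, smoking phenotypes); same function, different phenotype column.
3. *Exclusion restriction / no pleiotropy*: not testable directly; the
   weighted median (robust to <50% invalid weight), the MR-Egger
   intercept (average directional pleiotropy), leave-one-SNP-out
   exclusion lists and Cochran's Q are the package's sensitivity surface.

## Estimators and their numerical treatment

**Profile likelihood (primary).** At fixed $\theta$ the per-SNP nuisance
$\xi_j$ maximizing the joint likelihood has a closed form, leaving the
profile log-likelihood
$\ell_p(\theta) = -\tfrac12\sum_j (\hat\beta_{GD,j}-\theta\hat\beta_{GP,j})^2
/(\sigma_{GD,j}^2+\theta^2\sigma_{GP,j}^2)$.
$\theta$ is maximized by bounded golden-section/parabolic search
(`optimize`, tolerance 1e-10) over the Wald-ratio range widened by ±1 —
deterministic, no starting values. A maximum landing on the search
boundary raises an error rather than returning a spurious estimate. The
95% interval is by profile inversion ($2\Delta\ell = 3.841$, root-finding
with expanding brackets and `uniroot` at 1e-10) or by the
observed-information SE from the numerical curvature at the maximum; both
are exposed (`ci_method`) because either convention is defensible and they
agree whenever the profile is near-quadratic. The p-value is the
likelihood-ratio test against $\theta=0$ under the profile method, Wald
otherwise.

**IVW.** Closed form; it is also the no-measurement-error limit of the
likelihood estimator ($\sigma_{GP}\to 0$), a relationship the tests assert.

**Weighted median.** Ratios are ordered with a stable tie-break on
(ratio, rsID) so results are deterministic; order statistic $j$ represents
percentile $p_j=\sum_{k\le j} w_{(k)} - w_{(j)}/2$ of the normalized
inverse-variance weights, the estimate interpolates linearly at 1/2, and
outside $[p_1,p_J]$ the boundary ratio is returned. The SE is a parametric
bootstrap — both effect vectors redrawn from normals at their reported
SEs, weights recomputed per replicate — with 10,000 replicates by default
and a *mandatory* seed: an unseeded stochastic SE cannot be reproduced, so
the pipeline refuses to guess one.

**MR-Egger.** Weighted least squares with intercept via `lm`, fitted on
instruments oriented so every $\hat\beta_{GP,j}\ge 0$ (the orientation
`harmonize()` guarantees; Egger's estimand is not invariant to allele
reorientation, so this convention matters). Coefficient SEs use the model
residual dispersion floored at 1 — the fit may be over-dispersed relative
to the fixed-effect model but never under-dispersed — with t references on
$J-2$ degrees of freedom, the convention common in summary-data MR
software.

**Delta order.** Ratio SEs default to first order
($\sigma_{GD,j}/|\hat\beta_{GP,j}|$); the second-order form adding the
$\hat\beta_{GP}$ error term is available (`delta_order = 2`). First order
is the default because the weighting conventions of the median and IVW
literature are defined with it; with instrument F-statistics in the
regime the generator produces (≈90 and up) the difference is cosmetic.

All p-values are two-sided and unadjusted; the package reports raw
per-analysis inference and leaves multiplicity policy to the analyst.

## Harmonization policy

Records are paired by rsID (the analysis is rsID-keyed; no coordinates, no
liftover). Only single-base A/C/G/T alleles are accepted — multi-base
(indel) rows are rejected at parse time. For each shared SNP the outcome
record is classified into one of four configurations (label-matched,
label-swapped, strand-flipped, both); swaps negate the outcome beta and
complement its frequency, flips relabel alleles. Palindromic SNPs (A/T,
C/G), where strand cannot be read off the letters, default to
frequency alignment: the SNP is kept only when both studies report an
allele frequency outside [0.42, 0.58], and the outcome strand is flipped
when the two frequencies disagree about the minor allele; `drop` and
`keep` policies are provided because published analyses differ and the
choice should be visible, not buried. After alignment every SNP is
oriented to its exposure-increasing allele, so $\hat\beta_{GP,j} \ge 0$
holds package-wide. Imputation-quality filtering is *strict*
(info > 0.6): a SNP at exactly the threshold is excluded, and SNPs with no
info score are treated as directly genotyped and kept. SNPs absent from
the outcome study are dropped — no LD-proxy lookup, since the instrument
is already LD-pruned. Every exclusion, at every stage, carries a reason
string into the run log.

## Fixed-effects pooling

Study-level pooling (score-validation regressions; per-SNP outcome effects
across contributing GWAS) is inverse-variance fixed-effects with Cochran's
Q and $I^2 = \max(0, (Q-\mathrm{df})/Q)\cdot 100$ (floored at zero by
definition). Per-SNP pooling first re-expresses each study's record on a
common effect allele (first reporting study as reference) and drops SNPs
with irreconcilable allele pairs. Inverse-variance weighting was chosen
over sample-size/z-score weighting because downstream estimators need a
pooled beta *with* a pooled SE, which the z-score scheme does not supply.
Random-effects pooling is intentionally absent.

## Power

For a binary outcome with case fraction $\varphi$ in a sample of $N$, an
instrument explaining $R^2$ of exposure variance gives non-centrality
$|\ln OR|\sqrt{N R^2 \varphi(1-\varphi)}$ and power
$\Phi(\mathrm{ncp} - z_{1-\alpha/2})$ — a one-tailed normal approximation
with no continuity correction, so at $OR=1$ the function returns
$\alpha/2$, its rejection floor. `min_detectable_or()` is the exact
inverse and round-trips through `mr_power()` to 1e-9. With the motivating
design's printed case counts (16,572 / 5,282 / 4,224 / 904 against 21,480
controls, $R^2=0.027$, $\alpha=0.05$), this closed form yields minimum
detectable ORs of about 1.19 / 1.30 / 1.33 / 1.78 and 81.9% power for an
OR of 1.81 in the smallest series — computed, never tabulated; if the
per-stratum control counts actually available to a given analysis are
smaller than the full series, the detectable ORs rise accordingly.

## What the generator emulates — and what it does not

`simulate_summary_mr()` draws allele frequencies uniformly on the
configured range (default 0.05–0.5), true effects $\xi_j$ from a shifted
half-normal rescaled so $\sum_j 2f_j(1-f_j)\xi_j^2$ equals the target
explained variance exactly (default 0.027 across 97 SNPs — the calibration
of the motivating instrument), and observed effects by the standard GWAS
standard-error approximations $\sigma_{GP,j}=1/\sqrt{2f_j(1-f_j)N_{exp}}$
and $\sigma_{GD,j}=1/\sqrt{2f_j(1-f_j)N\varphi(1-\varphi)}$ (defaults:
exposure GWAS of 339,224; outcome 16,572 cases / 21,480 controls).
Pleiotropy scenarios inject direct effects $\alpha_j$ on a configurable
fraction of SNPs: balanced $N(0,\tau^2)$, directional $N(\mu,\tau^2)$, or
instrument-strength-correlated $\rho\,\xi_j$ (violating the
InSIDE condition MR-Egger needs). Allele labels, strands and effect-allele
orientation are randomized per study — including a 20% palindromic share —
so harmonization is exercised on every run, and reported frequencies carry
small (sd 0.004) sampling noise so palindromic resolution is realistic
rather than trivial. Everything is seeded; a `panel_seed` can hold the SNP
panel fixed while noise replicates vary.

`simulate_individual_cohort()` shares the same panel: Hardy-Weinberg
genotypes (no LD between instrument SNPs — appropriate for an LD-pruned
instrument, unrealistic for anything else), exposure built from the
genetic value plus age/sex/principal-component effects plus noise
calibrated so the score explains the target variance fraction, smoking
phenotypes independent of the score by construction (or with a controlled
leak), and case status from a logistic model on smoking and the exposure.
Outcome summary statistics are generated directly at the summary level
(normal approximation) rather than by aggregating subject-level logistic
fits; the individual-level generator provides the slower, more literal
route when a test needs it.

What the generator does *not* emulate — and what green tests therefore do
not establish about real data: linkage disequilibrium and proxy-SNP
ambiguity; population-stratification confounding (PCs exist but carry no
confounding structure); winner's-curse bias in discovery-estimated
$\hat\beta_{GP}$; selection or survival bias in case recruitment; and
non-collapsibility subtleties of odds ratios at high disease prevalence.

## Test calibration fixtures

The test suite cross-checks every estimator against an independent oracle
(closed-form algebra, exhaustive grid search with the closed-form inner
profile, a weighted-CDF built on a million-point grid, a normal-equations
solve, Monte-Carlo simulation). End-to-end calibration tests additionally
run the estimators on synthetic 97-SNP instrument sets constructed at the
motivating study's sample sizes with generating stratum-level odds ratios
fixed at that study's reported values (1.13 overall, 1.45 SQ, 1.81 SC,
0.82 AD; dispersed variant with the weighted median at 1.42): because the
original per-SNP supplementary tables are not redistributable, these are
clearly-labelled synthetic stand-ins, and the tests demonstrate estimator
calibration on consistent inputs, not reproduction of the original data.

## Problem sizes

Simulation-based tests use sizes chosen to make Monte-Carlo error small
relative to the asserted tolerances while keeping the default suite quick:
200 seeded replicates for the parameter-recovery/coverage sweep (J = 97,
outcome 16,572/21,480, coverage asserted within [0.92, 0.98]), 80
replicates for the pleiotropy-robustness comparison, 500 for the
Egger-intercept null-uniformity KS check, 1,000 noise replicates over a
fixed panel for the SE-calibration check, and 50,000 subjects for the
score-variance recovery check (asserted within ±0.005 of the 0.027
target). The robustness comparison uses a strong directional scenario
($\mu = 0.1$ on 30% of SNPs): the weighted median's advantage over IVW is
an asymptotic property that emerges when the pleiotropic ratio shift
clears the per-SNP ratio noise, and at stratum-sized outcome samples that
requires direct effects of this magnitude.

## Known limitations

- No correction for exposure-outcome sample overlap; the likelihood
  assumes none.
- No MR-PRESSO-style outlier removal, mode-based estimators, or
  multivariable MR.
- The weighted-median bootstrap redraws $\hat\beta_{GP}$ without
  truncation; with very weak instruments a redraw can cross zero and
  produce extreme replicate ratios, inflating the SE — a property of the
  parametric bootstrap itself, visible only when instrument F-statistics
  are far below anything the generator produces.
- Only SNP instruments (single-base alleles); indels are rejected at
  parse time by design.
- Tabular output only; forest *plots* are left to the analyst
  (`forest_table()` provides the columns).
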