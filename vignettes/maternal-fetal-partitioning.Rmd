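---
title: "Partitioning maternal and fetal genetic effects on birth weight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning maternal and fetal genetic effects on birth weight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matfet)
```

## The model

For each genotyped woman we may observe up to three variables: her allele
count at one SNP, her own birth weight (BW), and the birth weight of her
first child (BW_O). Two genotypes are latent: her mother's (G_G) and her
child's (G_O). Under Mendelian inheritance with random mating, each latent
genotype correlates 0.5 with the observed one, so both latent-to-observed
paths are fixed at 0.5 and all three genotype variances are set to a common
Φ (of which one quarter is transmitted variance and three quarters
residual). The structural equations are

$$
\mathrm{BW} = m\,G_G + f\,\mathrm{SNP} + \varepsilon,\qquad
\mathrm{BW_O} = m\,\mathrm{SNP} + f\,G_O + \varepsilon_O,
$$

with $\mathrm{cov}(\varepsilon, \varepsilon_O) = \rho$. Here `m` is the
maternal effect — the influence of a maternal allele on the child's birth
weight through the intrauterine environment — and `f` is the fetal effect
of an allele on the carrier's own birth weight, both in SD units of birth
weight per allele. The residual covariance ρ absorbs everything shared
between a woman's own birth weight and her child's that is not captured by
this one SNP: shared polygenic background and shared environment alike. We
model it as a single bivariate-normal covariance without attempting to
separate those sources.

Path tracing gives the implied moments coded in `implied_moments()`:

* var(SNP) = Φ
* cov(BW, SNP) = (0.5·m + f)·Φ
* cov(BW_O, SNP) = (m + 0.5·f)·Φ
* var(BW) = (m² + f² + m·f)·Φ + σ²  (likewise σ_O² for BW_O)
* cov(BW, BW_O) = (0.5·m² + 1.25·m·f + 0.5·f²)·Φ + ρ

These were re-derived by hand and verified against a large-n Monte-Carlo
simulation from the package's own generator before anything downstream was
built; the test suite keeps both checks.

The two genotype covariances are the heart of the identification argument:
a regression of offspring birth weight on maternal genotype alone estimates
cov(BW_O, SNP)/Φ = m + 0.5·f, not m. Inverting the two covariance
equations gives the method-of-moments solution `closed_form_mf()`
(f = (4a − 2b)/3, m = (4b − 2a)/3 with a = cov(BW,SNP)/Φ,
b = cov(BW_O,SNP)/Φ), which doubles as an exact oracle for the maximum
likelihood fit on complete data.

## Full-information maximum likelihood

Birth-weight reports arrive in three patterns: own birth weight only,
offspring birth weight only, or both. Rather than discarding incomplete
records, `fit_sem()` evaluates each record's likelihood under the marginal
multivariate normal of its observed variables and sums across patterns.
Each pattern block is reduced to its sufficient statistics (count, mean
vector, centred scatter matrix) once, so a likelihood evaluation costs the
same at n = 100 as at n = 100 000 and the full fit takes a fraction of a
second at biobank scale.

FIML is valid when missingness is unrelated to the unobserved values given
the observed ones. The simulator assigns patterns completely at random,
which satisfies this by construction; in real questionnaire data the
assumption deserves scrutiny (for example, whether women who report their
own birth weight differ systematically).

Two deliberate model simplifications are inherited from standard SEM
practice and documented rather than removed:

* The genotype is treated as Gaussian in the likelihood although it is a
  0/1/2 count (a pseudo-maximum-likelihood approximation). Calibration is
  checked by simulation: the test suite verifies near-nominal Wald
  rejection rates and confidence-interval coverage under the model.
* Means are free parameters. Phenotypes are typically z-scored so the
  means are near zero, but freeing them matches a saturated mean structure
  and costs nothing.

## Numerical choices

* **Working parameterization.** The optimizer works on
  (m, f, log Φ, log σ², log σ_O², atanh r, μ₁, μ₂, μ₃), where
  ρ = tanh(z)·σ·σ_O. Positivity and the Cauchy–Schwarz constraint hold by
  construction, so BFGS runs unconstrained.
* **Starting values.** Φ from the sample genotype variance; m and f from
  `closed_form_mf()` applied to pattern-pooled covariances; residual
  variances from the implied decomposition (floored at 5% of the phenotype
  variance); the residual correlation from the complete block, clamped to
  ±0.9; means from pattern-pooled sample means. These near-solution starts
  make the likelihood effectively quadratic from the first iteration.
* **Convergence.** BFGS with relative tolerance 1e-14 and up to two random
  restarts. A fit is declared converged only if the optimizer reports
  success, the observed information is positive definite, and the maximum
  absolute gradient is below 1e-6·max(1, |log-likelihood|). The gradient
  tolerance is relative because the log-likelihood magnitude grows with n;
  an absolute cutoff meaningful at n = 1 000 would be unattainable
  finite-difference noise at n = 80 000. Non-convergence is flagged in the
  returned object, never silent.
* **Standard errors.** Inverse numerical observed information (central
  differences, step 1e-5·max(1, |θ|)) on the working scale, mapped to the
  natural scale by a numerically differentiated delta method. Wald tests
  use the normal reference; at the sample sizes this model targets the
  normal and t references are indistinguishable.
* **Degenerate inputs.** A non-positive-definite implied covariance
  returns −∞ to the optimizer instead of erroring; datasets in which no
  record observes one of the two birth weights are rejected up front with
  the missing pattern named, because m and f are then not separable.
* **Φ free or fixed.** Whether the genotype variance should be estimated
  or fixed at 2p(1−p) is a genuinely open choice; we estimate it freely by
  default (it is well identified and costs half a parameter) and provide
  `fix_phi` for the fixed-variance variant.

The 2-df test (`lrt_2df()`) refits the model with m = f = 0 and refers
twice the log-likelihood difference to χ²₂ — the joint test that the SNP
affects birth weight through either route.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws grandparents and partners from Hardy–Weinberg
equilibrium at the configured allele frequency, transmits alleles by
Mendelian sampling across grandmother → mother → child, generates the two
birth weights from the structural equations with bivariate-normal
residuals, and assigns the three reporting patterns by a multinomial draw.
The default pattern mix (0.42/0.27/0.31) reproduces the reporting split of
a large biobank questionnaire sample of 78 674 individuals;
`add_reporting_artifacts()` additionally emulates pound-denominated
reports, repeat reports with discrepancies, and out-of-range values so the
cleaning filters can be exercised end to end.

Deliberate simplifications, which bound what passing tests can show about
real data:

* Random mating, no assortment: partners are independent HWE draws, which
  is what fixes the latent-to-observed paths at exactly 0.5.
* One SNP per cohort, no linkage disequilibrium; multi-SNP analyses are
  independent replicate runs, matching the per-SNP model.
* Gaussian residuals, no skew or kurtosis; hard-call genotypes (an
  optional noise switch mimics imputed dosages).
* Missingness completely at random — exactly the FIML validity condition,
  so the simulator cannot detect violations of it.
* No polygenic background beyond what ρ absorbs, no X-chromosome dosage
  compensation, no gene–environment interaction.

Passing tests therefore demonstrate that the estimator is correct,
calibrated and efficient *under the model's own assumptions*; they cannot
certify robustness to assortative mating, informative missingness or
non-normal phenotypes.

## Phenotype preparation and summary-statistics conventions

The cleaning rules are applied literally as stated in their sources:
pounds convert to kilograms by the factor 0.45 exactly; offspring birth
weights below 2.5 kg or above 4.5 kg are excluded with the boundaries kept
(strict inequalities); repeat reports differing by ≥ 1 lb are excluded
(inclusive, with a 1e-9 lb epsilon so exact 1-lb differences are caught
despite floating-point representation). Exclusions happen before
z-scoring, per cohort, because removing records changes the mean and SD;
z-scores use the n−1 denominator. The inverse-normal transform uses the
Blom offset (3/8) by default — no variant was prescribed, so it is
configurable. Blood-pressure preparation adds the medication offsets
(+15/+10 mmHg) before the 4.56-SD outlier screen, and the screen is
centred on the analysis sample's own mean; both orderings were open
choices, and adjustment-first was chosen so that the screen sees the
values that will be analysed.

Variant QC thresholds are strict in the stated direction (info < 0.8
excluded, so 0.8 itself is kept), and imputation-quality metrics slightly
above 1 are clamped at read. Genomic control divides by λ only when
λ > 1 — statistics are never inflated — and is exposed as a per-study
stage only. Allele harmonization rejects palindromic (A/T, C/G) variants
outright rather than inferring strand from frequency. The meta-analysis
is fixed-effects inverse-variance only; the parallel double-computation
that two independent analysts would perform is realized as a `verify`
mode that recomputes the pooled estimate through a separate
scalar-accumulation code path and requires agreement to 1e-10.

`variance_explained()` computes Σ 2p(1−p)β², the variance of the additive
score under Hardy–Weinberg and linkage equilibrium. It is an
approximation — the quantity's original estimation method for real cohorts
was not specified — and no standard error is attached.

## Problem sizes used in validation

The automated checks use sizes chosen to make Monte-Carlo error small
relative to the tolerances while keeping a full run comfortable on one
CPU: genotype-structure checks at n = 100 000; saturation checks on 20
complete-data cohorts of n = 20 000; parameter recovery over 200
replicates at the full biobank-like n = 78 674 and pattern mix; null
calibration of the Wald and 2-df tests over 1 000 replicates at n = 3 000;
heterogeneity null calibration over 10 000 replicated 4-study metas. With
the sufficient-statistics likelihood the complete suite runs in a few
minutes.

## Known limitations

* The SEM treats the genotype as continuous; with very rare alleles
  (Φ → 0) the normal approximation deteriorates and SEs become unstable.
* Relatedness is not modelled; the intended input is one unrelated woman
  per record.
* Paternal genotypes and effects are outside the model; `m` captures only
  the maternal route, and any paternal contribution folds into ρ.
* Fixed-effects meta-analysis assumes homogeneity; Cochran's Q is reported
  so users can inspect that assumption, but no random-effects model is
  provided.
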