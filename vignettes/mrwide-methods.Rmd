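---
title: "Methods: wide-angled two-sample Mendelian randomization with mrwide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wide-angled two-sample Mendelian randomization with mrwide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrwide)
```

## The problem

Does higher maternal blood pressure during pregnancy cause adverse pregnancy
and perinatal outcomes — pregnancy loss, gestational diabetes, labour
complications, impaired fetal growth, shortened gestation? Observational
associations are vulnerable to confounding (socioeconomic position,
adiposity, comorbidity) and reverse causation. Two-sample Mendelian
randomization (MR) addresses this by using genetic variants associated with
blood pressure as instrumental variables: variant–exposure associations come
from a large discovery GWAS (sample 1), variant–outcome associations from
pregnancy cohorts and consortia (sample 2), and the ratio of the two
estimates the causal effect under the instrumental-variable assumptions.

`mrwide` implements that full analysis as a reusable pipeline: instrument
selection, allele harmonisation, the pleiotropy-robust estimator suite,
multivariable MR, and — the intergenerational twist specific to
pregnancy outcomes — adjustment of maternal SNP–outcome effects for fetal
(and paternal) genotype. Because the outcome-side consortium data in this
field are access-restricted, the package also ships a synthetic
intergenerational GWAS generator that reproduces the statistical structure
the analysis assumes, so every stage is verifiable end-to-end.

## The model

For SNP $j$, let $\hat\beta_{Xj}$ (se $\sigma_{Xj}$) be its per-allele
association with the exposure and $\hat\beta_{Yj}$ (se $\sigma_{Yj}$) its
association with the outcome, harmonised to the same effect allele. Each SNP
gives a Wald ratio $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with
first-order standard error $\sigma_{Yj}/|\hat\beta_{Xj}|$ (exposure-side
error is ignored in the weights throughout; second-order weights are out of
scope).

**IVW.** The main estimator is the inverse-variance weighted combination,
equivalently weighted least squares of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$
through the origin with weights $1/\sigma_{Yj}^2$. The default is the
multiplicative random-effects variant: the fixed-effect standard error is
inflated by $\max\{1, \sqrt{Q/(J-1)}\}$, where $Q$ is Cochran's
heterogeneity statistic over the Wald ratios. This matters in two ways:
it is the convention of the toolchain this style of analysis uses, and in
simulation the first-order weights understate the per-SNP variance whenever
the causal effect and the exposure-side sampling error are non-negligible —
the multiplicative factor absorbs exactly that, which is why IVW confidence
intervals attain nominal coverage in the package's replication suite.

**Sensitivity estimators.** MR-Egger (weighted regression with intercept
after orienting all SNPs to positive exposure effect; the intercept tests
directional pleiotropy under InSIDE, with t-based p-values on $J-2$ degrees
of freedom), the weighted median (consistent if half the weight is valid;
cumulative-weight interpolation at 0.5, parametric-bootstrap standard
errors), and the weighted mode (consistent under ZEMPA; weighted Gaussian
kernel density over ratios with bandwidth
$\phi\cdot 0.9\,\min(\mathrm{sd},\mathrm{IQR}/1.349)\,J^{-1/5}$, argmax
taken on a 2048-point grid, bootstrap standard errors). Bootstrap draws
resample $(\hat\beta_{Xj},\hat\beta_{Yj})$ from their sampling
distributions; 1000 replicates by default, always under an explicit seed.

**Direction and multiplicity.** The Steiger test compares the summed
per-SNP variance explained in exposure versus outcome, with per-SNP
$r^2_j = t_j^2/(t_j^2+n_j-2)$ from the association t-statistic (an
observed-scale pseudo-$r^2$ for binary outcomes — an approximation, flagged
in the output) and a Fisher-z test on the difference. Benjamini–Hochberg
FDR at 5% is applied to the main IVW p-values; the family is all outcomes
of one exposure in one pipeline run, which is the natural reading of
"all main results" for a single-exposure panel (a run with both exposures
pools them only if configured to).

**Scaling.** Estimates are reported per 10 exposure units (10 mmHg for
blood pressure). Binary outcomes are presented as odds ratios,
$\mathrm{OR} = \exp(10\,\hat\theta)$, with the confidence interval
transformed endpoint-wise from the linear scale
($\hat\theta \pm 1.96\,\mathrm{se}$).

## Harmonisation rules

Outcome effects are aligned to the exposure's effect allele: matching
alleles kept, swapped alleles flipped (sign of beta, $1-$eaf), strand
complements resolved before the swap test, and anything irreconcilable
dropped as a mismatch. Palindromic SNPs (A/T, C/G) cannot be
strand-resolved from labels: those with minor allele frequency $\ge 0.42$
— evaluated in *either* dataset, the conservative reading since the source
convention does not say which — are excluded; below the threshold the
alignment follows allele frequency (effect allele minor in both or major in
both). The threshold comparison is inclusive ($\ge$). Records without eaf
cannot be frequency-resolved and are dropped when palindromic. Every
decision is written to a per-SNP audit table (`harmonise_audit()`).

## Multivariable MR and conditional instrument strength

`mvmr_ivw()` regresses outcome effects on the matrix of exposure effects
(no intercept, weights $1/\sigma_{Yj}^2$), estimating direct effects of the
primary exposure conditional on covariates such as BMI, height or
education, with the same multiplicative overdispersion as univariable IVW.
Conditional instrument strength uses a two-step convention: regress the
target exposure's SNP effects on the others', form per-SNP residual
variances by the delta method with SNP–exposure covariances approximated by
phenotypic correlations (appropriate under partial sample overlap between
exposure GWAS), and report $Q_x/(J - k_{\mathrm{other}})$. This convention
is documented and oracle-tested by its reduction properties (it equals the
mean-F analogue when the other exposures carry no signal, and collapses
toward zero under perfect collinearity); published analyses using other
software may scale the denominator differently, so values should be
compared qualitatively across implementations.

## Conditional maternal effects (the weighted linear model)

A maternal SNP can affect a perinatal outcome through the pregnancy
environment or through the copy transmitted to the child. Marginal
maternal GWAS effects mix the two. With mother–child genotype correlation
$1/2$ (and no assortative mating; both constants are fixed in the solver
and exposed for sensitivity analyses), the marginal effects satisfy

$$\beta_m = b_m + \tfrac12 b_c, \qquad \beta_c = b_c + \tfrac12 b_m,$$

so the conditional maternal effect is $b_m = (4\beta_m - 2\beta_c)/3$, with
variance $(16 V_m + 4 V_c - 16\rho\,s_m s_c)/9$ by linear propagation,
$\rho$ being the correlation between the two marginal estimates induced by
sample overlap (default 0; the parameter is surfaced rather than guessed,
because overlap handling differs between cohort configurations). The trio
solver additionally conditions on the father:
$b_c = 2\beta_c - \beta_m - \beta_f$ and
$b_m = (3\beta_m + \beta_f - 2\beta_c)/2$, guarding against the collider
opened by conditioning on the child alone. Both solvers are exact inverses
of their structural models (tested to $10^{-8}$) and agree with joint
individual-level regression on simulated trios within sampling error.
`ivw_conditional()` then reruns IVW with conditional effects substituted
for the marginal outcome associations.

## The synthetic intergenerational generator

`sim_config()` + `make_two_sample_scenario()` emulate what the restricted
consortium data provide: per-SNP marginal maternal, fetal and paternal
associations for continuous and binary outcomes from two (optionally
overlapping) samples, with exact LD computed from the generated genotypes.
The generative model: parental genotypes Binomial(2, MAF) with MAF uniform
on [0.1, 0.5]; child genotypes by Mendelian transmission (dosage
correlation 1/2 with each parent); maternal exposure
$X = \sum_j \alpha_j G_{m,j} + \varepsilon$; binary outcomes from a
logistic model in $X$, maternal pleiotropic effects and direct fetal
effects, with the intercept solved to hit the configured prevalence, so the
conditional log-odds per exposure unit is exactly $\theta/10$; continuous
outcomes Gaussian. Antihypertensive-treatment masking mirrors the source
phenotype preparation: the top `treatment_frac` of mothers by underlying
exposure have measured values lowered by the treatment effect, and the scan
adds `treatment_adjustment` (the +15/+10 mmHg convention) back before
regressing.

Default conditions, chosen once as the package's reference design and used
by the replication suite:

* 100 SNPs, exposure and outcome samples of 20,000;
* a diastolic-pressure-like exposure: per-allele effects
  `alpha_sd = 1.0` mmHg, residual SD 7.75 mmHg, total phenotype SD ≈ 10
  mmHg. The per-allele effects are deliberately larger than real GWAS hits:
  at desk-scale sample sizes this preserves the *dimensionless* quantity
  that governs MR estimator behaviour — instrument strength, mean F ≈
  100–130, matching what million-sample discovery GWAS deliver — instead of
  the raw effect sizes. Matching raw effects at n = 20,000 would give mean
  F ≈ 9 and weak-instrument dilution would dominate every property being
  tested;
* binary outcomes: true OR 1.33 per 10 mmHg at 7% prevalence (a
  low-birth-weight-like design); the null battery uses 18% prevalence
  (miscarriage-like);
* "directional" pleiotropy means a common-signed outcome effect of the
  exposure-*raising* alleles (sign-aligned with $\alpha_j$), the only
  version that survives MR-Egger's orientation step — sign-agnostic
  "directional" effects are rebalanced by orientation and are
  indistinguishable from balanced pleiotropy;
* fetal direct effects default to proportional to the SNP's exposure effect
  (the fetal-physiology pathway: the same variants act on fetal traits in
  proportion to their effect sizes). This makes the fetal-transmission bias
  in marginal maternal MR systematic and directional, which is the scenario
  the WLM adjustment exists for; an `independent` mode (mean-zero fetal
  effects uncorrelated with instrument strength) is available and produces
  only noise, not bias.

What the generator does *not* emulate: realistic genome-wide LD (an
optional block-LD mode exists solely to exercise clumping), imputation
uncertainty, ancestry structure, assortative mating, case–control
ascertainment. Passing tests therefore demonstrate correctness of the
estimators and solvers under the stated structural model, not robustness to
those additional features of real cohort data.

## Numerical choices and degenerate inputs

* Per-SNP logistic scans exploit the fact that dosage takes only values
  0/1/2: Newton iterations on the 2×3 sufficient-statistics table give the
  exact MLE for all SNPs simultaneously (matched to `glm()` to $10^{-6}$ in
  tests).
* Clumping p-value ties break by larger $|\beta/\mathrm{se}|$, then
  lexicographic SNP id — determinism is required for testing and the source
  convention is silent.
* The weighted mode returns the common ratio when all ratios are identical
  (zero bandwidth); the weighted median handles boundary cumulative weights
  without interpolation.
* `wald_ratio()` refuses $\hat\beta_X = 0$; IVW refuses empty SNP sets;
  Egger/median/mode require 3 SNPs; Cochran's Q requires 2.
* All stochastic operations (bootstrap, simulation) take explicit seeds and
  restore the caller's RNG state; identical seeds give bit-identical
  output.

## Replication suite problem sizes

The package's validation batteries (in `tests/testthat/test-acceptance.R`
and recomputed by `scripts/acceptance.R`) use: 500 replicates at the
reference design for IVW coverage, odds-ratio recovery and the true null;
500 summary-level replicates for Egger intercept power (sign-aligned
directional pleiotropy, scale 0.02 outcome SD) and size (balanced, same
scale), 200 for the 30%-invalid weighted-median comparison; 200 and 150
cohort-level replicates (n = 10,000) for the fetal-effect battery; 100
each for forward and reverse Steiger calls. Summary-level replication is
used where estimator operating characteristics depend only on the sampling
distribution of the per-SNP effects; cohort-level generation is used
wherever transmission, treatment masking or the logistic outcome model is
itself under test.

## Known limitations

* First-order weights throughout; no MR-PRESSO, contamination-mixture,
  robust or radial variants.
* The binary-outcome Steiger $r^2$ is an observed-scale approximation.
* Marginal/conditional WLM conversion assumes the fixed genotype
  correlations (1/2, 0); empirical deviations in small cohorts propagate
  into conditional estimates at order $1/n$.
* LD is an input; the package never computes it from external reference
  panels, and proxy-SNP lookup is out of scope.
* Non-collapsibility of the odds ratio means marginal per-SNP log-odds are
  very slightly attenuated relative to the conditional $\theta$ even with
  perfect instruments; at the reference design this contributes less than
  0.005 to the per-10-unit log-OR and is absorbed by the bias budget of
  the recovery battery.
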