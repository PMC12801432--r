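# mrwide

Wide-angled two-sample Mendelian randomization (MR) for intergenerational
exposure–outcome panels, built for questions like: *does higher maternal
blood pressure during pregnancy cause adverse pregnancy and perinatal
outcomes?*

Two-sample MR uses genetic variants as instrumental variables: per-SNP
associations with the exposure (from a large discovery GWAS, e.g. blood
pressure in a million individuals) are combined with per-SNP associations
with each outcome (from pregnancy cohorts and consortia) to estimate the
causal effect free of classical confounding. For SNP *j* with exposure
effect β<sub>Xj</sub> and outcome effect β<sub>Yj</sub>, the
inverse-variance weighted (IVW) estimate is the 1/σ²<sub>Yj</sub>-weighted
regression of β<sub>Yj</sub> on β<sub>Xj</sub> through the origin —
equivalently a precision-weighted average of the per-SNP Wald ratios
β<sub>Yj</sub>/β<sub>Xj</sub> — reported per 10 mmHg as an odds ratio
exp(10·θ̂) for binary outcomes.

The package covers the complete analysis around that estimator:

* **sumstats** — GWAS summary-statistics I/O (GWAS-SSF-like TSV, header
  dialects for GWAS Catalog exports) and fixed-effect meta-analysis across
  studies;
* **instruments** — genome-wide significance selection (p < 5×10⁻⁸), greedy
  LD clumping (r² < 0.001, 10,000 kb window), F-statistics and variance
  explained, cross-dataset effect-transfer checks;
* **harmonise** — effect-allele alignment with strand-complement
  resolution and the palindromic-SNP MAF ≥ 0.42 exclusion rule, with a full
  per-SNP audit trail;
* **estimators** — IVW (multiplicative random effects by default), MR-Egger
  with intercept test, weighted median, weighted mode, Cochran's Q, Steiger
  directionality, Benjamini–Hochberg FDR, per-10-unit scaling;
* **mvmr** — multivariable MR (direct effects adjusting for BMI, height,
  education, ...) with conditional F-statistics under
  phenotypic-correlation covariance approximation;
* **intergen** — weighted-linear-model conversion of marginal maternal,
  fetal and paternal GWAS effects into maternal effects conditional on
  offspring (and paternal) genotype, and IVW on the conditional effects;
* **simgen** — a synthetic intergenerational GWAS generator
  (mother–father–child trios, Mendelian transmission, treatment masking,
  configurable pleiotropy and fetal effects, sample overlap, exact LD) that
  stands in for restricted cohort data;
* **pipeline** — one-call orchestration over an outcome panel with tidy TSV
  results, per-outcome error isolation and YAML configuration.

## Worked example

Simulate a two-sample study with a true odds ratio of 1.33 per 10 mmHg and
run the full estimator suite:

```r
library(mrwide)

cfg <- sim_config(n_snps = 100, n_exposure = 20000, n_outcome = 20000,
                  outcome_type = "binary", prevalence = 0.07,
                  theta = log(1.33), seed = 7)
sc  <- make_two_sample_scenario(cfg)

inst <- clump(select_gws(sc$exposure, 5e-8), sc$ld)
h    <- harmonise_pair(inst, sc$outcome_maternal)

ivw(h)
#> MR estimate [ivw]: beta = 0.03215 (se 0.005082, 95% CI 0.02219 to 0.04211), p = 2.51e-10, 55 SNPs
#>   Cochran's Q = 51.25 on 54 df (p = 0.581)

scale_estimate(ivw(h), scale = 10, outcome_binary = TRUE)$or_point
#> [1] 1.379229
```

Genome-wide selection retains 55 of the 100 simulated variants as
instruments. The per-mmHg log-odds estimate (0.032, se 0.005) scales to an
odds ratio of 1.38 per 10 mmHg (95% CI 1.25 to 1.52), consistent with the
simulated truth of 1.33; Cochran's Q near its degrees of freedom shows no
excess heterogeneity, as expected with no pleiotropy simulated. Sensitivity estimators (`mr_egger()`, `weighted_median()`,
`weighted_mode()`), the Steiger direction check (`steiger()`), fetal-genotype
adjustment (`trio_sumstats()` + `wlm_duo()` + `ivw_conditional()`) and
multivariable MR (`harmonise_multi()` + `mvmr_ivw()` + `conditional_f()`)
take the same harmonised inputs. `run_pipeline(analysis_config(...))` wires
all of it over a panel of outcomes and applies FDR across the panel's main
IVW p-values.

The published outcome panel (case counts and sample sizes for the 24
perinatal outcomes) ships with the package: `outcome_panel()`.

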