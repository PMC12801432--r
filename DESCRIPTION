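Package: mrwide
Title: Wide-Angled Two-Sample Mendelian Randomization for Intergenerational
    Exposure-Outcome Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) toolkit for
    estimating effects of a maternal exposure (such as blood pressure) on
    panels of perinatal outcomes from GWAS summary statistics. Covers genetic
    instrument selection (genome-wide significance filtering and greedy LD
    clumping), instrument strength diagnostics (F-statistics and variance
    explained), effect-allele harmonisation with palindromic-SNP frequency
    rules, the standard estimator suite (inverse-variance weighted, MR-Egger,
    weighted median, weighted mode) with Cochran's Q, Egger intercept and
    Steiger directionality diagnostics, Benjamini-Hochberg FDR control,
    per-10-unit effect scaling, multivariable MR with conditional
    F-statistics, and weighted-linear-model conversion of marginal maternal,
    fetal and paternal genetic associations into conditional maternal
    effects. Includes a synthetic intergenerational GWAS generator (mother,
    father, child trios with Mendelian transmission) so every stage of the
    pipeline is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
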