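test_that("config validation names the offending field", {
  expect_error(sim_config(n_snps = 0), "n_snps")
  expect_error(sim_config(overlap_frac = 1.5), "overlap_frac")
  expect_error(sim_config(prevalence = 0, outcome_type = "binary"),
               "prevalence")
  expect_error(sim_config(maf_range = c(0.6, 0.7)), "maf_range")
})

test_that("genotypes have binomial dosages and Mendelian transmission", {
  cfg <- sim_config(n_snps = 40, n_outcome = 8000,
                    outcome_type = "continuous", seed = 51)
  cohort <- simulate_trio_cohort(cfg)
  maf <- cohort$truth$maf
  # mean dosage within 4 Monte-Carlo standard errors of 2 * MAF
  mc_se <- sqrt(2 * maf * (1 - maf) / nrow(cohort$Gm))
  expect_true(all(abs(colMeans(cohort$Gm) - 2 * maf) < 4 * mc_se))
  # mother-child dosage correlation near 1/2
  r_mc <- vapply(seq_len(40),
                 function(j) cor(cohort$Gm[, j], cohort$Gc[, j]),
                 numeric(1))
  expect_equal(mean(r_mc), 0.5, tolerance = 0.02)
  # parents are unrelated
  r_mp <- vapply(seq_len(40),
                 function(j) cor(cohort$Gm[, j], cohort$Gp[, j]),
                 numeric(1))
  expect_lt(abs(mean(r_mp)), 0.02)
})

test_that("generation is reproducible bit-for-bit given the config", {
  cfg <- sim_config(n_snps = 10, n_exposure = 500, n_outcome = 500,
                    outcome_type = "binary", prevalence = 0.2, seed = 52)
  s1 <- make_two_sample_scenario(cfg)
  s2 <- make_two_sample_scenario(cfg)
  expect_identical(as.data.frame(s1$exposure), as.data.frame(s2$exposure))
  expect_identical(as.data.frame(s1$outcome_maternal),
                   as.data.frame(s2$outcome_maternal))
  expect_identical(s1$truth$alpha, s2$truth$alpha)
})

test_that("the GWAS scan is an honest per-SNP regression", {
  cfg <- sim_config(n_snps = 25, n_outcome = 4000,
                    outcome_type = "continuous", theta = 0,
                    treatment_frac = 0, seed = 53)
  cohort <- simulate_trio_cohort(cfg)
  s <- gwas_scan(cohort, "exposure", "maternal")
  # column-by-column lm oracle on a few SNPs
  for (j in c(1, 13, 25)) {
    fit <- summary(lm(cohort$x_adjusted ~ cohort$Gm[, j]))
    expect_equal(s$beta[j], unname(fit$coefficients[2, 1]), tolerance = 1e-8)
    expect_equal(s$se[j], unname(fit$coefficients[2, 2]), tolerance = 1e-6)
  }
  # regressing a genotype on itself gives beta 1
  cohort2 <- cohort
  cohort2$x_adjusted <- cohort$Gm[, 3]
  s_self <- gwas_scan(cohort2, "exposure", "maternal")
  expect_equal(s_self$beta[3], 1, tolerance = 1e-12)

  # estimated exposure effects are consistent: about 95% within 2 se
  alpha_hat <- s$beta
  cover <- mean(abs(alpha_hat - cohort$truth$alpha) < 2 * s$se)
  expect_gte(cover, 0.8)

  # logistic scan against glm on a binary outcome
  cfgb <- sim_config(n_snps = 8, n_outcome = 3000, outcome_type = "binary",
                     prevalence = 0.2, seed = 54)
  cohort_b <- simulate_trio_cohort(cfgb)
  sb <- gwas_scan(cohort_b, "outcome", "maternal")
  for (j in c(2, 8)) {
    fit <- summary(glm(cohort_b$y ~ cohort_b$Gm[, j], family = binomial()))
    expect_equal(sb$beta[j], unname(fit$coefficients[2, 1]), tolerance = 1e-6)
    expect_equal(sb$se[j], unname(fit$coefficients[2, 2]), tolerance = 1e-5)
  }
  expect_equal(sb$n_case[1], sum(cohort_b$y))
})

test_that("null SNP-outcome p-values are uniform and effects centred at zero", {
  # theta 0, no pleiotropy: outcome scan p-values across many SNPs are
  # uniform (Kolmogorov-Smirnov at alpha 0.01)
  cfg <- sim_config(n_snps = 300, n_outcome = 2000,
                    outcome_type = "continuous", theta = 0,
                    treatment_frac = 0, seed = 55)
  cohort <- simulate_trio_cohort(cfg)
  s <- gwas_scan(cohort, "outcome", "maternal")
  ks <- suppressWarnings(ks.test(s$pval, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(s$beta / s$se)), 4 / sqrt(300))
})

test_that("two-sample scenarios honour overlap and satisfy container invariants", {
  cfg <- sim_config(n_snps = 12, n_exposure = 800, n_outcome = 800,
                    overlap_frac = 1, outcome_type = "continuous",
                    theta = 1, seed = 56)
  sc <- make_two_sample_scenario(cfg)
  expect_equal(nrow(sc$exposure), 12)
  # full overlap: the two samples are the same individuals, so scanning
  # the exposure trait in the outcome sample reproduces the exposure GWAS
  expect_identical(sc$exposure$beta,
                   gwas_scan(sc$outcome_cohort, "exposure",
                             "maternal")$beta)
  # generated summary statistics satisfy the container invariants
  expect_true(all(sc$exposure$se > 0))
  expect_true(all(sc$exposure$eaf > 0 & sc$exposure$eaf < 1))
  expect_false(anyDuplicated(sc$exposure$snp_id) > 0)
  # exact LD of independent SNPs is near-diagonal
  off <- sc$ld$r2[upper.tri(sc$ld$r2)]
  expect_lt(max(off), 0.05)

  # zero overlap: disjoint index sets, so exposure-sample and outcome-sample
  # scans of the same trait are distinct draws
  cfg0 <- sim_config(n_snps = 12, n_exposure = 800, n_outcome = 800,
                     overlap_frac = 0, outcome_type = "continuous",
                     theta = 1, seed = 56)
  sc0 <- make_two_sample_scenario(cfg0)
  expect_false(identical(sc0$exposure$beta,
                         gwas_scan(sc0$outcome_cohort, "exposure",
                                   "maternal")$beta))
})

test_that("block-LD mode produces correlated neighbours that clumping prunes", {
  cfg <- sim_config(n_snps = 20, n_exposure = 3000, n_outcome = 500,
                    ld_block_size = 4, outcome_type = "continuous",
                    theta = 1, seed = 57)
  sc <- make_two_sample_scenario(cfg)
  r2 <- sc$ld$r2
  blocks <- sc$truth$block
  within <- r2[outer(blocks, blocks, "==") & upper.tri(r2)]
  between <- r2[outer(blocks, blocks, "!=") & upper.tri(r2)]
  expect_gt(min(within), 0.5)
  expect_lt(max(between), 0.05)
  kept <- clump(sc$exposure, sc$ld, r2_threshold = 0.1, window_kb = 10000)
  # one index SNP per block survives
  expect_equal(nrow(kept), length(unique(blocks)))
  expect_equal(sort(unique(blocks[match(kept$snp_id, sc$truth$snp_id)])),
               sort(unique(blocks)))
})

test_that("scenario files round-trip through the writers", {
  cfg <- sim_config(n_snps = 6, n_exposure = 400, n_outcome = 400,
                    outcome_type = "binary", prevalence = 0.2, seed = 58)
  sc <- make_two_sample_scenario(cfg, fetal = TRUE)
  dir <- withr::local_tempdir()
  write_scenario(sc, dir)
  expect_setequal(list.files(dir),
                  c("exposure.tsv", "outcome_maternal.tsv",
                    "outcome_fetal.tsv", "ld.tsv", "truth.tsv"))
  back <- read_sumstats(file.path(dir, "exposure.tsv"), unit = "mmHg")
  expect_equal(back$beta, sc$exposure$beta)
  ld_back <- read_ld(file.path(dir, "ld.tsv"))
  expect_equal(sort(ld_back$snp_ids), sort(sc$ld$snp_ids))
})
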