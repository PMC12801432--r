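# forward structural models used to generate noise-free marginals
duo_forward <- function(bm, bc) list(beta_m = bm + bc / 2, beta_c = bc + bm / 2)
trio_forward <- function(bm, bf, bc) {
  list(beta_m = bm + bc / 2, beta_f = bf + bc / 2,
       beta_c = bc + bm / 2 + bf / 2)
}

make_trio_ss <- function(beta_m, beta_c, beta_f = NULL,
                         sm = 0.05, sc = 0.05, sp = 0.05, est_corr = 0) {
  n <- length(beta_m)
  ids <- sprintf("t%03d", seq_len(n))
  maternal <- make_ss(ids, beta = beta_m, se = rep(sm, n), unit = "SD")
  fetal <- make_ss(ids, beta = beta_c, se = rep(sc, n), unit = "SD")
  paternal <- if (is.null(beta_f)) NULL else
    make_ss(ids, beta = beta_f, se = rep(sp, n), unit = "SD")
  trio_sumstats(maternal, fetal, paternal, est_corr = est_corr)
}

test_that("duo solver inverts its structural model exactly", {
  set.seed(41)
  bm <- rnorm(20); bc <- rnorm(20)
  fwd <- duo_forward(bm, bc)
  t <- make_trio_ss(fwd$beta_m, fwd$beta_c)
  cond <- wlm_duo(t)
  expect_equal(cond$beta, bm, tolerance = 1e-10)
  expect_equal(cond$bc_cond, bc, tolerance = 1e-10)

  # spec-level arithmetic identities
  t1 <- make_trio_ss(1, 0.5)          # pure maternal effect
  expect_equal(wlm_duo(t1)$beta, 1)
  t2 <- make_trio_ss(1, 1)
  expect_equal(wlm_duo(t2)$beta, 2 / 3)

  # variance propagation: Var(bm) = (16 Vm + 4 Vc - 16 rho sm sc) / 9
  t3 <- make_trio_ss(0.2, 0.1, sm = 0.03, sc = 0.07, est_corr = 0.4)
  want_v <- (16 * 0.03^2 + 4 * 0.07^2 - 16 * 0.4 * 0.03 * 0.07) / 9
  expect_equal(wlm_duo(t3)$se, sqrt(want_v), tolerance = 1e-12)
})

test_that("trio solver inverts its structural model and signals missing paternal data", {
  set.seed(42)
  bm <- rnorm(15); bf <- rnorm(15); bc <- rnorm(15)
  fwd <- trio_forward(bm, bf, bc)
  t <- make_trio_ss(fwd$beta_m, fwd$beta_c, fwd$beta_f)
  cond <- wlm_trio(t)
  expect_equal(cond$beta, bm, tolerance = 1e-10)
  expect_equal(cond$bc_cond, bc, tolerance = 1e-10)

  # consistent pure-maternal case: beta_m 1, beta_f 0, beta_c 0.5 -> bm = 1
  t1 <- make_trio_ss(1, 0.5, 0)
  expect_equal(wlm_trio(t1)$beta, 1)
  expect_equal(wlm_trio(t1)$bc_cond, 0)
  # all-zero marginals give all-zero conditionals
  t0 <- make_trio_ss(0, 0, 0)
  expect_equal(wlm_trio(t0)$beta, 0)

  t_na <- make_trio_ss(1, 0.5)
  expect_error(wlm_trio(t_na), class = "mrwide_missing_paternal")
})

test_that("duo WLM matches individual-level joint regression on simulated trios", {
  cfg <- sim_config(n_snps = 12, n_outcome = 6000, alpha_sd = 0.5,
                    theta = 0, fetal_effect_sd = 0.04,
                    fetal_effect_mode = "independent",
                    outcome_type = "continuous", treatment_frac = 0,
                    seed = 43)
  cohort <- simulate_trio_cohort(cfg)
  maternal <- gwas_scan(cohort, "outcome", "maternal")
  fetal <- gwas_scan(cohort, "outcome", "fetal")
  t <- trio_sumstats(maternal, fetal)
  cond <- wlm_duo(t)

  # oracle: per-SNP regression of y on (Gm, Gc) jointly in the same cohort
  for (j in c(1, 5, 12)) {
    fit <- lm(cohort$y ~ cohort$Gm[, j] + cohort$Gc[, j])
    bm_joint <- unname(coef(fit)[2])
    se_joint <- sqrt(diag(vcov(fit)))[2]
    idx <- which(cond$snp_id == sprintf("snp%04d", j))
    # same data, same estimand: agreement within joint-model uncertainty
    expect_equal(cond$beta[idx], bm_joint, tolerance = 4 * se_joint)
  }
  # conditional maternal effects are centred on zero (no maternal effect
  # was simulated) while marginal ones are inflated by transmitted fetal
  # effects
  delta <- cohort$truth$delta
  expect_gt(cor(maternal$beta, delta), 0.5)
  z_cond <- sum(cond$beta * delta) / sqrt(sum((cond$se * delta)^2))
  expect_lt(abs(z_cond), 4)

  # conditional se never beats the marginal se when estimates are
  # uncorrelated (information is spent on the adjustment)
  expect_true(all(cond$se >= maternal$se[match(cond$snp_id,
                                               maternal$snp_id)]))
})

test_that("trio WLM matches the three-genotype individual-level regression", {
  cfg <- sim_config(n_snps = 10, n_outcome = 6000, alpha_sd = 0.5,
                    theta = 0, fetal_effect_sd = 0.05,
                    fetal_effect_mode = "independent",
                    outcome_type = "continuous", treatment_frac = 0,
                    seed = 44)
  cohort <- simulate_trio_cohort(cfg)
  t <- trio_sumstats(gwas_scan(cohort, "outcome", "maternal"),
                     gwas_scan(cohort, "outcome", "fetal"),
                     gwas_scan(cohort, "outcome", "paternal"))
  cond <- wlm_trio(t)
  for (j in c(2, 7)) {
    fit <- lm(cohort$y ~ cohort$Gm[, j] + cohort$Gc[, j] + cohort$Gp[, j])
    bm_joint <- unname(coef(fit)[2])
    se_joint <- sqrt(diag(vcov(fit)))[2]
    idx <- which(cond$snp_id == sprintf("snp%04d", j))
    expect_equal(cond$beta[idx], bm_joint, tolerance = 4 * se_joint)
  }
})

test_that("conditional IVW removes fetal-transmission bias absent a maternal effect", {
  # fetal effects only: the marginal maternal IVW picks up half the fetal
  # effect through transmission; the WLM-adjusted IVW is centred at zero
  n_rep <- 60
  res <- t(vapply(seq_len(n_rep), function(r) {
    cfg <- sim_config(n_snps = 40, n_exposure = 4000, n_outcome = 4000,
                      theta = 0, fetal_effect_sd = 0.05,
                      outcome_type = "continuous", treatment_frac = 0,
                      seed = 5000 + r)
    sc <- make_two_sample_scenario(cfg, fetal = TRUE, exact_ld = FALSE)
    h <- harmonise_pair(sc$exposure, sc$outcome_maternal)
    marg <- ivw(h)
    t <- trio_sumstats(sc$outcome_maternal, sc$outcome_fetal)
    cond_est <- ivw_conditional(wlm_duo(t), h)
    c(marg = marg$beta, cond = cond_est$beta)
  }, numeric(2)))
  mc_se <- apply(res, 2, sd) / sqrt(n_rep)
  expect_gt(abs(mean(res[, "marg"])), 3 * mc_se["marg"])
  expect_lt(abs(mean(res[, "cond"])), 3 * mc_se["cond"])

  # single-SNP conditional IVW equals the Wald ratio on conditional values
  cfg1 <- sim_config(n_snps = 5, n_exposure = 3000, n_outcome = 3000,
                     theta = 0.5, outcome_type = "continuous",
                     fetal_effect_sd = 0.02, seed = 46)
  sc1 <- make_two_sample_scenario(cfg1, fetal = TRUE, exact_ld = FALSE)
  h1 <- harmonise_pair(sc1$exposure, sc1$outcome_maternal)
  cond1 <- wlm_duo(trio_sumstats(sc1$outcome_maternal, sc1$outcome_fetal))
  one <- h1[1, , drop = FALSE]
  got <- ivw_conditional(cond1[cond1$snp_id == one$snp_id, ], one)
  ci <- which(cond1$snp_id == one$snp_id)
  want <- wald_ratio(one$bx, one$sx, cond1$beta[ci], cond1$se[ci])
  expect_equal(got$beta, want$beta, tolerance = 1e-12)
  expect_equal(got$se, want$se, tolerance = 1e-12)
})
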