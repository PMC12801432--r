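test_that("Wald ratio and its first-order se follow the delta method", {
  expect_equal(wald_ratio(0.5, 0.01, 0.1, 0.05)$beta, 0.2)
  expect_equal(wald_ratio(0.5, 0.01, 0, 0.05)$beta, 0)
  # first-order delta method: d(by/bx)/dby = 1/bx, so se = sy/|bx|
  expect_equal(wald_ratio(-0.4, 0.01, 0.1, 0.06)$se, 0.06 / 0.4)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.05), "degenerate")
})

test_that("IVW equals the weighted normal-equations oracle and the single-SNP Wald ratio", {
  set.seed(21)
  h <- make_h(bx = rnorm(40, 0, 1), by = rnorm(40, 0, 0.05),
              sy = runif(40, 0.02, 0.1))
  est <- ivw(h, mode = "fixed")
  w <- 1 / h$sy^2
  beta_oracle <- solve(t(h$bx * w) %*% h$bx, t(h$bx * w) %*% h$by)[1, 1]
  expect_equal(est$beta, beta_oracle, tolerance = 1e-10)
  expect_equal(est$se, sqrt(1 / sum(w * h$bx^2)), tolerance = 1e-12)

  # multiplicative random effects only ever inflates
  expect_gte(ivw(h, mode = "mre")$se, est$se)

  # single SNP: identical to the Wald ratio
  h1 <- make_h(bx = 0.5, by = 0.1, sy = 0.05)
  expect_equal(ivw(h1)$beta, wald_ratio(0.5, 0.01, 0.1, 0.05)$beta)
  expect_equal(ivw(h1)$se, wald_ratio(0.5, 0.01, 0.1, 0.05)$se)

  # two SNPs with equal sy and bx: precision-weighted mean of ratios
  h2 <- make_h(bx = c(0.5, 0.5), by = c(0.1, 0.3), sy = c(0.05, 0.05))
  expect_equal(ivw(h2)$beta, mean(c(0.2, 0.6)))
})

test_that("MR-Egger reproduces exact fits and the weighted-regression oracle", {
  # all ratios exactly c: slope c, intercept 0
  bx <- c(0.2, 0.5, -0.8, 1.1)
  h <- make_h(bx = bx, by = 0.3 * bx)
  e <- mr_egger(h)
  expect_equal(e$slope$beta, 0.3, tolerance = 1e-12)
  expect_equal(e$intercept, 0, tolerance = 1e-12)

  # general case against lm with orientation applied by hand
  set.seed(22)
  h2 <- make_h(bx = rnorm(30), by = rnorm(30, 0, 0.1),
               sy = runif(30, 0.02, 0.1))
  e2 <- mr_egger(h2)
  s <- sign(h2$bx)
  fit <- lm(I(h2$by * s) ~ I(h2$bx * s), weights = 1 / h2$sy^2)
  sm <- summary(fit)
  expect_equal(e2$slope$beta, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(e2$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  infl <- 1 / min(1, sm$sigma)
  expect_equal(e2$slope$se, unname(sm$coefficients[2, 2]) * infl,
               tolerance = 1e-10)

  # Egger with the intercept constrained to zero is fixed-effect IVW:
  # verified through the shared weighted-least-squares normal equations
  fit0 <- lm(h2$by ~ 0 + h2$bx, weights = 1 / h2$sy^2)
  expect_equal(ivw(h2, mode = "fixed")$beta, unname(coef(fit0)),
               tolerance = 1e-12)

  expect_error(mr_egger(make_h(bx = c(1, 2), by = c(1, 2))), "3 SNPs")
})

test_that("weighted median interpolates cumulative weights and equals the plain median under equal weights", {
  h3 <- make_h(bx = c(1, 1, 1), by = c(1, 2, 3))
  expect_equal(weighted_median(h3, n_boot = 0)$beta, 2)

  # hand oracle for equal weights on {1,2,3,4}: cumulative midpoints are
  # 1/8, 3/8, 5/8, 7/8, so 0.5 interpolates halfway between ratios 2 and 3
  h4 <- make_h(bx = rep(1, 4), by = c(1, 2, 3, 4))
  expect_equal(weighted_median(h4, n_boot = 0)$beta, 2.5)

  # equal weights equal the sample median for odd n (property)
  set.seed(23)
  for (n in c(5, 9, 15)) {
    ratios <- rnorm(n)
    hn <- make_h(bx = rep(1, n), by = ratios)
    expect_equal(weighted_median(hn, n_boot = 0)$beta, median(ratios))
  }

  # unequal weights against a direct cumulative-weight computation
  hw <- make_h(bx = c(2, 1, 1), by = c(2, 3, 10), sy = c(0.05, 0.05, 0.2))
  ratios <- hw$by / hw$bx
  w <- (hw$sy / abs(hw$bx))^-2
  ord <- order(ratios)
  r <- ratios[ord]; wn <- w[ord] / sum(w)
  cw <- cumsum(wn) - wn / 2
  k <- max(which(cw < 0.5))
  want <- r[k] + (r[k + 1] - r[k]) * (0.5 - cw[k]) / (cw[k + 1] - cw[k])
  expect_equal(weighted_median(hw, n_boot = 0)$beta, want, tolerance = 1e-12)

  # identical seed gives identical bootstrap se
  e1 <- weighted_median(h4, n_boot = 200, seed = 7)
  e2 <- weighted_median(h4, n_boot = 200, seed = 7)
  expect_identical(e1$se, e2$se)
})

test_that("weighted mode finds the dominant ratio cluster and matches a grid search", {
  h <- make_h(bx = rep(1, 5), by = rep(0.05, 5))
  expect_equal(weighted_mode(h, n_boot = 0)$beta, 0.05)

  set.seed(24)
  n <- 40
  ratios <- c(rnorm(28, 0.3, 0.01), rnorm(12, 2, 0.5))
  hm <- make_h(bx = rep(1, n), by = ratios)
  est <- weighted_mode(hm, n_boot = 0)
  expect_equal(est$beta, 0.3, tolerance = 0.05)

  # density argmax against a dense brute-force grid of the same kernel
  w <- (hm$sy / abs(hm$bx))^-2
  w <- w / sum(w)
  band <- 0.9 * min(sd(ratios), IQR(ratios) / 1.349) * n^(-1 / 5)
  grid <- seq(min(ratios) - 3 * band, max(ratios) + 3 * band,
              length.out = 50000)
  dens <- vapply(grid, function(x) sum(w * dnorm(x, ratios, band)),
                 numeric(1))
  expect_equal(est$beta, grid[which.max(dens)], tolerance = 1e-3)
})

test_that("Cochran's Q matches hand arithmetic and is zero for identical ratios", {
  h_same <- make_h(bx = c(1, 2, 4), by = c(0.5, 1, 2))
  q0 <- cochran_q(h_same, ivw(h_same))
  expect_equal(q0$q, 0, tolerance = 1e-20)

  # two SNPs by hand
  h2 <- make_h(bx = c(1, 1), by = c(0.1, 0.3), sy = c(0.1, 0.2))
  est <- ivw(h2, mode = "fixed")
  w <- (h2$bx / h2$sy)^2
  q_hand <- sum(w * (h2$by / h2$bx - est$beta)^2)
  got <- cochran_q(h2, est)
  expect_equal(got$q, q_hand, tolerance = 1e-12)
  expect_equal(got$q_df, 1)
  expect_equal(got$q_pval, pchisq(q_hand, 1, lower.tail = FALSE))

  # homogeneous simulated data: mean Q/df near 1 over replicates
  set.seed(25)
  qq <- replicate(300, {
    h <- draw_summary_mr(alpha = rnorm(20, 0, 1), theta_per_unit = 0,
                         sx = 1e-6, sy = 0.05)
    e <- ivw(h, mode = "fixed")
    cochran_q(h, e)$q / (nrow(h) - 1)
  })
  expect_equal(mean(qq), 1, tolerance = 0.05)
})

test_that("estimators are equivariant to exposure-unit rescaling", {
  set.seed(26)
  h <- make_h(bx = rnorm(15, 1), by = rnorm(15, 0.3, 0.1))
  c_scale <- 7
  h_scaled <- h
  h_scaled$bx <- h$bx * c_scale
  h_scaled$sx <- h$sx * c_scale
  expect_equal(ivw(h_scaled)$beta, ivw(h)$beta / c_scale, tolerance = 1e-12)
  expect_equal(mr_egger(h_scaled)$slope$beta, mr_egger(h)$slope$beta / c_scale,
               tolerance = 1e-12)
  expect_equal(weighted_median(h_scaled, n_boot = 0)$beta,
               weighted_median(h, n_boot = 0)$beta / c_scale,
               tolerance = 1e-12)
  expect_equal(weighted_mode(h_scaled, n_boot = 0)$beta,
               weighted_mode(h, n_boot = 0)$beta / c_scale, tolerance = 1e-6)
})

test_that("Steiger direction flips under exposure-outcome swap and reflects explained variance", {
  h <- make_h(bx = c(0.5, 0.4, 0.6), by = c(0.01, 0.02, 0.01),
              sx = rep(0.02, 3), sy = rep(0.02, 3))
  st <- steiger(h)
  expect_true(st$correct_direction)
  expect_true(st$r2_exposure > st$r2_outcome)
  # swapping the roles negates the call
  h_sw <- make_h(bx = h$by, by = h$bx, sx = h$sy, sy = h$sx)
  expect_false(steiger(h_sw)$correct_direction)
  expect_equal(steiger(h_sw)$r2_exposure, st$r2_outcome)
  # per-SNP r2 from the t statistic
  t1 <- h$bx[1] / h$sx[1]
  expect_equal(st$r2_exposure,
               sum((h$bx / h$sx)^2 / ((h$bx / h$sx)^2 + h$nx - 2)))
  h_nan <- h; h_nan$nx <- NA
  expect_error(steiger(h_nan), "sample sizes")
})

test_that("per-10-unit scaling maps log-odds to odds ratios exactly", {
  est0 <- mr_estimate("ivw", 0, 0.01, 1, 10)
  expect_equal(scale_estimate(est0, 10, TRUE)$or_point, 1)
  est1 <- mr_estimate("ivw", 0.1, 0.01, 0.001, 10)
  expect_equal(scale_estimate(est1, 10, TRUE)$or_point, exp(1))
  # a per-unit log odds of log(1.33)/10 scales to OR 1.33 per 10 units
  est2 <- mr_estimate("ivw", log(1.33) / 10, 0.003, 0.001, 10)
  sc <- scale_estimate(est2, 10, TRUE)
  expect_equal(sc$or_point, 1.33, tolerance = 1e-12)
  expect_equal(sc$or_low, exp(10 * est2$ci_low), tolerance = 1e-12)
  # continuous outcomes scale linearly
  sc_cont <- scale_estimate(est1, 10, FALSE)
  expect_equal(sc_cont$beta_scaled, 1)
  expect_equal(sc_cont$ci_low, 10 * est1$ci_low)
})

test_that("BH FDR matches the brute-force step-up oracle", {
  # direct re-implementation of the step-up rule
  bh_oracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    q <- numeric(m)
    prev <- 1
    for (i in m:1) {
      val <- min(prev, p[ord[i]] * m / i)
      q[ord[i]] <- val
      prev <- val
    }
    q
  }
  expect_equal(bh_fdr(0.03)$qval, 0.03)
  expect_equal(bh_fdr(rep(0.2, 5))$qval, rep(0.2, 5))
  set.seed(27)
  p <- runif(10)
  got <- bh_fdr(p)
  expect_equal(got$qval, bh_oracle(p), tolerance = 1e-12)
  expect_true(all(got$qval <= 1))
  # monotone non-decreasing in sorted p order
  expect_true(all(diff(got$qval[order(p)]) >= -1e-15))
  expect_equal(got$pass, got$qval < 0.05)
  expect_equal(nrow(bh_fdr(numeric(0))), 0)
})
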