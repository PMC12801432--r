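#' Construct an MR estimate record
#'
#' Internal constructor shared by all estimators. Confidence intervals are
#' estimate +/- 1.96 * se on the linear scale; odds-ratio presentation is
#' applied afterwards by [scale_estimate()].
#'
#' @keywords internal
mr_estimate <- function(method, beta, se, pval, n_snp,
                        q = NA_real_, q_df = NA_real_, q_pval = NA_real_) {
  structure(list(
    method = method, beta = beta, se = se,
    ci_low = beta - stats::qnorm(0.975) * se,
    ci_high = beta + stats::qnorm(0.975) * se,
    pval = pval, n_snp = n_snp,
    q = q, q_df = q_df, q_pval = q_pval
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s]: beta = %.4g (se %.4g, 95%% CI %.4g to %.4g), p = %.3g, %d SNPs\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$n_snp))
  if (!is.na(x$q)) {
    cat(sprintf("  Cochran's Q = %.4g on %d df (p = %.3g)\n",
                x$q, as.integer(x$q_df), x$q_pval))
  }
  invisible(x)
}

#' Wald ratio estimate for a single instrument
#'
#' Per-SNP causal estimate: the SNP-outcome effect divided by the
#' SNP-exposure effect, with the first-order standard error `sy / |bx|`
#' (the exposure-side sampling error is ignored, the convention used
#' throughout this estimator suite).
#'
#' @param bx,sx SNP-exposure effect and its standard error.
#' @param by,sy SNP-outcome effect and its standard error.
#' @return an `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(bx, sx, by, sy) {
  if (bx == 0) stop("degenerate instrument: bx = 0", call. = FALSE)
  beta <- by / bx
  se <- sy / abs(bx)
  mr_estimate("wald", beta, se, 2 * stats::pnorm(-abs(beta / se)), 1L)
}

first_order_weights <- function(h) (h$bx / h$sy)^2  # = 1/var(ratio), first order

#' Inverse-variance weighted MR
#'
#' The main estimator: weighted least squares of the SNP-outcome effects on
#' the SNP-exposure effects through the origin with weights 1/sy^2,
#' equivalent to the precision-weighted average of per-SNP Wald ratios with
#' first-order weights. The default multiplicative random-effects model
#' inflates the fixed-effect standard error by max(1, sqrt(Q / (n_snp - 1)))
#' when heterogeneity exceeds its expectation; `mode = "fixed"` disables the
#' inflation. Cochran's Q is attached.
#'
#' @param h a [harmonise_pair()] result (or any data frame with `bx`, `sx`,
#'   `by`, `sy`).
#' @param mode `"mre"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return an `mr_estimate` with method `"ivw"`.
#' @export
ivw <- function(h, mode = c("mre", "fixed")) {
  mode <- match.arg(mode)
  n <- nrow(h)
  if (is.null(n) || n < 1) stop("no SNPs available for IVW", call. = FALSE)
  w <- 1 / h$sy^2
  beta <- sum(w * h$bx * h$by) / sum(w * h$bx^2)
  se <- sqrt(1 / sum(w * h$bx^2))
  q <- NA_real_; q_df <- NA_real_; q_pval <- NA_real_
  if (n >= 2) {
    ratios <- h$by / h$bx
    wq <- first_order_weights(h)
    q <- sum(wq * (ratios - beta)^2)
    q_df <- n - 1
    q_pval <- stats::pchisq(q, q_df, lower.tail = FALSE)
    if (mode == "mre") se <- se * max(1, sqrt(q / q_df))
  }
  mr_estimate("ivw", beta, se, 2 * stats::pnorm(-abs(beta / se)), n,
              q, q_df, q_pval)
}

#' MR-Egger regression
#'
#' Weighted least squares of SNP-outcome effects on SNP-exposure effects
#' with an intercept, weights 1/sy^2, after orienting every SNP so that
#' bx > 0. The slope estimates the causal effect under the InSIDE
#' assumption; a non-zero intercept indicates unbalanced horizontal
#' pleiotropy. Standard errors use multiplicative random effects
#' (inflation by max(1, sqrt(Q_egger / (n_snp - 2)))); p-values use the
#' t distribution with n_snp - 2 degrees of freedom.
#'
#' @param h a [harmonise_pair()] result with at least 3 SNPs.
#' @return an object of class `egger_result`: list with `slope`
#'   (`mr_estimate`, method `"egger"`), `intercept`, `intercept_se`,
#'   `intercept_pval`, `q`, `q_df`.
#' @export
mr_egger <- function(h) {
  n <- nrow(h)
  if (is.null(n) || n < 3) {
    stop("MR-Egger requires at least 3 SNPs", call. = FALSE)
  }
  flip <- sign(h$bx)
  flip[flip == 0] <- 1
  bx <- h$bx * flip
  by <- h$by * flip
  w <- 1 / h$sy^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma                     # sqrt(Q_egger / (n - 2))
  infl <- 1 / min(1, sigma)             # se_mre = se_lm * max(1, sigma)/sigma
  est <- stats::coef(sm)
  slope <- est["bx", "Estimate"]
  slope_se <- est["bx", "Std. Error"] * infl
  int <- est["(Intercept)", "Estimate"]
  int_se <- est["(Intercept)", "Std. Error"] * infl
  q <- sigma^2 * (n - 2)
  structure(list(
    slope = {
      e <- mr_estimate("egger", slope, slope_se,
                       2 * stats::pt(-abs(slope / slope_se), df = n - 2), n,
                       q, n - 2, stats::pchisq(q, n - 2, lower.tail = FALSE))
      e
    },
    intercept = int,
    intercept_se = int_se,
    intercept_pval = 2 * stats::pt(-abs(int / int_se), df = n - 2),
    q = q, q_df = n - 2
  ), class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  Egger intercept = %.4g (se %.4g), p = %.3g\n",
              x$intercept, x$intercept_se, x$intercept_pval))
  invisible(x)
}

# weight-interpolated median: cumulative weight crossing 1/2 with linear
# interpolation between adjacent order statistics
weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(r[1])
  if (cw[length(cw)] <= 0.5) return(r[length(r)])
  below <- max(which(cw < 0.5))
  r[below] + (r[below + 1] - r[below]) * (0.5 - cw[below]) /
    (cw[below + 1] - cw[below])
}

#' Weighted median MR
#'
#' Consistent when at least 50% of the weight comes from valid instruments.
#' Per-SNP Wald ratios are combined by the weight-interpolated median with
#' inverse-variance weights (sy/|bx|)^-2; the standard error comes from a
#' parametric bootstrap resampling bx and by from their sampling
#' distributions.
#'
#' @param h a [harmonise_pair()] result with at least 3 SNPs.
#' @param n_boot bootstrap replicates for the standard error (default 1000;
#'   0 skips the bootstrap and returns `se = NA`).
#' @param seed integer seed for the bootstrap (reproducible by construction).
#' @return an `mr_estimate` with method `"wmedian"`.
#' @export
weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  n <- nrow(h)
  if (is.null(n) || n < 3) {
    stop("weighted median requires at least 3 SNPs", call. = FALSE)
  }
  ratios <- h$by / h$bx
  weights <- (h$sy / abs(h$bx))^-2
  beta <- weighted_median_point(ratios, weights)
  se <- NA_real_
  pval <- NA_real_
  if (n_boot > 0) {
    se <- boot_se(h, n_boot, seed, function(bx, by) {
      weighted_median_point(by / bx, (h$sy / abs(bx))^-2)
    })
    pval <- 2 * stats::pnorm(-abs(beta / se))
  }
  mr_estimate("wmedian", beta, se, pval, n)
}

#' Weighted mode MR
#'
#' Consistent under the zero modal pleiotropy assumption (ZEMPA): the most
#' frequent per-SNP ratio estimate equals the true causal effect. Ratios are
#' smoothed by a weighted Gaussian kernel density with bandwidth
#' `phi * 0.9 * min(sd, IQR/1.349) * n^(-1/5)`; the estimate is the density
#' argmax; the standard error comes from a parametric bootstrap. If all
#' ratios are identical (zero bandwidth) the common ratio is returned.
#'
#' @param h a [harmonise_pair()] result with at least 3 SNPs.
#' @param phi bandwidth multiplier (default 1).
#' @param n_boot,seed bootstrap settings as in [weighted_median()].
#' @return an `mr_estimate` with method `"wmode"`.
#' @export
weighted_mode <- function(h, phi = 1, n_boot = 1000, seed = 1L) {
  n <- nrow(h)
  if (is.null(n) || n < 3) {
    stop("weighted mode requires at least 3 SNPs", call. = FALSE)
  }
  ratios <- h$by / h$bx
  weights <- (h$sy / abs(h$bx))^-2
  beta <- weighted_mode_point(ratios, weights, phi)
  se <- NA_real_
  pval <- NA_real_
  if (n_boot > 0) {
    se <- boot_se(h, n_boot, seed, function(bx, by) {
      weighted_mode_point(by / bx, (h$sy / abs(bx))^-2, phi)
    })
    pval <- 2 * stats::pnorm(-abs(beta / se))
  }
  mr_estimate("wmode", beta, se, pval, n)
}

weighted_mode_point <- function(ratios, weights, phi) {
  s <- stats::sd(ratios)
  iqr <- stats::IQR(ratios) / 1.349
  h_band <- phi * 0.9 * min(s, iqr) * length(ratios)^(-1 / 5)
  if (!is.finite(h_band) || h_band <= 0) return(ratios[1])
  d <- stats::density(ratios, weights = weights / sum(weights), bw = h_band,
                      n = 2048)
  d$x[which.max(d$y)]
}

# parametric bootstrap over (bx, by); point_fun(bx*, by*) -> scalar
boot_se <- function(h, n_boot, seed, point_fun) {
  n <- nrow(h)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  reps <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(n, h$bx, h$sx)
    by <- stats::rnorm(n, h$by, h$sy)
    point_fun(bx, by)
  }, numeric(1))
  stats::sd(reps)
}

# seed hygiene: set a local seed, return previous .Random.seed for restore
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum over SNPs of w_j (theta_j - theta_hat)^2 with first-order
#' inverse-variance weights w_j = (bx_j / sy_j)^2, theta_j the per-SNP Wald
#' ratio and theta_hat the supplied pooled estimate; df = n_snp - 1; p from
#' the upper chi-square tail.
#'
#' @param h a [harmonise_pair()] result with at least 2 SNPs.
#' @param est an `mr_estimate` providing the pooled effect.
#' @return list with `q`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(h, est) {
  n <- nrow(h)
  if (is.null(n) || n < 2) stop("Cochran's Q requires at least 2 SNPs",
                                call. = FALSE)
  ratios <- h$by / h$bx
  w <- first_order_weights(h)
  q <- sum(w * (ratios - est$beta)^2)
  list(q = q, q_df = n - 1,
       q_pval = stats::pchisq(q, n - 1, lower.tail = FALSE))
}

#' Steiger directionality test
#'
#' Tests whether the instruments explain more variance in the exposure than
#' in the outcome, supporting the assumed causal direction. Per-SNP variance
#' explained is computed from the t-statistic, r2_j = t_j^2 / (t_j^2 + n_j -
#' 2), and summed over SNPs for each trait (valid for independent
#' instruments). For binary outcomes this is the observed-scale pseudo-r2 of
#' the log-odds regression, an approximation. The p-value is a two-sided z
#' test on the difference of Fisher-z transformed summed correlations.
#'
#' @param h a [harmonise_pair()] result with per-trait sample sizes `nx`,
#'   `ny` available.
#' @param outcome_type `"continuous"` or `"binary"` (label recorded in the
#'   result; the computation is the observed-scale approximation in both
#'   cases).
#' @return list of class `steiger_result`: `r2_exposure`, `r2_outcome`,
#'   `correct_direction`, `pval`.
#' @export
steiger <- function(h, outcome_type = c("continuous", "binary")) {
  outcome_type <- match.arg(outcome_type)
  if (anyNA(h$nx) || anyNA(h$ny)) {
    stop("Steiger test requires per-trait sample sizes (nx, ny)",
         call. = FALSE)
  }
  tx <- h$bx / h$sx
  ty <- h$by / h$sy
  r2x <- tx^2 / (tx^2 + h$nx - 2)
  r2y <- ty^2 / (ty^2 + h$ny - 2)
  r2_exposure <- sum(r2x)
  r2_outcome <- sum(r2y)
  rx <- sqrt(min(r2_exposure, 1))
  ry <- sqrt(min(r2_outcome, 1))
  nx <- mean(h$nx)
  ny <- mean(h$ny)
  z <- (atanh(rx) - atanh(ry)) / sqrt(1 / (nx - 3) + 1 / (ny - 3))
  structure(list(
    r2_exposure = r2_exposure,
    r2_outcome = r2_outcome,
    correct_direction = r2_exposure > r2_outcome,
    pval = 2 * stats::pnorm(-abs(z)),
    outcome_type = outcome_type
  ), class = "steiger_result")
}

#' Scale an MR estimate to a clinically interpretable exposure increment
#'
#' Converts a per-1-exposure-unit estimate to a per-`scale`-unit estimate
#' (default: per 10 units, e.g. per 10 mmHg of blood pressure). For binary
#' outcomes (outcome beta in log-odds) the scaled effect and its confidence
#' interval are exponentiated to odds ratios; continuous outcomes are
#' reported on the scaled linear scale.
#'
#' @param est an `mr_estimate`.
#' @param scale exposure-unit multiplier (default 10).
#' @param outcome_binary is the outcome effect on the log-odds scale?
#' @return list of class `scaled_estimate`: `scale`, and either
#'   `or_point`/`or_low`/`or_high` (binary) or
#'   `beta_scaled`/`ci_low`/`ci_high` (continuous).
#' @export
scale_estimate <- function(est, scale = 10, outcome_binary = TRUE) {
  lo <- scale * est$ci_low
  hi <- scale * est$ci_high
  if (outcome_binary) {
    structure(list(scale = scale,
                   or_point = exp(scale * est$beta),
                   or_low = exp(min(lo, hi)), or_high = exp(max(lo, hi)),
                   method = est$method),
              class = "scaled_estimate")
  } else {
    structure(list(scale = scale,
                   beta_scaled = scale * est$beta,
                   ci_low = min(lo, hi), ci_high = max(lo, hi),
                   method = est$method),
              class = "scaled_estimate")
  }
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Standard step-up BH q-values (monotonicity enforced) with pass flags at
#' the declared FDR level.
#'
#' @param pvals numeric vector of p-values in [0,1].
#' @param fdr_level flag threshold (default 0.05).
#' @return data frame with `pval`, `qval`, `pass`.
#' @export
bh_fdr <- function(pvals, fdr_level = 0.05) {
  if (length(pvals) == 0) {
    return(data.frame(pval = numeric(0), qval = numeric(0),
                      pass = logical(0)))
  }
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  q <- stats::p.adjust(pvals, method = "BH")
  data.frame(pval = pvals, qval = q, pass = !is.na(q) & q < fdr_level)
}
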