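#' Multivariable MR by inverse-variance weighting
#'
#' Weighted least squares of the SNP-outcome effects on the matrix of
#' SNP-exposure effects with no intercept and weights 1/outcome_se^2,
#' estimating the direct effect of each exposure conditional on the others.
#' Standard errors use the WLS covariance with the same multiplicative
#' overdispersion as univariable IVW: inflation by max(1, sqrt(Q / (n_snp -
#' k))) where Q is the weighted residual sum of squares.
#'
#' With a single exposure this reduces exactly to [ivw()].
#'
#' @param m an `mvmr_set` from [harmonise_multi()] (or a list with
#'   `exposure_betas`, `outcome_beta`, `outcome_se`, `exposures`).
#' @return object of class `mvmr_result`: list with `estimates` (data frame:
#'   exposure, beta, se, ci_low, ci_high, pval), `q`, `q_df`, `q_pval`,
#'   `conditional_f` (filled by [conditional_f()], `NULL` here).
#' @export
mvmr_ivw <- function(m) {
  bx <- as.matrix(m$exposure_betas)
  by <- m$outcome_beta
  sy <- m$outcome_se
  n <- nrow(bx); k <- ncol(bx)
  if (n <= k) stop("multivariable MR requires more SNPs than exposures",
                   call. = FALSE)
  if (qr(bx)$rank < k) {
    stop("exposure effect matrix is rank deficient (collinear exposures)",
         call. = FALSE)
  }
  w <- 1 / sy^2
  xtwx <- crossprod(bx * sqrt(w))
  xtwy <- crossprod(bx, w * by)
  beta <- solve(xtwx, xtwy)[, 1]
  resid <- by - as.vector(bx %*% beta)
  q <- sum(w * resid^2)
  q_df <- n - k
  infl <- max(1, sqrt(q / q_df))
  se <- sqrt(diag(solve(xtwx))) * infl
  est <- data.frame(
    exposure = m$exposures,
    beta = beta, se = se,
    ci_low = beta - stats::qnorm(0.975) * se,
    ci_high = beta + stats::qnorm(0.975) * se,
    pval = 2 * stats::pnorm(-abs(beta / se)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(estimates = est, n_snp = n,
                 q = q, q_df = q_df,
                 q_pval = stats::pchisq(q, q_df, lower.tail = FALSE),
                 conditional_f = NULL),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat("Multivariable MR (", x$n_snp, " SNPs):\n", sep = "")
  print(x$estimates, digits = 4)
  cat(sprintf("  Q = %.4g on %d df (p = %.3g)\n", x$q, x$q_df, x$q_pval))
  if (!is.null(x$conditional_f)) {
    cat("  conditional F:",
        paste(sprintf("%s = %.3g", names(x$conditional_f), x$conditional_f),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Conditional instrument strength in multivariable MR
#'
#' Measures how strongly each exposure's SNP effects can be predicted
#' independently of the other exposures. Convention implemented (two-step,
#' Sanderson-style): for exposure x, (1) ordinary least squares of x's SNP
#' effects on the other exposures' SNP effects gives coefficients delta; (2)
#' the per-SNP residual variance is the delta-method combination of the
#' SNP-exposure standard errors, with cross-covariances approximated as
#' `pheno_corr[x, l] * se_x * se_l` (phenotypic correlations standing in for
#' the unavailable sampling covariances, appropriate under partial sample
#' overlap); (3) the conditional strength is
#' `Q_x / (n_snp - n_other_exposures)` with
#' `Q_x = sum_j residual_j^2 / v_j`.
#'
#' With a single "other" exposure whose effects are all zero and zero
#' correlation, this reduces to the mean per-SNP F analogue
#' `sum(bx^2/sx^2) / (n_snp - 1)`.
#'
#' @param m an `mvmr_set` from [harmonise_multi()]; `pheno_corr` must be
#'   present when there are two or more exposures.
#' @return named numeric vector of conditional F statistics, one per
#'   exposure.
#' @export
conditional_f <- function(m) {
  bx <- as.matrix(m$exposure_betas)
  sx <- as.matrix(m$exposure_ses)
  n <- nrow(bx); k <- ncol(bx)
  if (k >= 2 && is.null(m$pheno_corr)) {
    stop("pheno_corr is required for conditional F with >= 2 exposures",
         call. = FALSE)
  }
  rho <- if (is.null(m$pheno_corr)) diag(k) else as.matrix(m$pheno_corr)

  out <- numeric(k)
  names(out) <- m$exposures
  for (x in seq_len(k)) {
    others <- setdiff(seq_len(k), x)
    if (length(others) == 0) {
      out[x] <- sum(bx[, x]^2 / sx[, x]^2) / n
      next
    }
    bo <- bx[, others, drop = FALSE]
    delta <- stats::coef(stats::lm.fit(bo, bx[, x]))
    delta[is.na(delta)] <- 0  # degenerate columns contribute nothing
    resid <- bx[, x] - as.vector(bo %*% delta)
    # delta-method per-SNP variance with pheno_corr cross terms
    v <- sx[, x]^2
    for (a in seq_along(others)) {
      la <- others[a]
      v <- v + delta[a]^2 * sx[, la]^2 -
        2 * delta[a] * rho[x, la] * sx[, x] * sx[, la]
      if (a < length(others)) {
        for (b in (a + 1):length(others)) {
          lb <- others[b]
          v <- v + 2 * delta[a] * delta[b] * rho[la, lb] *
            sx[, la] * sx[, lb]
        }
      }
    }
    v <- pmax(v, .Machine$double.eps)
    qx <- sum(resid^2 / v)
    out[x] <- qx / (n - length(others))
  }
  pmax(out, 0)
}
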