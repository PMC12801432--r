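#' Bundle marginal maternal, fetal and paternal GWAS summary statistics
#'
#' Marginal (unconditional) per-SNP associations of an outcome with the
#' maternal, fetal and (optionally) paternal genotype, harmonised to one
#' effect allele, plus the assumed correlation between the marginal
#' estimates induced by sample overlap (0 for independent samples).
#'
#' @param maternal,fetal [sumstats()] objects of marginal effects; `paternal`
#'   optional.
#' @param est_corr scalar or named list/vector of pairwise estimate
#'   correlations (`mf` mother-fetal, `mp` mother-paternal, `fp`
#'   fetal-paternal); a scalar applies to all pairs. Default 0.
#' @return object of class `trio_sumstats`: data frame of shared SNPs with
#'   `bm`, `sm` (maternal marginal), `bc`, `sc` (fetal), `bp`, `sp`
#'   (paternal, `NA` if absent), plus attribute `est_corr`.
#' @export
trio_sumstats <- function(maternal, fetal, paternal = NULL, est_corr = 0) {
  stopifnot(inherits(maternal, "sumstats"), inherits(fetal, "sumstats"))
  hm <- harmonise_pair(maternal, fetal)  # aligns fetal to maternal alleles
  df <- data.frame(snp_id = hm$snp_id,
                   effect_allele = hm$effect_allele,
                   other_allele = hm$other_allele,
                   bm = hm$bx, sm = hm$sx,
                   bc = hm$by, sc = hm$sy,
                   bp = NA_real_, sp = NA_real_,
                   stringsAsFactors = FALSE)
  if (!is.null(paternal)) {
    hp <- harmonise_pair(maternal, paternal)
    idx <- match(df$snp_id, hp$snp_id)
    df$bp <- hp$by[idx]
    df$sp <- hp$sy[idx]
    df <- df[!is.na(df$bp), , drop = FALSE]
  }
  if (is.numeric(est_corr) && length(est_corr) == 1) {
    est_corr <- list(mf = est_corr, mp = est_corr, fp = est_corr)
  }
  stopifnot(all(unlist(est_corr) >= -1), all(unlist(est_corr) <= 1))
  rownames(df) <- NULL
  structure(df, est_corr = est_corr,
            outcome = attr(maternal, "trait"),
            unit = attr(maternal, "unit"),
            class = c("trio_sumstats", "data.frame"))
}

# genotype-correlation constants of the structural model: parent-child 1/2,
# mother-father 0 (no assortative mating); exposed for sensitivity use
wlm_constants <- function() c(parent_child = 0.5, mother_father = 0)

#' Weighted linear model: maternal effects conditional on offspring genotype
#'
#' Converts marginal maternal and fetal GWAS effects into the maternal
#' effect conditional on offspring genotype, under the structural model with
#' mother-child genotype correlation 1/2:
#' \deqn{\beta_m^{marg} = b_m + b_c/2, \quad \beta_c^{marg} = b_c + b_m/2,}
#' giving \eqn{b_m = (4\beta_m - 2\beta_c)/3}. Variances follow by linear
#' propagation: \eqn{Var(b_m) = (16 Var(\beta_m) + 4 Var(\beta_c) - 16 \rho\,
#' SE(\beta_m) SE(\beta_c))/9}, with \eqn{\rho} the overlap-induced estimate
#' correlation (`est_corr$mf`).
#'
#' @param t a [trio_sumstats()] object (paternal effects ignored).
#' @return object of class `conditional_sumstats`: data frame with `snp_id`,
#'   `beta` (conditional maternal effect), `se`, `bc_cond` (conditional
#'   fetal effect) and attribute `model = "duo"`.
#' @export
wlm_duo <- function(t) {
  stopifnot(inherits(t, "trio_sumstats"))
  rho <- attr(t, "est_corr")$mf
  bm <- (4 * t$bm - 2 * t$bc) / 3
  vm <- (16 * t$sm^2 + 4 * t$sc^2 - 16 * rho * t$sm * t$sc) / 9
  bc <- (4 * t$bc - 2 * t$bm) / 3
  vc <- (16 * t$sc^2 + 4 * t$sm^2 - 16 * rho * t$sm * t$sc) / 9
  conditional_sumstats(t, beta = bm, se = sqrt(vm),
                       bc_cond = bc, sc_cond = sqrt(vc), model = "duo")
}

#' Weighted linear model: maternal effects conditional on offspring and
#' paternal genotype
#'
#' Solves the trio structural model (parent-child genotype correlation 1/2,
#' no assortative mating):
#' \deqn{\beta_m = b_m + b_c/2,\; \beta_f = b_f + b_c/2,\;
#'       \beta_c = b_c + b_m/2 + b_f/2,}
#' giving \eqn{b_c = 2\beta_c - \beta_m - \beta_f},
#' \eqn{b_m = (3\beta_m + \beta_f - 2\beta_c)/2} and symmetrically for the
#' father. Variances follow by linear propagation with the `est_corr`
#' cross terms.
#'
#' If the paternal set is absent the function signals an explicit condition
#' of class `mrwide_missing_paternal` instructing the caller to fall back to
#' [wlm_duo()].
#'
#' @param t a [trio_sumstats()] object with paternal effects present.
#' @return a `conditional_sumstats` object with attribute `model = "trio"`.
#' @export
wlm_trio <- function(t) {
  stopifnot(inherits(t, "trio_sumstats"))
  if (all(is.na(t$bp))) {
    stop(structure(class = c("mrwide_missing_paternal", "error", "condition"),
                   list(message = paste("paternal summary statistics absent;",
                                        "use wlm_duo() instead"),
                        call = sys.call())))
  }
  rho <- attr(t, "est_corr")
  # b_m = 1.5 bm_marg + 0.5 bf_marg - 1 bc_marg
  bm <- (3 * t$bm + t$bp - 2 * t$bc) / 2
  vm <- 2.25 * t$sm^2 + 0.25 * t$sp^2 + t$sc^2 +
    2 * 1.5 * 0.5 * rho$mp * t$sm * t$sp -
    2 * 1.5 * rho$mf * t$sm * t$sc -
    2 * 0.5 * rho$fp * t$sp * t$sc
  bc <- 2 * t$bc - t$bm - t$bp
  vc <- t$sm^2 + t$sp^2 + 4 * t$sc^2 +
    2 * rho$mp * t$sm * t$sp -
    4 * rho$mf * t$sm * t$sc -
    4 * rho$fp * t$sp * t$sc
  conditional_sumstats(t, beta = bm, se = sqrt(pmax(vm, 0)),
                       bc_cond = bc, sc_cond = sqrt(pmax(vc, 0)),
                       model = "trio")
}

conditional_sumstats <- function(t, beta, se, bc_cond, sc_cond, model) {
  df <- data.frame(snp_id = t$snp_id,
                   effect_allele = t$effect_allele,
                   other_allele = t$other_allele,
                   beta = beta, se = se,
                   bc_cond = bc_cond, sc_cond = sc_cond,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, model = model,
            outcome = attr(t, "outcome"), unit = attr(t, "unit"),
            class = c("conditional_sumstats", "data.frame"))
}

#' IVW on conditional maternal effects
#'
#' Re-estimates the MR effect with the weighted-linear-model conditional
#' maternal SNP-outcome effects substituted for the marginal ones; identical
#' contract to [ivw()] otherwise.
#'
#' @param c a [wlm_duo()] / [wlm_trio()] result.
#' @param exposure_instruments a [harmonise_pair()] result supplying the
#'   SNP-exposure effects (`bx`, `sx`) on the same effect-allele frame.
#' @param mode see [ivw()].
#' @return an `mr_estimate` with method `"ivw"`.
#' @export
ivw_conditional <- function(c, exposure_instruments, mode = c("mre", "fixed")) {
  stopifnot(inherits(c, "conditional_sumstats"))
  shared <- intersect(exposure_instruments$snp_id, c$snp_id)
  if (length(shared) == 0) stop("no shared SNPs", call. = FALSE)
  ei <- match(shared, exposure_instruments$snp_id)
  ci <- match(shared, c$snp_id)
  # orientation: both frames carry effect-allele labels; flip where needed
  s <- ifelse(
    c$effect_allele[ci] == exposure_instruments$effect_allele[ei], 1,
    ifelse(c$effect_allele[ci] == exposure_instruments$other_allele[ei],
           -1, NA_real_))
  if (anyNA(s)) stop("conditional and exposure effect alleles do not match",
                     call. = FALSE)
  h <- data.frame(bx = exposure_instruments$bx[ei],
                  sx = exposure_instruments$sx[ei],
                  by = c$beta[ci] * s,
                  sy = c$se[ci])
  ivw(h, mode = match.arg(mode))
}
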