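COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

complement_allele <- function(a) {
  out <- unname(COMPLEMENT[a])
  out[is.na(out)] <- a[is.na(out)]  # indels pass through
  out
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonise exposure and outcome summary statistics to a common effect allele
#'
#' Aligns the outcome dataset's per-SNP effects to the exposure dataset's
#' effect alleles so that the ratio by/bx is meaningful:
#'
#' * matching alleles are kept as-is;
#' * swapped alleles (outcome effect allele equals exposure other allele)
#'   have the outcome beta sign flipped and `eaf_y` replaced by `1 - eaf_y`;
#' * strand complements (e.g. A/G vs T/C) are resolved before the swap test;
#' * palindromic SNPs (A/T or C/G) cannot be strand-resolved from alleles:
#'   those with minor allele frequency at or above
#'   `maf_palindrome_threshold` in either dataset are dropped; below the
#'   threshold they are aligned by frequency so the effect allele is the
#'   minor (or major) allele in both datasets;
#' * irreconcilable allele pairs are dropped as mismatches.
#'
#' @param exposure,outcome [sumstats()] objects sharing SNPs.
#' @param maf_palindrome_threshold inclusive MAF cut-off for excluding
#'   palindromic SNPs (default 0.42).
#' @return an object of class `harmonised_pair`: a data frame with columns
#'   `snp_id`, `bx`, `sx`, `by`, `sy`, `eaf_x`, `eaf_y`, `nx`, `ny`,
#'   `action` restricted to retained SNPs, with attributes `exposure`,
#'   `outcome`, `unit_x`, `unit_y`, `outcome_binary` and `audit` (per-SNP
#'   action/reason table including dropped SNPs).
#' @export
harmonise_pair <- function(exposure, outcome, maf_palindrome_threshold = 0.42) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  ex <- as.data.frame(exposure)
  oy <- as.data.frame(outcome)
  shared <- intersect(ex$snp_id, oy$snp_id)
  if (length(shared) == 0) {
    stop("no shared SNPs between exposure and outcome", call. = FALSE)
  }
  ex <- ex[match(shared, ex$snp_id), , drop = FALSE]
  oy <- oy[match(shared, oy$snp_id), , drop = FALSE]

  n <- length(shared)
  action <- character(n)
  reason <- character(n)
  by <- oy$beta
  eaf_y <- oy$eaf

  pal_x <- is_palindromic(ex$effect_allele, ex$other_allele)
  pal_y <- is_palindromic(oy$effect_allele, oy$other_allele)

  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- oy$effect_allele[i]; oa_y <- oy$other_allele[i]

    if (pal_x[i] || pal_y[i]) {
      if (!(pal_x[i] && pal_y[i]) ||
          !setequal(c(ea_x, oa_x), c(ea_y, oa_y))) {
        action[i] <- "dropped-mismatch"
        reason[i] <- "palindrome paired with non-matching alleles"
        next
      }
      if (is.na(ex$eaf[i]) || is.na(oy$eaf[i])) {
        action[i] <- "dropped-palindrome"
        reason[i] <- "palindromic SNP without eaf cannot be strand-resolved"
        next
      }
      maf_x <- min(ex$eaf[i], 1 - ex$eaf[i])
      maf_y <- min(oy$eaf[i], 1 - oy$eaf[i])
      if (maf_x >= maf_palindrome_threshold ||
          maf_y >= maf_palindrome_threshold) {
        action[i] <- "dropped-palindrome"
        reason[i] <- sprintf("palindromic with MAF >= %.2f",
                             maf_palindrome_threshold)
        next
      }
      # align labels, then resolve strand by frequency concordance
      flips <- 0L
      e_y <- oy$eaf[i]
      if (ea_y == oa_x) { flips <- flips + 1L; e_y <- 1 - e_y }
      if ((ex$eaf[i] < 0.5) != (e_y < 0.5)) { flips <- flips + 1L; e_y <- 1 - e_y }
      if (flips %% 2L == 1L) {
        by[i] <- -by[i]
        eaf_y[i] <- e_y
        action[i] <- "flipped"
        reason[i] <- "palindrome aligned by allele frequency"
      } else {
        eaf_y[i] <- e_y
        action[i] <- "kept-as-is"
        reason[i] <- "palindrome frequency-concordant"
      }
      next
    }

    # non-palindromic: try direct, swapped, complement, complement-swapped
    cea_y <- complement_allele(ea_y); coa_y <- complement_allele(oa_y)
    if (ea_y == ea_x && oa_y == oa_x) {
      action[i] <- "kept-as-is"; reason[i] <- "alleles match"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      by[i] <- -by[i]; eaf_y[i] <- 1 - eaf_y[i]
      action[i] <- "flipped"; reason[i] <- "alleles swapped"
    } else if (cea_y == ea_x && coa_y == oa_x) {
      action[i] <- "kept-as-is"; reason[i] <- "strand complement"
    } else if (cea_y == oa_x && coa_y == ea_x) {
      by[i] <- -by[i]; eaf_y[i] <- 1 - eaf_y[i]
      action[i] <- "flipped"; reason[i] <- "strand complement, swapped"
    } else {
      action[i] <- "dropped-mismatch"
      reason[i] <- "irreconcilable allele pair"
    }
  }

  audit <- data.frame(snp_id = shared, action = action, reason = reason,
                      stringsAsFactors = FALSE)
  keep <- !startsWith(action, "dropped")
  h <- data.frame(
    snp_id = shared[keep],
    effect_allele = ex$effect_allele[keep],
    other_allele = ex$other_allele[keep],
    bx = ex$beta[keep], sx = ex$se[keep],
    by = by[keep], sy = oy$se[keep],
    eaf_x = ex$eaf[keep], eaf_y = eaf_y[keep],
    nx = ex$n[keep], ny = oy$n[keep],
    action = action[keep],
    stringsAsFactors = FALSE
  )
  rownames(h) <- NULL
  structure(h,
            exposure = attr(exposure, "trait"),
            outcome = attr(outcome, "trait"),
            unit_x = attr(exposure, "unit"),
            unit_y = attr(outcome, "unit"),
            outcome_binary = identical(attr(outcome, "unit"), "log-odds"),
            audit = audit,
            class = c("harmonised_pair", "data.frame"))
}

#' Harmonisation audit trail
#' @param h a [harmonise_pair()] result.
#' @return data frame with `snp_id`, `action`, `reason` for every shared SNP
#'   (retained and dropped).
#' @export
harmonise_audit <- function(h) attr(h, "audit")

#' Write the harmonisation audit TSV
#' @param h a [harmonise_pair()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_harmonise_audit <- function(h, path) {
  utils::write.table(harmonise_audit(h), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Harmonise several exposures and an outcome to one effect-allele frame
#'
#' Builds the input for multivariable MR: the SNP set is restricted to SNPs
#' present in every dataset; all traits are aligned to the first exposure's
#' effect alleles using the same palindrome and mismatch rules as
#' [harmonise_pair()]. A SNP dropped against any dataset is dropped from the
#' whole set.
#'
#' @param exposures list of >= 2 [sumstats()] objects (first is the primary
#'   exposure).
#' @param outcome a [sumstats()] object.
#' @param maf_palindrome_threshold see [harmonise_pair()].
#' @param pheno_corr optional square matrix of phenotypic correlations
#'   between the exposures (unit diagonal), used to approximate SNP-exposure
#'   covariance in conditional F-statistics; defaults to the identity
#'   (independent samples).
#' @return an object of class `mvmr_set`: list with `snp_id`,
#'   `exposure_betas` (n_snp x k matrix), `exposure_ses`, `outcome_beta`,
#'   `outcome_se`, `pheno_corr`, `exposures`, `outcome`.
#' @export
harmonise_multi <- function(exposures, outcome,
                            maf_palindrome_threshold = 0.42,
                            pheno_corr = NULL) {
  stopifnot(is.list(exposures), length(exposures) >= 2)
  k <- length(exposures)
  names_x <- vapply(exposures, function(e) attr(e, "trait"), character(1))

  pairs <- lapply(exposures, harmonise_pair, outcome = outcome,
                  maf_palindrome_threshold = maf_palindrome_threshold)
  # anchor frame: first exposure vs outcome
  anchor <- pairs[[1]]
  snps <- anchor$snp_id
  for (j in 2:k) snps <- intersect(snps, pairs[[j]]$snp_id)
  if (length(snps) == 0) stop("no SNPs shared by all datasets", call. = FALSE)

  bx <- matrix(NA_real_, length(snps), k, dimnames = list(snps, names_x))
  sx <- bx
  for (j in seq_len(k)) {
    hj <- pairs[[j]]
    idx <- match(snps, hj$snp_id)
    # express exposure j's effects on the anchor's effect allele: each pair
    # is aligned exposure_j -> outcome; re-align to anchor via the outcome
    # frame (outcome by is identical across pairs up to the sign flip applied
    # to match exposure j, so the exposure beta needs the same flip applied
    # relative to the anchor orientation)
    same_sign <- sign_match(anchor, hj, snps)
    bx[, j] <- hj$bx[idx] * same_sign
    sx[, j] <- hj$sx[idx]
  }
  a_idx <- match(snps, anchor$snp_id)

  if (is.null(pheno_corr)) pheno_corr <- diag(k)
  pheno_corr <- as.matrix(pheno_corr)
  stopifnot(nrow(pheno_corr) == k, ncol(pheno_corr) == k)
  dimnames(pheno_corr) <- list(names_x, names_x)

  structure(list(
    snp_id = snps,
    exposure_betas = bx,
    exposure_ses = sx,
    outcome_beta = anchor$by[a_idx],
    outcome_se = anchor$sy[a_idx],
    pheno_corr = pheno_corr,
    exposures = names_x,
    outcome = attr(anchor, "outcome"),
    outcome_binary = attr(anchor, "outcome_binary")
  ), class = "mvmr_set")
}

# +1 where pair hj's effect allele matches the anchor pair's (directly or by
# strand complement), -1 where it matches the anchor's other allele.
sign_match <- function(anchor, hj, snps) {
  ai <- match(snps, anchor$snp_id)
  ji <- match(snps, hj$snp_id)
  ea_a <- anchor$effect_allele[ai]; oa_a <- anchor$other_allele[ai]
  ea_j <- hj$effect_allele[ji]
  cea_j <- complement_allele(ea_j)
  s <- rep(NA_real_, length(snps))
  s[ea_j == ea_a | cea_j == ea_a] <- 1
  s[ea_j == oa_a | cea_j == oa_a] <- -1
  # palindromes match both ways; direct label equality wins there
  s[ea_j == ea_a] <- 1
  if (anyNA(s)) stop("unalignable alleles across exposures", call. = FALSE)
  s
}
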