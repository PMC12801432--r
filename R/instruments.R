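#' Pairwise linkage-disequilibrium information
#'
#' Container for pairwise r-squared between candidate instruments, used by
#' [clump()]. LD is an input (supplied as a matrix or long-format table),
#' never computed from a remote reference panel; the simulator emits exact
#' r-squared from its generated genotypes.
#'
#' @param snp_ids character vector of variant identifiers.
#' @param r2 square symmetric matrix of r-squared values in [0,1] with unit
#'   diagonal, rows/columns ordered as `snp_ids`.
#' @return an object of class `ld_info`.
#' @export
ld_info <- function(snp_ids, r2) {
  r2 <- as.matrix(r2)
  stopifnot(length(snp_ids) == nrow(r2), nrow(r2) == ncol(r2))
  if (any(r2 < -1e-8 | r2 > 1 + 1e-8, na.rm = TRUE)) {
    stop("r2 values must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 matrix must be symmetric",
                                        call. = FALSE)
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("r2 diagonal must be 1",
                                          call. = FALSE)
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r2 = r2),
            class = "ld_info")
}

#' Read long-format LD table (columns snp_a, snp_b, r2)
#'
#' Pairs absent from the table are taken as r2 = 0 (unlinked).
#'
#' @param path tab-separated file with header `snp_a`, `snp_b`, `r2`.
#' @return an [ld_info()] object.
#' @export
read_ld <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(df)))
  ids <- unique(c(df$snp_a, df$snp_b))
  m <- diag(length(ids))
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(nrow(df))) {
    m[df$snp_a[i], df$snp_b[i]] <- df$r2[i]
    m[df$snp_b[i], df$snp_a[i]] <- df$r2[i]
  }
  ld_info(ids, m)
}

#' Select genome-wide-significant candidate instruments
#'
#' Subsets a summary-statistics table to SNPs with association p-value
#' strictly below the genome-wide significance threshold (default
#' 5e-8). An empty result is allowed.
#'
#' @param s a [sumstats()] object.
#' @param p_threshold significance level; the comparison is strict (`<`).
#' @return a [sumstats()] object (subset of `s`).
#' @export
select_gws <- function(s, p_threshold = 5e-8) {
  stopifnot(inherits(s, "sumstats"))
  if (anyNA(s$pval)) stop("pval must be present for all records", call. = FALSE)
  keep <- s$pval < p_threshold
  sumstats(as.data.frame(s)[keep, , drop = FALSE],
           trait = attr(s, "trait"), unit = attr(s, "unit"),
           ancestry = attr(s, "ancestry"), validate = FALSE)
}

#' Greedy LD clumping of candidate instruments
#'
#' Repeatedly takes the remaining SNP with the smallest p-value as an index
#' variant and removes all remaining SNPs on the same chromosome within
#' `window_kb` of it whose r-squared with the index is at or above
#' `r2_threshold`. Among correlated SNPs, those with the smallest p-values
#' are retained. P-value ties are broken by larger |beta/se|, then
#' lexicographic `snp_id`, so the procedure is deterministic.
#'
#' @param candidates a [sumstats()] object with `chrom` and `pos` filled.
#' @param ld an [ld_info()] object covering every candidate.
#' @param r2_threshold r-squared cut-off (default 0.001).
#' @param window_kb window half-width in kilobases (default 10000).
#' @return a [sumstats()] object of index SNPs, ordered by p-value.
#' @export
clump <- function(candidates, ld, r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(inherits(candidates, "sumstats"), inherits(ld, "ld_info"))
  df <- as.data.frame(candidates)
  if (nrow(df) == 0) return(candidates)
  missing <- setdiff(df$snp_id, ld$snp_ids)
  if (length(missing) > 0) {
    stop("candidate SNP(s) missing from LD information: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (anyNA(df$chrom) || anyNA(df$pos)) {
    stop("clumping requires chrom and pos for every candidate", call. = FALSE)
  }
  ord <- order(df$pval, -abs(df$beta / df$se), df$snp_id)
  df <- df[ord, , drop = FALSE]
  window_bp <- window_kb * 1000

  alive <- rep(TRUE, nrow(df))
  index <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!alive[i]) next
    index[i] <- TRUE
    alive[i] <- FALSE
    if (!any(alive)) break
    rest <- which(alive)
    same_chr <- df$chrom[rest] == df$chrom[i]
    in_window <- abs(df$pos[rest] - df$pos[i]) <= window_bp
    r2 <- ld$r2[df$snp_id[i], df$snp_id[rest]]
    alive[rest[same_chr & in_window & r2 >= r2_threshold]] <- FALSE
  }
  sumstats(df[index, , drop = FALSE],
           trait = attr(candidates, "trait"), unit = attr(candidates, "unit"),
           ancestry = attr(candidates, "ancestry"), validate = FALSE)
}

#' Instrument strength: per-SNP F-statistics and variance explained
#'
#' Per-SNP F = beta^2 / se^2 (invariant to unit rescaling). Variance
#' explained uses the standardised effect beta_SD = beta / phenotype_sd:
#' per-SNP R^2 = 2 * beta_SD^2 * MAF * (1 - MAF) with MAF = min(eaf, 1-eaf);
#' `total_r2` is the sum over SNPs (valid for independent, clumped
#' instruments). SNPs with missing `eaf` are excluded from the R^2 sum with
#' a warning; they still contribute to the F summaries.
#'
#' @param inst a [sumstats()] object of selected instruments.
#' @param phenotype_sd standard deviation of the exposure phenotype in the
#'   same units as `beta` (must be supplied; > 0).
#' @return an object of class `instrument_set`: list with `exposure`,
#'   `records`, `f_per_snp`, `mean_f`, `min_f`, `max_f`, `total_r2`,
#'   `r2_per_snp`, `n_snp`.
#' @export
instrument_strength <- function(inst, phenotype_sd) {
  stopifnot(inherits(inst, "sumstats"), is.numeric(phenotype_sd),
            phenotype_sd > 0, nrow(inst) >= 1)
  if (any(inst$se <= 0)) stop("se must be positive", call. = FALSE)
  f <- inst$beta^2 / inst$se^2
  beta_sd <- inst$beta / phenotype_sd
  maf <- pmin(inst$eaf, 1 - inst$eaf)
  r2 <- 2 * beta_sd^2 * maf * (1 - maf)
  if (anyNA(maf)) {
    warning(sum(is.na(maf)), " SNP(s) without eaf excluded from R^2",
            call. = FALSE)
  }
  structure(list(
    exposure = attr(inst, "trait"),
    records = as.data.frame(inst),
    f_per_snp = f,
    mean_f = mean(f),
    min_f = min(f),
    max_f = max(f),
    r2_per_snp = r2,
    total_r2 = sum(r2, na.rm = TRUE),
    n_snp = nrow(inst)
  ), class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set for ", x$exposure, ": ", x$n_snp, " SNPs\n",
      "  mean F = ", format(x$mean_f, digits = 4),
      " (range ", format(x$min_f, digits = 4), " to ",
      format(x$max_f, digits = 4), ")\n",
      "  total R^2 = ", format(100 * x$total_r2, digits = 3), "%\n", sep = "")
  invisible(x)
}

#' Compare per-SNP effects between two datasets (instrument relevance)
#'
#' Quantifies how well instrument effects estimated in one setting (e.g. a
#' general-population GWAS) transfer to another (e.g. measurements taken
#' during pregnancy): Pearson correlation with its two-sided p-value, plus
#' an ordinary least-squares regression of the second dataset's effects on
#' the first's (slope 1 means equal average effects; slope below 1 means
#' attenuated effects in dataset `b`).
#'
#' Shared SNPs are aligned by effect allele (swapped alleles are flipped)
#' before comparison.
#'
#' @param a,b [sumstats()] objects sharing at least 3 SNPs.
#' @return list of class `relevance_report`: `pearson_r`, `r_pval`, `slope`,
#'   `intercept`, `reg_r2`, `n_snp`.
#' @export
compare_effects <- function(a, b) {
  stopifnot(inherits(a, "sumstats"), inherits(b, "sumstats"))
  da <- as.data.frame(a); db <- as.data.frame(b)
  shared <- intersect(da$snp_id, db$snp_id)
  da <- da[match(shared, da$snp_id), , drop = FALSE]
  db <- db[match(shared, db$snp_id), , drop = FALSE]
  same <- da$effect_allele == db$effect_allele & da$other_allele == db$other_allele
  swapped <- da$effect_allele == db$other_allele & da$other_allele == db$effect_allele
  keep <- same | swapped
  da <- da[keep, , drop = FALSE]; db <- db[keep, , drop = FALSE]
  db$beta[swapped[keep]] <- -db$beta[swapped[keep]]
  if (nrow(da) < 3) {
    stop("fewer than 3 shared harmonisable SNPs between datasets",
         call. = FALSE)
  }
  ct <- stats::cor.test(da$beta, db$beta)
  fit <- stats::lm(db$beta ~ da$beta)
  # exact collinearity (e.g. comparing a dataset with itself) is legitimate
  # here; summary.lm's perfect-fit warning is not informative
  fit_summary <- suppressWarnings(summary(fit))
  structure(list(
    pearson_r = unname(ct$estimate),
    r_pval = ct$p.value,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    reg_r2 = fit_summary$r.squared,
    n_snp = nrow(da)
  ), class = "relevance_report")
}

#' @export
print.relevance_report <- function(x, ...) {
  cat("Effect comparison over ", x$n_snp, " SNPs: r = ",
      format(x$pearson_r, digits = 3), " (p = ",
      format(x$r_pval, digits = 3), "); slope = ",
      format(x$slope, digits = 3), ", intercept = ",
      format(x$intercept, digits = 3), ", R^2 = ",
      format(x$reg_r2, digits = 3), "\n", sep = "")
  invisible(x)
}
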