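#' GWAS summary statistics container
#'
#' A `sumstats` object is a data frame of per-variant association summaries
#' (one row per SNP) with trait metadata attached as attributes. It is the
#' universal currency of the pipeline: instrument selection, harmonisation,
#' estimation and the simulator all consume and produce `sumstats`.
#'
#' Canonical columns: `snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`, `n_case`. Units of
#' `beta` depend on the trait: mmHg per allele for blood pressure exposures,
#' log-odds per allele for binary outcomes, SD or weeks per allele for
#' continuous outcomes.
#'
#' @param records data frame with the canonical columns (missing optional
#'   columns `chrom`, `pos`, `eaf`, `n`, `n_case` are filled with `NA`).
#' @param trait trait name.
#' @param unit unit label, one of `"mmHg"`, `"log-odds"`, `"SD"`, `"weeks"`
#'   (free text tolerated).
#' @param ancestry free-text ancestry label.
#' @param validate drop rows violating record invariants (with a message)?
#'
#' @return a data frame of class `sumstats` with attributes `trait`, `unit`,
#'   `ancestry`.
#' @export
sumstats <- function(records, trait = "trait", unit = "SD",
                     ancestry = "European", validate = TRUE) {
  stopifnot(is.data.frame(records))
  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- setdiff(mandatory, names(records))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  optional <- c("chrom", "pos", "eaf", "n", "n_case")
  for (col in setdiff(optional, names(records))) records[[col]] <- NA
  records <- records[, c("snp_id", "chrom", "pos", "effect_allele",
                         "other_allele", "eaf", "beta", "se", "pval",
                         "n", "n_case")]
  records$snp_id <- as.character(records$snp_id)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n", "n_case")) {
    records[[col]] <- as.numeric(records[[col]])
  }

  if (validate && nrow(records) > 0) {
    ok <- validate_records(records)
    n_drop <- sum(!ok)
    if (n_drop > 0) {
      message("sumstats: dropped ", n_drop,
              " record(s) violating invariants (trait: ", trait, ")")
      records <- records[ok, , drop = FALSE]
    }
  }
  if (anyDuplicated(records$snp_id)) {
    stop("duplicate snp_id in summary statistics", call. = FALSE)
  }
  rownames(records) <- NULL
  structure(records,
            trait = trait, unit = unit, ancestry = ancestry,
            class = c("sumstats", "data.frame"))
}

# Row-level invariants. eaf may be missing (NA passes; the record is then
# ineligible for palindrome resolution and R^2, handled downstream).
validate_records <- function(r) {
  ok <- !is.na(r$snp_id) & nzchar(r$snp_id) &
    !is.na(r$effect_allele) & !is.na(r$other_allele) &
    r$effect_allele != r$other_allele &
    !is.na(r$beta) & is.finite(r$beta) &
    !is.na(r$se) & r$se > 0 &
    !is.na(r$pval) & r$pval >= 0 & r$pval <= 1
  ok <- ok & (is.na(r$eaf) | (r$eaf > 0 & r$eaf < 1))
  # p-value consistency with beta/se is a warning, never a drop
  z <- abs(r$beta / r$se)
  expected <- -stats::pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10) -
    log10(2)
  observed <- -log10(pmax(r$pval, .Machine$double.xmin))
  fishy <- ok & is.finite(expected) & r$pval > 0 &
    abs(expected - observed) > 0.5 & observed < 300
  if (any(fishy, na.rm = TRUE)) {
    warning(sum(fishy, na.rm = TRUE),
            " record(s) with p-value inconsistent with beta/se by > 0.5",
            " log10 units", call. = FALSE)
  }
  ok
}

#' @export
print.sumstats <- function(x, ...) {
  cat("GWAS summary statistics: ", attr(x, "trait"),
      " [", attr(x, "unit"), "], ", nrow(x), " variants, ancestry: ",
      attr(x, "ancestry"), "\n", sep = "")
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Trait metadata accessors
#' @param s a `sumstats` object.
#' @return character scalar.
#' @export
trait_name <- function(s) attr(s, "trait")

#' @rdname trait_name
#' @export
trait_unit <- function(s) attr(s, "unit")

# default column-name mapping: canonical names plus common GWAS Catalog /
# GWAS-SSF export headers
default_dialect <- function() {
  c(snp_id = "snp_id", chrom = "chrom", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pval = "pval",
    n = "n", n_case = "n_case")
}

#' Read GWAS summary statistics from a TSV file
#'
#' Tab-delimited, '.' decimal, mandatory header. The `dialect` argument maps
#' canonical column names to the file's headers so that GWAS Catalog /
#' GWAS-SSF exports (e.g. `variant_id`, `rsid`, `chromosome`,
#' `base_pair_location`, `effect_allele_frequency`, `standard_error`,
#' `p_value`) can be read without preprocessing.
#'
#' Rows violating record invariants (allele identity, `eaf` outside (0,1),
#' non-positive `se`, p-value outside [0,1]) are dropped with a logged count.
#'
#' @param path file path to a tab-separated table with a header row.
#' @param dialect named character vector mapping canonical names
#'   (`snp_id`, `chrom`, ..., see [sumstats()]) to column names in the file.
#'   Unmentioned canonical names fall back to their own spelling.
#' @param trait,unit,ancestry metadata labels, see [sumstats()].
#' @return a [sumstats()] object.
#' @export
read_sumstats <- function(path, dialect = NULL, trait = NULL, unit = "SD",
                          ancestry = "European") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    stop("empty summary-statistics file: ", path, call. = FALSE)
  }
  map <- default_dialect()
  if (!is.null(dialect)) map[names(dialect)] <- dialect

  out <- data.frame(row.names = seq_len(nrow(raw)))
  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")
  for (canon in names(map)) {
    col <- map[[canon]]
    if (col %in% names(raw)) {
      out[[canon]] <- raw[[col]]
    } else if (canon %in% mandatory) {
      stop("missing mandatory column '", col, "' (for ", canon, ") in ",
           path, call. = FALSE)
    }
  }
  if (is.null(trait)) trait <- sub("\\.[^.]*$", "", basename(path))
  sumstats(out, trait = trait, unit = unit, ancestry = ancestry)
}

#' Write GWAS summary statistics to a TSV file
#'
#' Fixed canonical column order, full-precision floats (up to 17 significant
#' digits), so that a write/read round trip is lossless.
#'
#' @param s a [sumstats()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(s, path) {
  stopifnot(inherits(s, "sumstats"))
  df <- as.data.frame(s)
  for (col in names(df)) {
    if (is.numeric(df[[col]])) {
      df[[col]] <- vapply(df[[col]], function(v) {
        if (is.na(v)) "NA" else format(v, digits = 17, scientific = NA)
      }, character(1))
    }
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) {
    stop("cannot write summary statistics to ", path, ": ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

#' Fixed-effect meta-analysis of per-SNP associations across studies
#'
#' Inverse-variance fixed-effect pooling of study-specific GWAS summary
#' statistics, the model used to combine cohort-level outcome associations
#' into a single per-SNP estimate. For each SNP present in k studies the
#' pooled effect is sum(beta_i/se_i^2) / sum(1/se_i^2) with standard error
#' (sum 1/se_i^2)^(-1/2); sample sizes are summed. SNPs present in a single
#' study carry that study's values unchanged.
#'
#' All studies must already be aligned to a common effect allele per SNP
#' (see [harmonise_pair()]); conflicting alleles raise an error.
#'
#' @param studies list of [sumstats()] objects (length >= 1).
#' @param trait,unit,ancestry metadata for the pooled result; default from
#'   the first study.
#' @return a [sumstats()] object with pooled `beta`, `se`, recomputed
#'   two-sided normal `pval`, summed `n`/`n_case`, and sample-size-weighted
#'   `eaf`.
#' @export
meta_analyse_fixed <- function(studies, trait = NULL, unit = NULL,
                               ancestry = NULL) {
  stopifnot(is.list(studies), length(studies) >= 1,
            all(vapply(studies, inherits, logical(1), "sumstats")))
  if (length(studies) == 1) return(studies[[1]])

  all_rows <- do.call(rbind, lapply(studies, as.data.frame))
  split_rows <- split(all_rows, all_rows$snp_id)

  pooled <- lapply(split_rows, function(g) {
    if (length(unique(paste(g$effect_allele, g$other_allele))) > 1) {
      stop("conflicting alleles for snp ", g$snp_id[1],
           "; harmonise studies before meta-analysis", call. = FALSE)
    }
    if (nrow(g) == 1) return(g)
    w <- 1 / g$se^2
    beta <- sum(w * g$beta) / sum(w)
    se <- sqrt(1 / sum(w))
    out <- g[1, , drop = FALSE]
    out$beta <- beta
    out$se <- se
    out$pval <- 2 * stats::pnorm(-abs(beta / se))
    out$n <- if (all(is.na(g$n))) NA else sum(g$n, na.rm = TRUE)
    out$n_case <- if (all(is.na(g$n_case))) NA else sum(g$n_case, na.rm = TRUE)
    out$eaf <- if (all(is.na(g$eaf)) || all(is.na(g$n))) {
      mean(g$eaf, na.rm = FALSE)
    } else {
      sum(g$eaf * g$n, na.rm = TRUE) / sum(g$n[!is.na(g$eaf)], na.rm = TRUE)
    }
    out
  })
  res <- do.call(rbind, pooled)
  res <- res[order(match(res$snp_id, all_rows$snp_id)), , drop = FALSE]
  sumstats(res,
           trait = trait %||% attr(studies[[1]], "trait"),
           unit = unit %||% attr(studies[[1]], "unit"),
           ancestry = ancestry %||% attr(studies[[1]], "ancestry"),
           validate = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
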