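#' Analysis configuration for a wide-angled MR run
#'
#' Bundles the exposure dataset, an outcome panel, optional covariate
#' exposures for multivariable MR, optional replicate (non-overlapping)
#' exposure data, and all thresholds. Dataset arguments accept either
#' [sumstats()] objects or file paths (read with [read_sumstats()] at run
#' time).
#'
#' @param exposure exposure GWAS ([sumstats()] or path).
#' @param outcomes named list; each element a list with fields `data`
#'   ([sumstats()] or path), `binary` (logical), and optionally `primary`
#'   (logical, default `TRUE`), `fetal` and `paternal` (marginal fetal /
#'   paternal outcome GWAS for the weighted-linear-model adjustment).
#' @param exposure_replicate optional second exposure GWAS from a
#'   non-overlapping sample, for the sample-overlap comparison.
#' @param covariates optional named list of covariate exposure GWAS for
#'   multivariable MR.
#' @param pheno_corr optional phenotypic correlation matrix over
#'   `c(exposure, covariates)` for conditional F approximation.
#' @param ld optional [ld_info()] (or long-format TSV path) for clumping;
#'   when absent the exposure is assumed pre-clumped.
#' @param p_select,clump_r2,clump_window_kb,palindrome_maf,fdr_level,scale
#'   pipeline thresholds (defaults: 5e-8, 0.001, 10000, 0.42, 0.05, 10).
#' @param n_boot,seed bootstrap replicates and seed for the median/mode
#'   estimators.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(exposure, outcomes,
                            exposure_replicate = NULL,
                            covariates = NULL, pheno_corr = NULL,
                            ld = NULL,
                            p_select = 5e-8, clump_r2 = 0.001,
                            clump_window_kb = 10000, palindrome_maf = 0.42,
                            fdr_level = 0.05, scale = 10,
                            n_boot = 1000, seed = 1L) {
  stopifnot(is.list(outcomes), length(outcomes) >= 1,
            !is.null(names(outcomes)), all(nzchar(names(outcomes))))
  if (anyDuplicated(names(outcomes))) {
    stop("outcome names must be unique", call. = FALSE)
  }
  structure(list(exposure = exposure, outcomes = outcomes,
                 exposure_replicate = exposure_replicate,
                 covariates = covariates, pheno_corr = pheno_corr,
                 ld = ld,
                 p_select = p_select, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb,
                 palindrome_maf = palindrome_maf,
                 fdr_level = fdr_level, scale = scale,
                 n_boot = n_boot, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [analysis_config()]; dataset entries are
#' file paths resolved relative to the config file's directory.
#'
#' @param path YAML file.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p)) NULL else file.path(base, p)
  outcomes <- lapply(raw$outcomes, function(o) {
    list(data = rel(o$file), binary = isTRUE(o$binary),
         primary = !isFALSE(o$primary),
         fetal = rel(o$fetal), paternal = rel(o$paternal))
  })
  names(outcomes) <- vapply(raw$outcomes, `[[`, character(1), "name")
  covariates <- NULL
  if (!is.null(raw$covariates)) {
    covariates <- lapply(raw$covariates, function(x) rel(x$file))
    names(covariates) <- vapply(raw$covariates, `[[`, character(1), "name")
  }
  thr <- function(key, default) raw[[key]] %||% default
  analysis_config(
    exposure = rel(raw$exposure),
    outcomes = outcomes,
    exposure_replicate = rel(raw$exposure_replicate),
    covariates = covariates,
    pheno_corr = if (is.null(raw$pheno_corr)) NULL else
      as.matrix(utils::read.delim(rel(raw$pheno_corr), row.names = 1)),
    ld = rel(raw$ld),
    p_select = thr("p_select", 5e-8),
    clump_r2 = thr("clump_r2", 0.001),
    clump_window_kb = thr("clump_window_kb", 10000),
    palindrome_maf = thr("palindrome_maf", 0.42),
    fdr_level = thr("fdr_level", 0.05),
    scale = thr("scale", 10),
    n_boot = thr("n_boot", 1000),
    seed = thr("seed", 1L)
  )
}

load_dataset <- function(x, unit = "SD", trait = NULL) {
  if (inherits(x, "sumstats")) return(x)
  read_sumstats(x, unit = unit, trait = trait)
}

empty_results_row <- function() {
  data.frame(exposure = character(0), outcome = character(0),
             method = character(0), adjustment = character(0),
             n_snp = integer(0), beta = numeric(0), se = numeric(0),
             ci_low = numeric(0), ci_high = numeric(0), pval = numeric(0),
             qval = numeric(0), or = numeric(0), or_low = numeric(0),
             or_high = numeric(0), q = numeric(0), q_pval = numeric(0),
             egger_intercept = numeric(0), egger_intercept_pval = numeric(0),
             steiger_direction = logical(0), steiger_pval = numeric(0),
             stringsAsFactors = FALSE)
}

result_row <- function(exposure, outcome, method, adjustment, est,
                       scaled = NULL, egger = NULL, st = NULL) {
  data.frame(
    exposure = exposure, outcome = outcome, method = method,
    adjustment = adjustment, n_snp = est$n_snp,
    beta = est$beta, se = est$se,
    ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pval,
    qval = NA_real_,
    or = if (!is.null(scaled) && !is.null(scaled$or_point))
      scaled$or_point else NA_real_,
    or_low = if (!is.null(scaled) && !is.null(scaled$or_low))
      scaled$or_low else NA_real_,
    or_high = if (!is.null(scaled) && !is.null(scaled$or_high))
      scaled$or_high else NA_real_,
    q = if (is.null(est$q)) NA_real_ else est$q,
    q_pval = if (is.null(est$q_pval)) NA_real_ else est$q_pval,
    egger_intercept = if (is.null(egger)) NA_real_ else egger$intercept,
    egger_intercept_pval = if (is.null(egger)) NA_real_ else
      egger$intercept_pval,
    steiger_direction = if (is.null(st)) NA else st$correct_direction,
    steiger_pval = if (is.null(st)) NA_real_ else st$pval,
    stringsAsFactors = FALSE
  )
}

#' Run the full wide-angled MR analysis over an outcome panel
#'
#' Per outcome: harmonisation, IVW (main), MR-Egger, weighted median,
#' weighted mode, Cochran's Q, Egger intercept and Steiger diagnostics, and
#' per-`scale`-unit effect presentation; Benjamini-Hochberg FDR across the
#' panel's main IVW p-values; weighted-linear-model fetal (and paternal)
#' adjustment where fetal data are supplied; multivariable MR with
#' conditional F where covariates are supplied; replicate-exposure overlap
#' comparison where a second exposure is supplied. A failing outcome is
#' reported and skipped without aborting the panel.
#'
#' @param cfg an [analysis_config()].
#' @return list of class `mr_results`: `results` (tidy data frame, one row
#'   per exposure x outcome x method x adjustment), `instruments`
#'   (instrument-selection audit), `failures` (named character vector of
#'   per-outcome error messages), `overlap` (replicate-comparison rows or
#'   `NULL`), `mvmr` (list of `mvmr_result` or `NULL`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  exposure <- load_dataset(cfg$exposure, unit = "mmHg")
  candidates <- select_gws(exposure, cfg$p_select)
  instruments <- if (!is.null(cfg$ld)) {
    ld <- if (inherits(cfg$ld, "ld_info")) cfg$ld else read_ld(cfg$ld)
    clump(candidates, ld, cfg$clump_r2, cfg$clump_window_kb)
  } else candidates
  exp_name <- trait_name(exposure)

  replicate <- if (!is.null(cfg$exposure_replicate)) {
    rep_full <- load_dataset(cfg$exposure_replicate, unit = "mmHg")
    idx <- match(instruments$snp_id, rep_full$snp_id)
    sumstats(as.data.frame(rep_full)[idx[!is.na(idx)], , drop = FALSE],
             trait = trait_name(rep_full), unit = "mmHg", validate = FALSE)
  } else NULL

  rows <- empty_results_row()
  failures <- character(0)
  overlap_rows <- NULL
  mvmr_out <- list()

  for (out_name in names(cfg$outcomes)) {
    spec_o <- cfg$outcomes[[out_name]]
    res <- tryCatch({
      outcome <- load_dataset(spec_o$data,
                              unit = if (isTRUE(spec_o$binary)) "log-odds"
                                     else "SD",
                              trait = out_name)
      h <- harmonise_pair(instruments, outcome, cfg$palindrome_maf)
      binary <- isTRUE(spec_o$binary)

      est_ivw <- ivw(h)
      est_egger <- mr_egger(h)
      est_med <- weighted_median(h, n_boot = cfg$n_boot, seed = cfg$seed)
      est_mode <- weighted_mode(h, n_boot = cfg$n_boot, seed = cfg$seed)
      st <- if (!anyNA(h$nx) && !anyNA(h$ny)) {
        steiger(h, if (binary) "binary" else "continuous")
      } else NULL

      out_rows <- rbind(
        result_row(exp_name, out_name, "ivw", "marginal", est_ivw,
                   scale_estimate(est_ivw, cfg$scale, binary),
                   egger = est_egger, st = st),
        result_row(exp_name, out_name, "egger", "marginal", est_egger$slope,
                   scale_estimate(est_egger$slope, cfg$scale, binary),
                   egger = est_egger),
        result_row(exp_name, out_name, "wmedian", "marginal", est_med,
                   scale_estimate(est_med, cfg$scale, binary)),
        result_row(exp_name, out_name, "wmode", "marginal", est_mode,
                   scale_estimate(est_mode, cfg$scale, binary))
      )

      # weighted-linear-model adjustment for fetal (and paternal) genotype
      if (!is.null(spec_o$fetal)) {
        fetal <- load_dataset(spec_o$fetal,
                              unit = trait_unit(outcome),
                              trait = paste0(out_name, "_fetal"))
        paternal <- if (!is.null(spec_o$paternal)) {
          load_dataset(spec_o$paternal, unit = trait_unit(outcome),
                       trait = paste0(out_name, "_paternal"))
        } else NULL
        tri <- trio_sumstats(outcome, fetal, paternal)
        cond <- wlm_duo(tri)
        est_duo <- ivw_conditional(cond, h)
        out_rows <- rbind(out_rows,
          result_row(exp_name, out_name, "ivw", "fetal-adjusted", est_duo,
                     scale_estimate(est_duo, cfg$scale, binary)))
        if (!is.null(paternal)) {
          cond3 <- wlm_trio(tri)
          est_trio <- ivw_conditional(cond3, h)
          out_rows <- rbind(out_rows,
            result_row(exp_name, out_name, "ivw", "fetal+paternal-adjusted",
                       est_trio, scale_estimate(est_trio, cfg$scale, binary)))
        }
      }

      # multivariable MR over the configured covariates
      if (!is.null(cfg$covariates) && length(cfg$covariates) > 0) {
        covs <- lapply(names(cfg$covariates), function(nm) {
          load_dataset(cfg$covariates[[nm]], trait = nm)
        })
        mset <- harmonise_multi(c(list(instruments), covs), outcome,
                                cfg$palindrome_maf, cfg$pheno_corr)
        mres <- mvmr_ivw(mset)
        mres$conditional_f <- conditional_f(mset)
        mvmr_out[[out_name]] <- mres
        main_idx <- 1L  # primary exposure is the first column
        est_mv <- mr_estimate("ivw",
                              mres$estimates$beta[main_idx],
                              mres$estimates$se[main_idx],
                              mres$estimates$pval[main_idx],
                              mres$n_snp, mres$q, mres$q_df, mres$q_pval)
        out_rows <- rbind(out_rows,
          result_row(exp_name, out_name, "ivw", "mvmr", est_mv,
                     scale_estimate(est_mv, cfg$scale, binary)))
      }

      # replicate (non-overlapping) exposure comparison
      if (!is.null(replicate)) {
        h_rep <- harmonise_pair(replicate, outcome, cfg$palindrome_maf)
        est_rep <- ivw(h_rep)
        out_rows <- rbind(out_rows,
          result_row(trait_name(replicate), out_name, "ivw",
                     "replicate-exposure", est_rep,
                     scale_estimate(est_rep, cfg$scale, binary)))
        cmp <- compare_overlap(est_ivw, est_rep)
        overlap_rows <- rbind(overlap_rows,
          data.frame(outcome = out_name, beta_main = cmp$beta_a,
                     beta_replicate = cmp$beta_b, z = cmp$z,
                     pval = cmp$pval,
                     note = cmp$note, stringsAsFactors = FALSE))
      }
      out_rows
    }, error = function(e) {
      failures[[out_name]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) rows <- rbind(rows, res)
  }

  # FDR family: main marginal IVW p-values across the panel's outcomes
  main <- rows$method == "ivw" & rows$adjustment == "marginal"
  if (any(main)) {
    rows$qval[main] <- bh_fdr(rows$pval[main], cfg$fdr_level)$qval
  }
  rownames(rows) <- NULL

  structure(list(results = rows,
                 instruments = instruments,
                 failures = failures,
                 overlap = overlap_rows,
                 mvmr = if (length(mvmr_out)) mvmr_out else NULL),
            class = "mr_results")
}

#' @export
print.mr_results <- function(x, ...) {
  cat("Wide-angled MR results: ", nrow(x$results), " rows over ",
      length(unique(x$results$outcome)), " outcome(s); ",
      nrow(x$instruments), " instruments\n", sep = "")
  if (length(x$failures)) {
    cat("Failed outcomes:\n")
    for (nm in names(x$failures)) cat("  ", nm, ": ", x$failures[[nm]], "\n",
                                      sep = "")
  }
  print(utils::head(x$results, 12), digits = 3)
  invisible(x)
}

#' Write the tidy results table as TSV
#' @param res an `mr_results` object (or its `results` data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(res, path) {
  df <- if (inherits(res, "mr_results")) res$results else res
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare MR estimates from two exposure sources
#'
#' Reports both estimates and the z statistic for their difference,
#' `z = (beta_a - beta_b) / sqrt(se_a^2 + se_b^2)`, under an independence
#' approximation (the two samples are treated as non-overlapping; noted in
#' the output). Used to check that estimates from partially overlapping
#' exposure-outcome samples agree with those from non-overlapping samples.
#'
#' @param a,b `mr_estimate` objects for the same outcome.
#' @return list with `beta_a`, `se_a`, `beta_b`, `se_b`, `z`, `pval`,
#'   `note`.
#' @export
compare_overlap <- function(a, b) {
  z <- (a$beta - b$beta) / sqrt(a$se^2 + b$se^2)
  list(beta_a = a$beta, se_a = a$se, beta_b = b$beta, se_b = b$se,
       z = z, pval = 2 * stats::pnorm(-abs(z)),
       note = "difference z assumes independent estimates")
}
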