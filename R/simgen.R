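#' Configuration for the synthetic intergenerational GWAS generator
#'
#' Defines the generative model for mother-father-child trios with a
#' maternal exposure (blood-pressure-like, mmHg) and a perinatal outcome
#' (binary log-odds or continuous), from which two-sample GWAS summary
#' statistics are scanned. Defaults describe the package's reference study
#' conditions: 100 independent instruments, samples of 20,000, a
#' diastolic-pressure-like exposure (phenotype SD about 10 mmHg), and a
#' binary outcome with true odds ratio 1.33 per 10 mmHg at 7% prevalence.
#' Per-allele effects are scaled so the instruments carry the strength (mean
#' F around 100) that million-sample discovery GWAS provide, preserving the
#' dimensionless quantity that governs MR estimator behaviour at desk scale.
#'
#' @param n_snps number of instruments (>= 1).
#' @param maf_range interval from which minor allele frequencies are drawn.
#' @param alpha_sd SD of per-allele exposure effects (mmHg per allele).
#' @param theta true causal effect of the exposure on the outcome per 10
#'   exposure units (log-odds for binary outcomes, outcome units for
#'   continuous).
#' @param pleiotropy_mode `"none"`, `"balanced"` (direct SNP-outcome effects
#'   centred at zero), `"directional"` (same-sign effects, half-normal), or
#'   `"correlated"` (effects correlated with instrument strength,
#'   InSIDE-violating).
#' @param pleiotropy_sd scale of the pleiotropic outcome effects.
#' @param pleiotropy_frac fraction of SNPs carrying pleiotropic effects
#'   (default 1; set to e.g. 0.3 for "30% invalid instruments").
#' @param fetal_effect_sd scale of direct fetal-genotype effects on the
#'   outcome (per allele of the child's genotype).
#' @param fetal_effect_mode `"proportional"` (fetal effect proportional to
#'   the SNP's exposure effect, the fetal-physiology pathway; makes the
#'   fetal-transmission bias systematic) or `"independent"`.
#' @param n_exposure,n_outcome GWAS sample sizes for the exposure and
#'   outcome scans.
#' @param overlap_frac fraction of the smaller sample shared between the two
#'   scans (0 = non-overlapping, 1 = fully overlapping).
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param prevalence case fraction for binary outcomes (in (0,1)).
#' @param treatment_frac fraction of mothers (those with the highest
#'   underlying exposure) whose measured exposure is lowered by treatment.
#' @param treatment_adjustment mmHg added back to treated mothers' measured
#'   values before the scan (the +15 systolic / +10 diastolic convention;
#'   default 10). The simulated treatment lowers measured values by the same
#'   amount.
#' @param x_noise_sd residual SD of the exposure (mmHg); with the default
#'   genetic variance the total phenotype SD is about 10 mmHg.
#' @param y_noise_sd residual SD of a continuous outcome.
#' @param ld_block_size instruments per LD block (1 = independent SNPs;
#'   larger values create correlated blocks to exercise clumping).
#' @param reverse_causation if `TRUE`, SNPs act directly on the outcome and
#'   the exposure is downstream of it (for directionality testing;
#'   continuous outcomes only).
#' @param seed integer seed; all generator output is reproducible
#'   bit-for-bit given the config.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 100,
                       maf_range = c(0.1, 0.5),
                       alpha_sd = 1.0,
                       theta = log(1.33),
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "correlated"),
                       pleiotropy_sd = 0.02,
                       pleiotropy_frac = 1,
                       fetal_effect_sd = 0,
                       fetal_effect_mode = c("proportional", "independent"),
                       n_exposure = 20000,
                       n_outcome = 20000,
                       overlap_frac = 0,
                       outcome_type = c("binary", "continuous"),
                       prevalence = 0.07,
                       treatment_frac = 0.1,
                       treatment_adjustment = 10,
                       x_noise_sd = 7.75,
                       y_noise_sd = 1,
                       ld_block_size = 1,
                       reverse_causation = FALSE,
                       seed = 1L) {
  cfg <- list(n_snps = n_snps, maf_range = maf_range, alpha_sd = alpha_sd,
              theta = theta,
              pleiotropy_mode = match.arg(pleiotropy_mode),
              pleiotropy_sd = pleiotropy_sd,
              pleiotropy_frac = pleiotropy_frac,
              fetal_effect_sd = fetal_effect_sd,
              fetal_effect_mode = match.arg(fetal_effect_mode),
              n_exposure = n_exposure, n_outcome = n_outcome,
              overlap_frac = overlap_frac,
              outcome_type = match.arg(outcome_type),
              prevalence = prevalence,
              treatment_frac = treatment_frac,
              treatment_adjustment = treatment_adjustment,
              x_noise_sd = x_noise_sd, y_noise_sd = y_noise_sd,
              ld_block_size = ld_block_size,
              reverse_causation = reverse_causation,
              seed = as.integer(seed))
  check_field <- function(ok, field, what) {
    if (!ok) stop("invalid sim_config field '", field, "': ", what,
                  call. = FALSE)
  }
  check_field(is.numeric(n_snps) && n_snps >= 1, "n_snps", "must be >= 1")
  check_field(length(maf_range) == 2 && maf_range[1] > 0 &&
                maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2],
              "maf_range", "must be an interval within (0, 0.5]")
  check_field(alpha_sd > 0, "alpha_sd", "must be positive")
  check_field(pleiotropy_sd >= 0, "pleiotropy_sd", "must be non-negative")
  check_field(pleiotropy_frac >= 0 && pleiotropy_frac <= 1,
              "pleiotropy_frac", "must be a fraction in [0,1]")
  check_field(fetal_effect_sd >= 0, "fetal_effect_sd", "must be non-negative")
  check_field(n_exposure >= 10 && n_outcome >= 10, "n_exposure",
              "sample sizes must be at least 10")
  check_field(overlap_frac >= 0 && overlap_frac <= 1, "overlap_frac",
              "must be a fraction in [0,1]")
  check_field(cfg$outcome_type != "binary" ||
                (prevalence > 0 && prevalence < 1), "prevalence",
              "must lie in (0,1) for binary outcomes")
  check_field(treatment_frac >= 0 && treatment_frac <= 1, "treatment_frac",
              "must be a fraction in [0,1]")
  check_field(x_noise_sd > 0, "x_noise_sd", "must be positive")
  check_field(ld_block_size >= 1 && ld_block_size == round(ld_block_size),
              "ld_block_size", "must be a positive integer")
  structure(cfg, class = "sim_config")
}

# Draw per-SNP ground truth: frequencies, positions, alleles, exposure
# effects alpha, pleiotropic outcome effects gamma, fetal effects delta.
draw_truth <- function(cfg) {
  p <- cfg$n_snps
  maf <- stats::runif(p, cfg$maf_range[1], cfg$maf_range[2])
  block <- rep(seq_len(ceiling(p / cfg$ld_block_size)),
               each = cfg$ld_block_size)[seq_len(p)]
  if (cfg$ld_block_size > 1) maf <- maf[match(block, block)]  # shared per block
  chrom <- ((block - 1) %% 22) + 1
  within <- stats::ave(seq_len(p), block, FUN = seq_along)
  pos <- 1e6 + (ceiling(block / 22) - 1) * 5e7 + (within - 1) * 1e3

  alpha <- stats::rnorm(p, 0, cfg$alpha_sd)
  n_pleio <- round(cfg$pleiotropy_frac * p)
  pleio_idx <- seq_len(n_pleio)
  gamma <- numeric(p)
  if (cfg$pleiotropy_sd > 0 && n_pleio > 0) {
    # "directional" means directional with respect to the exposure-raising
    # allele: a common positive outcome effect of the alleles that raise the
    # exposure (orientation-invariant, so MR-Egger's bx > 0 flip preserves it)
    g <- switch(cfg$pleiotropy_mode,
                none = numeric(n_pleio),
                balanced = stats::rnorm(n_pleio, 0, cfg$pleiotropy_sd),
                directional = sign(alpha[pleio_idx]) *
                  abs(stats::rnorm(n_pleio, 0, cfg$pleiotropy_sd)),
                correlated = 0.5 * cfg$pleiotropy_sd *
                  alpha[pleio_idx] / cfg$alpha_sd +
                  sqrt(0.75) * stats::rnorm(n_pleio, 0, cfg$pleiotropy_sd))
    gamma[pleio_idx] <- g
  }
  delta <- numeric(p)
  if (cfg$fetal_effect_sd > 0) {
    delta <- switch(cfg$fetal_effect_mode,
                    proportional = cfg$fetal_effect_sd * alpha / cfg$alpha_sd,
                    independent = stats::rnorm(p, 0, cfg$fetal_effect_sd))
  }
  # non-palindromic allele pairs so harmonisation is unambiguous by default
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pick <- sample.int(nrow(pairs), p, replace = TRUE)
  structure(list(
    snp_id = sprintf("snp%04d", seq_len(p)),
    chrom = chrom, pos = pos, block = block,
    effect_allele = pairs[pick, 1], other_allele = pairs[pick, 2],
    maf = maf, alpha = alpha, gamma = gamma, delta = delta,
    theta = cfg$theta
  ), class = "sim_truth")
}

# Genotypes for n individuals at the truth's SNPs. Independent SNPs by
# default; within an LD block, each haplotype copies the block founder's
# haplotype with probability 1 - mut, giving high pairwise r^2.
draw_genotypes <- function(truth, n, mut = 0.05) {
  p <- length(truth$maf)
  if (max(truth$block) == p) {  # all blocks singletons
    return(matrix(stats::rbinom(n * p, 2, rep(truth$maf, each = n)), n, p))
  }
  G <- matrix(0L, n, p)
  for (b in unique(truth$block)) {
    idx <- which(truth$block == b)
    maf <- truth$maf[idx[1]]
    h1 <- stats::rbinom(n, 1, maf)
    h2 <- stats::rbinom(n, 1, maf)
    for (j in idx) {
      m1 <- stats::runif(n) < mut
      m2 <- stats::runif(n) < mut
      a1 <- ifelse(m1, stats::rbinom(n, 1, maf), h1)
      a2 <- ifelse(m2, stats::rbinom(n, 1, maf), h2)
      G[, j] <- a1 + a2
    }
  }
  G
}

# Mendelian transmission: one allele from each parent.
transmit <- function(Gm, Gp) {
  n <- nrow(Gm); p <- ncol(Gm)
  hm <- matrix(stats::rbinom(n * p, 1, Gm / 2), n, p)
  hp <- matrix(stats::rbinom(n * p, 1, Gp / 2), n, p)
  hm + hp
}

#' Simulate an intergenerational trio cohort
#'
#' Generates `n` mother-father-child trios under the configured structural
#' model: parental genotypes from Binomial(2, MAF), child genotypes by
#' Mendelian transmission (mother-child dosage correlation 1/2), maternal
#' exposure X as the genetic score plus Gaussian noise, antihypertensive
#' treatment masking for the top `treatment_frac` of mothers, and outcome Y
#' generated from the exposure, maternal pleiotropic effects and direct
#' fetal-genotype effects (logistic for binary outcomes, so the conditional
#' log-odds per exposure unit equals `theta/10` exactly).
#'
#' @param cfg a [sim_config()].
#' @param truth optional pre-drawn truth (from an internal draw); drawn from
#'   `cfg` when `NULL`. Pass the same truth to generate several cohorts from
#'   one genetic architecture.
#' @param n cohort size (default `cfg$n_outcome`).
#' @param fetal,paternal generate child/father genotypes? (Child genotypes
#'   are always generated when fetal effects are active.)
#' @param use_seed set the RNG from `cfg$seed`? (`FALSE` when called inside
#'   a larger seeded generation.)
#' @return list of class `sim_cohort`: genotype matrices `Gm`, `Gp`, `Gc`
#'   (may be `NULL`), `x_true`, `x_measured`, `treated`, `x_adjusted`
#'   (measured plus treatment adjustment, the value the GWAS scans), `y`,
#'   `truth`, `cfg`.
#' @export
simulate_trio_cohort <- function(cfg, truth = NULL, n = cfg$n_outcome,
                                 fetal = TRUE, paternal = TRUE,
                                 use_seed = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (use_seed) {
    old <- local_seed(cfg$seed)
    on.exit(restore_seed(old))
  }
  if (is.null(truth)) truth <- draw_truth(cfg)
  need_child <- fetal || any(truth$delta != 0)
  Gm <- draw_genotypes(truth, n)
  Gp <- if (need_child || paternal) draw_genotypes(truth, n) else NULL
  Gc <- if (need_child) transmit(Gm, Gp) else NULL

  if (cfg$reverse_causation) {
    if (cfg$outcome_type != "continuous") {
      stop("reverse_causation scenarios require a continuous outcome",
           call. = FALSE)
    }
    y <- as.vector(Gm %*% truth$alpha) * (cfg$theta / 10) / cfg$alpha_sd +
      stats::rnorm(n, 0, cfg$y_noise_sd)
    # exposure downstream of the outcome
    x_true <- 3 * y + stats::rnorm(n, 0, cfg$x_noise_sd)
  } else {
    x_true <- as.vector(Gm %*% truth$alpha) + stats::rnorm(n, 0, cfg$x_noise_sd)
    lin <- (cfg$theta / 10) * x_true + as.vector(Gm %*% truth$gamma)
    if (!is.null(Gc) && any(truth$delta != 0)) {
      lin <- lin + as.vector(Gc %*% truth$delta)
    }
    if (cfg$outcome_type == "binary") {
      b0 <- stats::uniroot(function(b) mean(stats::plogis(b + lin)) -
                             cfg$prevalence,
                           interval = c(-40, 40), tol = 1e-10)$root
      y <- stats::rbinom(n, 1, stats::plogis(b0 + lin))
    } else {
      y <- lin + stats::rnorm(n, 0, cfg$y_noise_sd)
    }
  }

  treated <- rep(FALSE, n)
  x_measured <- x_true
  if (cfg$treatment_frac > 0) {
    cut <- stats::quantile(x_true, 1 - cfg$treatment_frac, names = FALSE)
    treated <- x_true > cut
    x_measured[treated] <- x_measured[treated] - cfg$treatment_adjustment
  }
  x_adjusted <- x_measured + cfg$treatment_adjustment * treated

  structure(list(Gm = Gm, Gp = Gp, Gc = Gc,
                 x_true = x_true, x_measured = x_measured,
                 treated = treated, x_adjusted = x_adjusted,
                 y = y, truth = truth, cfg = cfg),
            class = "sim_cohort")
}

# vectorised per-SNP simple linear regression of y on each genotype column
linear_scan <- function(G, y) {
  n <- length(y)
  storage.mode(G) <- "double"
  gm <- colMeans(G)
  yc <- y - mean(y)
  sxx <- colSums(G * G) - n * gm^2
  sxy <- as.vector(crossprod(G, yc))
  beta <- sxy / sxx
  sse <- sum(yc^2) - beta^2 * sxx
  se <- sqrt(pmax(sse, 0) / (n - 2) / sxx)
  list(beta = beta, se = se, eaf = gm / 2)
}

# vectorised per-SNP logistic regression (intercept + dosage). Dosages take
# only the values 0/1/2, so the per-SNP likelihood depends on the data only
# through the 2x3 table (carriers and cases per dosage level); Newton
# iterations on those sufficient statistics give the exact MLE for every
# SNP simultaneously at negligible cost.
logistic_scan <- function(G, y, max_iter = 50, tol = 1e-12) {
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop("degenerate binary outcome: no variation in case status",
         call. = FALSE)
  }
  p <- ncol(G)
  n_g <- matrix(0, 3, p)   # carriers per dosage level
  k_g <- matrix(0, 3, p)   # cases per dosage level
  for (g in 0:2) {
    m <- G == g
    n_g[g + 1, ] <- colSums(m)
    k_g[g + 1, ] <- as.vector(crossprod(y, m))
  }
  x <- c(0, 1, 2)
  b0 <- rep(stats::qlogis(mean(y)), p)
  b1 <- rep(0, p)
  for (it in seq_len(max_iter)) {
    s0 <- s1 <- s2 <- u0 <- u1 <- 0
    for (g in 1:3) {
      mu <- stats::plogis(b0 + b1 * x[g])
      w <- n_g[g, ] * mu * (1 - mu)
      r <- k_g[g, ] - n_g[g, ] * mu
      s0 <- s0 + w
      s1 <- s1 + w * x[g]
      s2 <- s2 + w * x[g]^2
      u0 <- u0 + r
      u1 <- u1 + r * x[g]
    }
    det <- s0 * s2 - s1^2
    d0 <- (s2 * u0 - s1 * u1) / det
    d1 <- (s0 * u1 - s1 * u0) / det
    b0 <- b0 + d0
    b1 <- b1 + d1
    if (max(abs(d0), abs(d1)) < tol) break
  }
  s0 <- s1 <- s2 <- 0
  for (g in 1:3) {
    mu <- stats::plogis(b0 + b1 * x[g])
    w <- n_g[g, ] * mu * (1 - mu)
    s0 <- s0 + w
    s1 <- s1 + w * x[g]
    s2 <- s2 + w * x[g]^2
  }
  det <- s0 * s2 - s1^2
  list(beta = b1, se = sqrt(s0 / det), eaf = colMeans(G) / 2)
}

#' Per-SNP GWAS scan of a simulated cohort
#'
#' Simple linear regression (continuous traits) or logistic regression
#' (binary outcome) of the chosen phenotype on each SNP of the chosen
#' family member's genotype, exactly as a consortium scan would produce
#' marginal associations. The exposure phenotype used is the
#' treatment-adjusted measurement.
#'
#' @param cohort a [simulate_trio_cohort()] result.
#' @param trait `"exposure"` (maternal exposure) or `"outcome"`.
#' @param who genotype to scan against: `"maternal"`, `"fetal"` or
#'   `"paternal"`.
#' @param trait_name,unit metadata for the returned [sumstats()]; sensible
#'   defaults derived from the scan.
#' @return a [sumstats()] object.
#' @export
gwas_scan <- function(cohort, trait = c("exposure", "outcome"),
                      who = c("maternal", "fetal", "paternal"),
                      trait_name = NULL, unit = NULL) {
  stopifnot(inherits(cohort, "sim_cohort"))
  trait <- match.arg(trait)
  who <- match.arg(who)
  G <- switch(who, maternal = cohort$Gm, fetal = cohort$Gc,
              paternal = cohort$Gp)
  if (is.null(G)) stop("genotypes for '", who, "' were not generated",
                       call. = FALSE)
  binary <- trait == "outcome" && cohort$cfg$outcome_type == "binary" &&
    !cohort$cfg$reverse_causation
  y <- if (trait == "exposure") cohort$x_adjusted else cohort$y
  fit <- if (binary) logistic_scan(G, y) else linear_scan(G, y)
  n <- length(y)
  tr <- cohort$truth
  records <- data.frame(
    snp_id = tr$snp_id, chrom = tr$chrom, pos = tr$pos,
    effect_allele = tr$effect_allele, other_allele = tr$other_allele,
    eaf = fit$eaf, beta = fit$beta, se = fit$se,
    pval = 2 * stats::pnorm(-abs(fit$beta / fit$se)),
    n = n,
    n_case = if (binary) sum(y) else NA,
    stringsAsFactors = FALSE
  )
  if (is.null(unit)) {
    unit <- if (trait == "exposure") "mmHg" else
      if (binary) "log-odds" else "SD"
  }
  if (is.null(trait_name)) {
    trait_name <- paste0("simulated_", trait, "_", who)
  }
  sumstats(records, trait = trait_name, unit = unit,
           ancestry = "simulated", validate = FALSE)
}

#' Generate a complete two-sample MR scenario
#'
#' Draws one genetic architecture, simulates an exposure sample and an
#' outcome sample sharing `overlap_frac` of their individuals, scans them,
#' and returns everything a two-sample MR analysis consumes: the exposure
#' GWAS, maternal (and optionally fetal/paternal) outcome GWAS, exact LD
#' information computed from the exposure-sample genotypes, and the ground
#' truth.
#'
#' @param cfg a [sim_config()].
#' @param fetal,paternal also scan the outcome against child / father
#'   genotypes?
#' @param exact_ld compute the pairwise r-squared matrix from the generated
#'   genotypes (`TRUE`; `FALSE` returns the identity, appropriate for
#'   independent SNPs, and saves time in large replication loops)?
#' @return list of class `sim_scenario` with elements `exposure`,
#'   `outcome_maternal`, `outcome_fetal`, `outcome_paternal` (the last two
#'   `NULL` unless requested), `ld`, `truth`, `cfg`.
#' @export
make_two_sample_scenario <- function(cfg, fetal = FALSE, paternal = FALSE,
                                     exact_ld = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- local_seed(cfg$seed)
  on.exit(restore_seed(old))

  truth <- draw_truth(cfg)
  n_shared <- round(cfg$overlap_frac * min(cfg$n_exposure, cfg$n_outcome))
  n_pool <- cfg$n_exposure + cfg$n_outcome - n_shared
  cohort <- simulate_trio_cohort(cfg, truth = truth, n = n_pool,
                                 fetal = fetal, paternal = paternal,
                                 use_seed = FALSE)
  idx_exp <- seq_len(cfg$n_exposure)
  idx_out <- (n_pool - cfg$n_outcome + 1):n_pool

  slice <- function(idx) {
    structure(list(Gm = cohort$Gm[idx, , drop = FALSE],
                   Gp = if (is.null(cohort$Gp)) NULL else
                     cohort$Gp[idx, , drop = FALSE],
                   Gc = if (is.null(cohort$Gc)) NULL else
                     cohort$Gc[idx, , drop = FALSE],
                   x_true = cohort$x_true[idx],
                   x_measured = cohort$x_measured[idx],
                   treated = cohort$treated[idx],
                   x_adjusted = cohort$x_adjusted[idx],
                   y = cohort$y[idx],
                   truth = truth, cfg = cfg),
              class = "sim_cohort")
  }
  exp_cohort <- slice(idx_exp)
  out_cohort <- slice(idx_out)

  exposure <- gwas_scan(exp_cohort, "exposure", "maternal",
                        trait_name = "simulated_exposure", unit = "mmHg")
  outcome_maternal <- gwas_scan(out_cohort, "outcome", "maternal",
                                trait_name = "simulated_outcome")
  outcome_fetal <- if (fetal) {
    gwas_scan(out_cohort, "outcome", "fetal",
              trait_name = "simulated_outcome_fetal")
  } else NULL
  outcome_paternal <- if (paternal) {
    gwas_scan(out_cohort, "outcome", "paternal",
              trait_name = "simulated_outcome_paternal")
  } else NULL

  ld <- if (exact_ld) {
    r2 <- stats::cor(exp_cohort$Gm)^2
    r2[is.na(r2)] <- 0
    diag(r2) <- 1
    r2 <- (r2 + t(r2)) / 2
    ld_info(truth$snp_id, r2)
  } else {
    ld_info(truth$snp_id, diag(length(truth$snp_id)))
  }

  structure(list(exposure = exposure,
                 outcome_maternal = outcome_maternal,
                 outcome_fetal = outcome_fetal,
                 outcome_paternal = outcome_paternal,
                 ld = ld, truth = truth, cfg = cfg,
                 exposure_cohort = exp_cohort,
                 outcome_cohort = out_cohort),
            class = "sim_scenario")
}

#' Write a simulated scenario to an output directory
#'
#' Emits exposure/outcome (and fetal/paternal when present) summary
#' statistics TSVs, a long-format LD table, and a ground-truth TSV.
#'
#' @param scenario a [make_two_sample_scenario()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sumstats(scenario$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(scenario$outcome_maternal, file.path(dir, "outcome_maternal.tsv"))
  if (!is.null(scenario$outcome_fetal)) {
    write_sumstats(scenario$outcome_fetal, file.path(dir, "outcome_fetal.tsv"))
  }
  if (!is.null(scenario$outcome_paternal)) {
    write_sumstats(scenario$outcome_paternal,
                   file.path(dir, "outcome_paternal.tsv"))
  }
  r2 <- scenario$ld$r2
  ids <- scenario$ld$snp_ids
  ut <- which(upper.tri(r2), arr.ind = TRUE)
  ld_long <- data.frame(snp_a = ids[ut[, 1]], snp_b = ids[ut[, 2]],
                        r2 = r2[ut])
  utils::write.table(ld_long, file.path(dir, "ld.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- scenario$truth
  utils::write.table(
    data.frame(snp_id = tr$snp_id, chrom = tr$chrom, pos = tr$pos,
               effect_allele = tr$effect_allele,
               other_allele = tr$other_allele, maf = tr$maf,
               alpha = tr$alpha, gamma = tr$gamma, delta = tr$delta,
               theta = tr$theta),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
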