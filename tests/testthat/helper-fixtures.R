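# Small deterministic fixtures built in code.

# quick sumstats builder with sensible defaults
make_ss <- function(snp_id, beta, se,
                    effect_allele = rep("A", length(snp_id)),
                    other_allele = rep("G", length(snp_id)),
                    eaf = rep(0.3, length(snp_id)),
                    pval = 2 * pnorm(-abs(beta / se)),
                    chrom = rep(1, length(snp_id)),
                    pos = seq_along(snp_id) * 1e6,
                    n = rep(10000, length(snp_id)),
                    n_case = rep(NA, length(snp_id)),
                    trait = "trait", unit = "SD", validate = FALSE) {
  sumstats(data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                      effect_allele = effect_allele,
                      other_allele = other_allele,
                      eaf = eaf, beta = beta, se = se, pval = pval,
                      n = n, n_case = n_case,
                      stringsAsFactors = FALSE),
           trait = trait, unit = unit, validate = validate)
}

# harmonised-pair-shaped data frame for direct estimator input
make_h <- function(bx, by, sx = rep(0.05, length(bx)),
                   sy = rep(0.05, length(bx)),
                   nx = rep(20000, length(bx)),
                   ny = rep(20000, length(bx))) {
  data.frame(snp_id = sprintf("s%03d", seq_along(bx)),
             bx = bx, sx = sx, by = by, sy = sy,
             nx = nx, ny = ny)
}

# summary-level two-sample draw: per-SNP effects from their sampling
# distributions around a fixed architecture; much faster than cohort
# simulation and exact for estimator operating characteristics
draw_summary_mr <- function(alpha, theta_per_unit, gamma = 0, sx, sy) {
  p <- length(alpha)
  bx <- rnorm(p, alpha, sx)
  by <- rnorm(p, theta_per_unit * alpha + gamma, sy)
  make_h(bx, by, sx = rep(sx, p), sy = rep(sy, p))
}
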