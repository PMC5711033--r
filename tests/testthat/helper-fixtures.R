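# Shared helpers for building small in-memory fixtures.

# One-row association records for Wald ratio / harmonisation tests.
assoc_row <- function(beta, se, n = 1000, snp = "rs1", trait = "t",
                      allele = "A") {
  pval <- 2 * stats::pt(-abs(beta / se), df = n - 2)
  summary_assoc(snp = snp, trait = trait, beta = beta, se = se,
                pval = pval, n = n, effect_allele = allele)
}

# Draw a causal-model dataset with defaults used across tests.
draw_causal <- function(n, var_xy = 0.4, sigma2_mx = 0, sigma2_my = 0,
                        var_gx = 0.1) {
  simulate_causal(sim_config(n = n, var_gx = var_gx, var_xy = var_xy,
                             sigma2_mx = sigma2_mx, sigma2_my = sigma2_my))
}

# Independent implementation of the one-sample Steiger Z used as an oracle:
# pooled-covariance (Dunn-Clark style) form of the test for two correlations
# sharing a variable, algebraically distinct from the f/h parameterisation.
oracle_steiger_z <- function(r_gx, r_gy, r_xy, n) {
  rm2 <- (r_gx^2 + r_gy^2) / 2
  psi <- r_xy * (1 - 2 * rm2) - 0.5 * rm2 * (1 - 2 * rm2 - r_xy^2)
  s <- psi / (1 - rm2)^2
  (atanh(r_gx) - atanh(r_gy)) * sqrt((n - 3) / (2 - 2 * s))
}
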