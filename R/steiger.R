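#' Fisher's z-transformation
#'
#' `fisher_z(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilising
#' transform that places correlation coefficients on an approximately normal
#' scale with standard error `1 / sqrt(N - 3)`.
#'
#' @param r Correlation(s), each with `|r| < 1`.
#' @return Transformed value(s).
#' @export
#' @examples
#' fisher_z(0.5) # = 0.5 * log(3)
fisher_z <- function(r) {
  if (any(!is.finite(r) | abs(r) >= 1)) {
    stop("fisher_z requires |r| < 1", call. = FALSE)
  }
  0.5 * log((1 + r) / (1 - r))
}

new_steiger_result <- function(z, r_gx, r_gy, mode) {
  p <- 2 * stats::pnorm(-abs(z))
  direction <- if (z > 0) "x_causes_y" else if (z < 0) "y_causes_x" else "undetermined"
  structure(
    list(z_stat = z, p_steiger = p, direction = direction,
         r_gx = r_gx, r_gy = r_gy, mode = mode),
    class = "steiger_result"
  )
}

#' @export
print.steiger_result <- function(x, ...) {
  cat("MR Steiger directionality test (", x$mode, ")\n", sep = "")
  cat(sprintf("  |r_gx| = %.4f   |r_gy| = %.4f\n", x$r_gx, x$r_gy))
  cat(sprintf("  Z = %.4f   p = %.4g\n", x$z_stat, x$p_steiger))
  cat("  inferred direction:", x$direction, "\n")
  invisible(x)
}

#' Steiger's Z-test for two correlations sharing a variable (one sample)
#'
#' Tests whether the instrument g is more strongly correlated with the
#' measured exposure than with the measured outcome, when all three variables
#' are observed on the same individuals. The statistic is
#' \deqn{Z = (Z_{gx} - Z_{gy}) \sqrt{\frac{N - 3}{2 (1 - \rho_{xy}) h}}}
#' with \eqn{Z_{g\cdot}} the Fisher-transformed correlations,
#' \eqn{r_m^2 = (\rho_{gx}^2 + \rho_{gy}^2)/2},
#' \eqn{f = (1 - \rho_{xy}) / (2 (1 - r_m^2))} and
#' \eqn{h = (1 - f r_m^2) / (1 - r_m^2)}.
#'
#' The two instrument-trait correlations enter as absolute values: the test
#' asks which trait has the larger magnitude of correlation with g, so `Z > 0`
#' indicates the instrument acts most proximally on x (direction x -> y) and
#' `Z < 0` the reverse. The trait-trait correlation `r_xy` enters signed. The
#' p-value is two-sided from the standard normal.
#'
#' @param obs An [observed_correlations()] object in one-sample mode.
#' @return A `steiger_result` with elements `z_stat`, `p_steiger`,
#'   `direction`, `r_gx`, `r_gy`, `mode`.
#' @export
steiger_one_sample <- function(obs) {
  stopifnot(inherits(obs, "observed_correlations"))
  if (obs$mode != "one_sample") {
    stop("steiger_one_sample needs one-sample correlations", call. = FALSE)
  }
  if (is.null(obs$r_xy)) stop("one-sample test needs r_xy", call. = FALSE)
  if (abs(obs$r_xy) >= 1) {
    stop("degenerate input: |r_xy| = 1 leaves h undefined", call. = FALSE)
  }
  if (obs$n < 4) stop("need N >= 4", call. = FALSE)
  ra <- abs(obs$r_gx)
  rb <- abs(obs$r_gy)
  rxy <- obs$r_xy
  rm2 <- (ra^2 + rb^2) / 2
  f <- (1 - rxy) / (2 * (1 - rm2))
  h <- (1 - f * rm2) / (1 - rm2)
  scale2 <- 2 * (1 - rxy) * h
  if (!is.finite(scale2) || scale2 <= 0) {
    stop("correlations are not jointly consistent ",
         "(no positive-definite correlation matrix has these entries)",
         call. = FALSE)
  }
  z <- (fisher_z(ra) - fisher_z(rb)) * sqrt((obs$n - 3) / scale2)
  new_steiger_result(z, ra, rb, "one_sample")
}

#' Steiger test for two independent correlations (two samples)
#'
#' Two-sample variant for the setting where the instrument-exposure and
#' instrument-outcome correlations are estimated in independent cohorts
#' (e.g. from two GWAS summary tables), possibly of different sizes:
#' \deqn{Z = \frac{Z_{gx} - Z_{gy}}{\sqrt{1/(N_1 - 3) + 1/(N_2 - 3)}}}
#' No trait-trait correlation is needed. Sign and p-value conventions as in
#' [steiger_one_sample()].
#'
#' @param obs An [observed_correlations()] object in two-sample mode.
#' @return A `steiger_result`.
#' @export
steiger_two_sample <- function(obs) {
  stopifnot(inherits(obs, "observed_correlations"))
  if (obs$mode != "two_sample") {
    stop("steiger_two_sample needs two-sample correlations", call. = FALSE)
  }
  if (obs$n1 <= 3 || obs$n2 <= 3) {
    stop("need N1 > 3 and N2 > 3", call. = FALSE)
  }
  ra <- abs(obs$r_gx)
  rb <- abs(obs$r_gy)
  z <- (fisher_z(ra) - fisher_z(rb)) /
    sqrt(1 / (obs$n1 - 3) + 1 / (obs$n2 - 3))
  new_steiger_result(z, ra, rb, "two_sample")
}

#' Combine per-instrument correlations into a single correlation magnitude
#'
#' With several independent instruments the variance they jointly explain is
#' the sum of the per-SNP r-squared values, so the combined correlation is
#' `sqrt(sum(r^2))`. Correlated instruments are out of scope.
#'
#' @param r_values Per-SNP correlation magnitudes, each `|r| <= 1`.
#' @return Combined correlation magnitude.
#' @export
#' @examples
#' aggregate_instruments(c(0.3, 0.4)) # 0.5
aggregate_instruments <- function(r_values) {
  if (any(!is.finite(r_values) | abs(r_values) > 1)) {
    stop("each |r| must be <= 1", call. = FALSE)
  }
  total <- sum(r_values^2)
  if (total > 1) {
    stop("sum of r^2 exceeds 1: independent instruments cannot jointly ",
         "explain more than 100% of variance", call. = FALSE)
  }
  sqrt(total)
}

#' Combined MR + Steiger causal-direction decision
#'
#' Applies the three-branch rule: a directional causal call requires both the
#' MR causal test and the Steiger direction test to be significant at `alpha`,
#' with the direction taken from the sign of the Steiger Z;
#' otherwise no model is accepted.
#'
#' @param p_mr P-value of the MR causal test (Wald ratio or 2SLS).
#' @param steiger A `steiger_result`.
#' @param alpha Significance threshold in (0, 1). The default 0.05 is a
#'   compilation convenience for simulation summaries; real analyses should
#'   not hinge on a fixed threshold.
#' @return A `direction_call` with elements `outcome` (one of `"x_causes_y"`,
#'   `"y_causes_x"`, `"no_call"`), `p_mr`, `steiger`, `alpha`.
#' @export
infer_direction <- function(p_mr, steiger, alpha = 0.05) {
  stopifnot(inherits(steiger, "steiger_result"))
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  outcome <- if (steiger$p_steiger < alpha && p_mr < alpha &&
                 steiger$z_stat > 0) {
    "x_causes_y"
  } else if (steiger$p_steiger < alpha && p_mr < alpha &&
             steiger$z_stat < 0) {
    "y_causes_x"
  } else {
    "no_call"
  }
  structure(
    list(outcome = outcome, p_mr = p_mr, steiger = steiger, alpha = alpha),
    class = "direction_call"
  )
}

#' @export
print.direction_call <- function(x, ...) {
  cat("MR Steiger direction call (alpha =", x$alpha, ")\n")
  cat(sprintf("  p_MR = %.4g   p_Steiger = %.4g   Z = %.3f\n",
              x$p_mr, x$steiger$p_steiger, x$steiger$z_stat))
  cat("  outcome:", x$outcome, "\n")
  invisible(x)
}

#' Two-sample MR Steiger analysis from summary statistics
#'
#' Convenience pipeline for the summary-data setting: harmonises effect
#' alleles, recovers the instrument-trait correlation magnitudes from p-values
#' and sample sizes, runs the two-sample Steiger test, estimates the causal
#' effect by Wald ratio in the inferred orientation, and applies the combined
#' decision rule.
#'
#' @param exposure,outcome Single-row [summary_assoc()] records sharing a SNP.
#' @param alpha Significance threshold for the decision rule.
#' @return A `direction_call` with an added `mr` element (the Wald-ratio
#'   [mr_result][wald_ratio()] in the inferred orientation; oriented x -> y
#'   when the direction is undetermined).
#' @export
steiger_from_summary <- function(exposure, outcome, alpha = 0.05) {
  h <- harmonise_effects(exposure, outcome)
  obs <- observed_correlations(
    r_gx = r_from_pn(h$exposure$pval, h$exposure$n),
    r_gy = r_from_pn(h$outcome$pval, h$outcome$n),
    n1 = h$exposure$n, n2 = h$outcome$n
  )
  st <- steiger_two_sample(obs)
  mr <- if (st$z_stat < 0) {
    wald_ratio(h$outcome, h$exposure)
  } else {
    wald_ratio(h$exposure, h$outcome)
  }
  call <- infer_direction(mr$p_mr, st, alpha = alpha)
  call$mr <- mr
  call
}
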