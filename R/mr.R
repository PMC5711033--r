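#' Wald ratio causal effect estimate from summary statistics
#'
#' The causal effect of the exposure on the outcome instrumented by a shared
#' SNP is `beta_outcome / beta_exposure`; the standard error is first-order
#' delta method, `se_outcome / |beta_exposure|`, and the p-value comes from
#' the normal approximation (summary-data convention; samples are large in
#' intended use).
#'
#' @param exposure,outcome Single-row [summary_assoc()] records for the same
#'   SNP, alleles already harmonised (see [harmonise_effects()]).
#' @return An `mr_result` with `beta_mr`, `se_mr`, `p_mr`, `method`,
#'   `direction_tested`.
#' @export
wald_ratio <- function(exposure, outcome) {
  if (exposure$snp != outcome$snp) {
    stop("exposure and outcome records must share a SNP", call. = FALSE)
  }
  if (is.na(exposure$beta) || is.na(outcome$beta)) {
    stop("wald_ratio needs effect sizes for both records", call. = FALSE)
  }
  if (exposure$beta == 0) {
    stop("degenerate instrument: exposure effect is zero", call. = FALSE)
  }
  b <- outcome$beta / exposure$beta
  se <- outcome$se / abs(exposure$beta)
  p <- 2 * stats::pnorm(-abs(b / se))
  structure(
    list(beta_mr = b, se_mr = se, p_mr = p, method = "wald_ratio",
         direction_tested = paste(exposure$trait, "->", outcome$trait)),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat("MR causal estimate (", x$method, "), ", x$direction_tested, "\n",
      sep = "")
  cat(sprintf("  beta = %.4f  se = %.4f  p = %.4g\n",
              x$beta_mr, x$se_mr, x$p_mr))
  invisible(x)
}

#' Two-stage least squares with a single instrument
#'
#' Stage 1 regresses the exposure on the genotype; stage 2 regresses the
#' outcome on the fitted exposure. With one instrument the point estimate is
#' the just-identified IV estimator `cov(g, y) / cov(g, x)`, identical to the
#' Wald ratio of the two marginal regression slopes. The standard error uses
#' the IV form with residuals taken against the *observed* exposure
#' (`y - beta * x`), which is what makes the estimator consistent under
#' exposure measurement error.
#'
#' @param g Genotype vector (0/1/2).
#' @param x Exposure measurements.
#' @param y Outcome measurements.
#' @return An `mr_result` with `method = "tsls"` and an added `beta_stage1`
#'   element (the first-stage slope, reported as an instrument-strength
#'   diagnostic).
#' @export
tsls <- function(g, x, y) {
  n <- length(g)
  if (length(x) != n || length(y) != n) {
    stop("g, x and y must have equal length", call. = FALSE)
  }
  gc <- g - mean(g)
  sgx <- sum(gc * x)
  sgg <- sum(gc * gc)
  if (sgg == 0 || sgx == 0) {
    stop("degenerate instrument: zero first-stage slope", call. = FALSE)
  }
  b <- sum(gc * y) / sgx
  resid <- (y - mean(y)) - b * (x - mean(x))
  sigma2 <- sum(resid^2) / (n - 2)
  se <- sqrt(sigma2 * sgg) / abs(sgx)
  p <- 2 * stats::pnorm(-abs(b / se))
  out <- structure(
    list(beta_mr = b, se_mr = se, p_mr = p, method = "tsls",
         direction_tested = "x -> y", beta_stage1 = sgx / sgg),
    class = "mr_result"
  )
  out
}

#' MR p-values for both orientations of the same instrumented pair
#'
#' With a single shared instrument, the MR causal test p-value is (near)
#' identical whether the SNP instruments x on y or, erroneously, y on x:
#' both reduce to a test of the instrument-outcome association scaled by the
#' instrument-exposure association. This helper computes both so the
#' near-equality can be checked, and underpins the design choice that the
#' orientation in which `p_MR` is computed cannot flip a direction call.
#'
#' @inheritParams tsls
#' @return Named numeric vector with elements `forward` (x -> y) and
#'   `reverse` (y -> x).
#' @export
mr_pvalue_symmetry_check <- function(g, x, y) {
  c(forward = tsls(g, x, y)$p_mr, reverse = tsls(g, y, x)$p_mr)
}
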