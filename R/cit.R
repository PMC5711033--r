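# Causal inference test (CIT): mediation-based comparator.
#
# The omnibus p-value is the largest of four component p-values, the
# intuition being that the causal chain is only as strong as its weakest
# link. Conditions 1-3 are ordinary F-tests of a focal covariate in a linear
# regression; condition 4 is an equivalence test of conditional independence
# estimated by simulation. Equivalence with the reference implementation is
# behavioural (calibration, power and direction patterns), not numerical.

# p-value of the focal covariate in lm(response ~ covariates), via the
# single-df F-test (equal to the squared t). Degenerate fits (collinear
# covariates, zero residual variance) are rejected.
focal_pvalue <- function(response, focal, conditioning = NULL) {
  X <- if (is.null(conditioning)) {
    stats::model.matrix(~focal)
  } else {
    stats::model.matrix(~ conditioning + focal)
  }
  fit <- stats::lm.fit(X, response)
  if (any(is.na(fit$coefficients))) {
    stop("degenerate input: collinear covariates in CIT regression",
         call. = FALSE)
  }
  rss <- sum(fit$residuals^2)
  if (rss < 1e-10 * sum((response - mean(response))^2) || fit$df.residual < 1) {
    stop("degenerate input: zero residual variance in CIT regression",
         call. = FALSE)
  }
  # drop focal column, compare residual sums of squares
  fit0 <- stats::lm.fit(X[, -ncol(X), drop = FALSE], response)
  rss0 <- sum(fit0$residuals^2)
  fstat <- (rss0 - rss) / (rss / fit$df.residual)
  stats::pf(fstat, 1, fit$df.residual, lower.tail = FALSE)
}

#' CIT conditions 1-3
#'
#' The three regression-based conditions of the causal inference test, for
#' the orientation in which `exposure` is hypothesised to mediate the effect
#' of the SNP on `outcome`:
#' 1. the SNP associates with the outcome (`outcome ~ g`);
#' 2. the SNP associates with the exposure conditional on the outcome
#'    (`exposure ~ outcome + g`);
#' 3. the exposure associates with the outcome conditional on the SNP
#'    (`outcome ~ g + exposure`).
#' Each p-value is the F-test of the focal covariate.
#'
#' @param g Genotype vector.
#' @param exposure,outcome Numeric trait vectors.
#' @return Named numeric vector `c(p1, p2, p3)`.
#' @export
cit_conditions_1to3 <- function(g, exposure, outcome) {
  n <- length(g)
  if (length(exposure) != n || length(outcome) != n) {
    stop("g, exposure and outcome must have equal length", call. = FALSE)
  }
  for (v in list(g, exposure, outcome)) {
    if (stats::var(v) == 0) {
      stop("degenerate input: a variable has zero variance", call. = FALSE)
    }
  }
  c(
    p1 = focal_pvalue(outcome, g),
    p2 = focal_pvalue(exposure, g, conditioning = outcome),
    p3 = focal_pvalue(outcome, exposure, conditioning = g)
  )
}

# F statistic of g in lm(y ~ x + g) from the partial correlation of y and g
# given x; algebraically identical to the regression F, O(n) per evaluation.
partial_f <- function(r_yg, r_yx, r_gx, n) {
  denom <- (1 - r_yx^2) * (1 - r_gx^2)
  rp <- (r_yg - r_yx * r_gx) / sqrt(denom)
  rp2 <- pmin(rp^2, 1 - 1e-12)
  (n - 3) * rp2 / (1 - rp2)
}

#' CIT condition 4: conditional-independence equivalence test
#'
#' Tests whether the SNP is independent of the outcome given the exposure,
#' i.e. whether `cov(g, y - y_hat) = 0` where `y_hat` is the fitted value of
#' the outcome on the exposure. Full mediation forces this covariance to
#' zero; measurement imprecision in the exposure leaves a residual
#' SNP-outcome association.
#'
#' Because the alternative of interest is "no residual association", this is
#' an equivalence test estimated by simulation: the observed F statistic for
#' g in `lm(outcome ~ exposure + g)` is compared against an empirical null in
#' which the exposure carries the same fitted genetic signal but fresh
#' (permuted) residual noise, so its residual association with the outcome is
#' broken while the SNP's non-mediated path is preserved. A noncentral F
#' distribution (numerator df 1, denominator df n - 3) is fitted to the
#' simulated statistics by the method of moments and the returned p-value is
#' its lower-tail probability at the observed F. It is therefore *small*
#' when the observed residual association is consistent with zero (full
#' mediation) and *large* when residual association persists, and remains
#' continuous below `1 / n_null` so that gradual loss of mediation evidence
#' is visible.
#'
#' @inheritParams cit_conditions_1to3
#' @param n_null Number of simulated null datasets (>= 100).
#' @param seed Optional integer seed for the permutation stream.
#' @return Equivalence p-value in (0, 1].
#' @export
cit_condition_4 <- function(g, exposure, outcome, n_null = 500, seed = NULL) {
  n <- length(g)
  if (length(exposure) != n || length(outcome) != n) {
    stop("g, exposure and outcome must have equal length", call. = FALSE)
  }
  if (n_null < 100) {
    stop("n_null must be at least 100", call. = FALSE)
  }
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  gc_ <- g - mean(g)
  yc <- outcome - mean(outcome)
  xc <- exposure - mean(exposure)
  sg <- sqrt(sum(gc_^2))
  sy <- sqrt(sum(yc^2))
  sx <- sqrt(sum(xc^2))
  if (sg == 0 || sy == 0 || sx == 0) {
    stop("degenerate input: a variable has zero variance", call. = FALSE)
  }
  r_yg <- sum(yc * gc_) / (sy * sg)
  r_yx <- sum(yc * xc) / (sy * sx)
  r_gx <- sum(gc_ * xc) / (sg * sx)
  f_obs <- partial_f(r_yg, r_yx, r_gx, n)

  # exposure* = fitted(exposure ~ g) + permuted residuals
  b1 <- sum(gc_ * xc) / sum(gc_^2)
  fitted_c <- b1 * gc_
  res <- xc - fitted_c
  sf2 <- sum(fitted_c^2)

  f_null <- numeric(n_null)
  chunk <- max(1L, floor(2e6 / n))
  done <- 0L
  while (done < n_null) {
    k <- min(chunk, n_null - done)
    E <- vapply(seq_len(k), function(i) res[sample.int(n)], numeric(n))
    cross <- crossprod(cbind(yc, gc_, fitted_c), E) # 3 x k sums
    sxstar <- sqrt(sf2 + sum(res^2) + 2 * cross[3, ])
    r_yxs <- (sum(yc * fitted_c) + cross[1, ]) / (sy * sxstar)
    r_gxs <- (sum(gc_ * fitted_c) + cross[2, ]) / (sg * sxstar)
    f_null[done + seq_len(k)] <- partial_f(r_yg, r_yxs, r_gxs, n)
    done <- done + k
  }
  # method-of-moments noncentral F fit: E[F] = df2 (1 + ncp) / (df2 - 2)
  df2 <- n - 3
  ncp_hat <- max(0, mean(f_null) * (df2 - 2) / df2 - 1)
  stats::pf(f_obs, 1, df2, ncp = ncp_hat)
}

#' CIT omnibus test for one orientation
#'
#' Runs the four CIT conditions with `exposure` as the hypothesised mediator
#' and returns the omnibus p-value, the largest (least extreme) of the four.
#'
#' @inheritParams cit_condition_4
#' @param orientation Label recording which trait was treated as exposure.
#' @return A `cit_result` with elements `p1`, `p2`, `p3`, `p4`, `p_omnibus`,
#'   `orientation`, `n_null`, `seed`.
#' @export
cit_omnibus <- function(g, exposure, outcome, n_null = 500, seed = NULL,
                        orientation = "x->y") {
  p123 <- cit_conditions_1to3(g, exposure, outcome)
  p4 <- cit_condition_4(g, exposure, outcome, n_null = n_null, seed = seed)
  structure(
    list(p1 = unname(p123[1]), p2 = unname(p123[2]), p3 = unname(p123[3]),
         p4 = p4, p_omnibus = max(p123, p4), orientation = orientation,
         n_null = n_null, seed = seed),
    class = "cit_result"
  )
}

#' @export
print.cit_result <- function(x, ...) {
  cat("CIT (", x$orientation, ")\n", sep = "")
  cat(sprintf("  p1 = %.3g  p2 = %.3g  p3 = %.3g  p4 = %.3g\n",
              x$p1, x$p2, x$p3, x$p4))
  cat(sprintf("  omnibus p_CIT = %.3g\n", x$p_omnibus))
  invisible(x)
}

#' Bidirectional CIT with the four-way outcome code
#'
#' Runs the omnibus CIT in both orientations and classifies the pair of
#' omnibus p-values at threshold `alpha`:
#' * forward < alpha, reverse > alpha: `model1_accepted` (x -> y);
#' * forward > alpha, reverse < alpha: `model2_accepted` (y -> x);
#' * both > alpha: `no_evidence`;
#' * both < alpha: `no_call_confounding` (potential confounding; no call).
#'
#' @inheritParams cit_condition_4
#' @param x,y The two trait vectors.
#' @param alpha Significance threshold.
#' @return A `cit_bidirectional_call` with `p_forward`, `p_reverse`,
#'   `outcome_code`, `alpha`, `forward`, `reverse`.
#' @export
cit_bidirectional <- function(g, x, y, alpha = 0.05, n_null = 500,
                              seed = NULL) {
  fw <- cit_omnibus(g, x, y, n_null = n_null, seed = seed,
                    orientation = "x->y")
  rv <- cit_omnibus(g, y, x, n_null = n_null,
                    seed = if (is.null(seed)) NULL else seed + 1L,
                    orientation = "y->x")
  pf_ <- fw$p_omnibus
  pr_ <- rv$p_omnibus
  code <- if (pf_ < alpha && pr_ >= alpha) {
    "model1_accepted"
  } else if (pf_ >= alpha && pr_ < alpha) {
    "model2_accepted"
  } else if (pf_ >= alpha && pr_ >= alpha) {
    "no_evidence"
  } else {
    "no_call_confounding"
  }
  structure(
    list(p_forward = pf_, p_reverse = pr_, outcome_code = code,
         alpha = alpha, forward = fw, reverse = rv),
    class = "cit_bidirectional_call"
  )
}

#' @export
print.cit_bidirectional_call <- function(x, ...) {
  cat("Bidirectional CIT (alpha =", x$alpha, ")\n")
  cat(sprintf("  p_CIT(x->y) = %.3g   p_CIT(y->x) = %.3g\n",
              x$p_forward, x$p_reverse))
  cat("  outcome:", x$outcome_code, "\n")
  invisible(x)
}
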