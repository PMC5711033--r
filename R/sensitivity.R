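# Measurement-error sensitivity analysis.
#
# Non-differential measurement error x_o = beta_mx * x + eps_mx attenuates
# every correlation involving x by the reliability correlation
# rho_x,xo = cor(x, x_o). The observed instrument-trait correlation therefore
# understates the true one: rho_g,x = rho_g,xo / rho_x,xo. Because the
# instrument explains rho_g,xo^2 of the *observed* trait, the reliability
# cannot be lower than rho_g,xo (otherwise the corrected correlation would
# exceed 1), which bounds the admissible measurement-error values.

#' Attenuation factor D
#'
#' Fraction of the observed exposure's variance attributable to the scaled
#' true exposure:
#' `D = beta_mx^2 var(x) / (beta_mx^2 var(x) + var(eps_mx))`.
#' `D = 1` iff the measurement carries no imprecision; pure scale
#' transformations (any `beta_mx`, zero noise) leave `D = 1`. `D` equals the
#' squared reliability correlation `cor(x, x_o)^2`.
#'
#' @param beta_mx Scale coefficient of the measurement model (non-zero).
#' @param var_x Variance of the true exposure (> 0).
#' @param var_eps_mx Variance of the measurement imprecision (>= 0).
#' @return Attenuation factor in (0, 1].
#' @export
attenuation_factor <- function(beta_mx, var_x, var_eps_mx) {
  if (any(var_x <= 0)) stop("var_x must be > 0", call. = FALSE)
  if (any(var_eps_mx < 0)) stop("var_eps_mx must be >= 0", call. = FALSE)
  if (any(beta_mx == 0)) stop("beta_mx must be non-zero", call. = FALSE)
  beta_mx^2 * var_x / (beta_mx^2 * var_x + var_eps_mx)
}

#' Residual SNP-outcome covariance under outcome/exposure measurement error
#'
#' The mediation condition cov(g, y - y_hat) = 0 fails under exposure
#' imprecision: with measurement models applied to both traits, the residual
#' covariance is `beta_my * beta_g * beta_x * var(g) * (1 - D)`, zero only
#' when `D = 1` (no exposure imprecision) or when any path coefficient is
#' zero. This is the analytic source of the mediation-based test's
#' wrong-direction behaviour.
#'
#' @param beta_g SNP-exposure effect.
#' @param beta_x Exposure-outcome causal effect.
#' @param beta_my Outcome measurement scale coefficient.
#' @param var_g Variance of the genotype (> 0).
#' @param D Attenuation factor of the exposure, see [attenuation_factor()].
#' @return The residual covariance cov(g, y_o - y_o_hat).
#' @export
residual_cov_bias <- function(beta_g, beta_x, beta_my, var_g, D) {
  if (any(var_g <= 0)) stop("var_g must be > 0", call. = FALSE)
  beta_my * beta_g * beta_x * var_g * (1 - D)
}

#' The d statistic delimiting Steiger-test reliability
#'
#' `d = rho_x,xo - rho_xy * rho_y,yo`. When `d > 0` the Steiger comparison of
#' observed correlations ranks the traits the same way as the true
#' correlations, so the direction call is expected to be correct; `d < 0`
#' marks the measurement-error regime in which the test is liable to infer
#' the wrong direction. With a perfectly measured exposure
#' (`rho_x,xo = 1`), `d >= 0` for all valid arguments.
#'
#' @param rho_xxo Reliability correlation of the exposure, in `[0, 1]`.
#' @param rho_xy True exposure-outcome correlation, in `[-1, 1]`.
#' @param rho_yyo Reliability correlation of the outcome, in `[0, 1]`.
#' @return The value of d.
#' @export
d_statistic <- function(rho_xxo, rho_xy, rho_yyo) {
  if (any(rho_xxo < 0 | rho_xxo > 1) || any(rho_yyo < 0 | rho_yyo > 1)) {
    stop("reliability correlations must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rho_xy) > 1)) {
    stop("rho_xy must lie in [-1, 1]", call. = FALSE)
  }
  rho_xxo - rho_xy * rho_yyo
}

#' Predicted Steiger surface at a hypothesised measurement-error point
#'
#' Given the observed instrument-trait correlations, predicts what the
#' Steiger comparison would be if the true reliability correlations were
#' `(rho_xxo, rho_yyo)`: each observed correlation is corrected for the
#' hypothesised attenuation (`true = observed / reliability`) and the
#' difference is returned. Positive values mean that amount of measurement
#' error would favour y -> x, i.e. overturn an inferred x -> y direction.
#'
#' The default `scale = "r2"` returns the difference of squared corrected
#' correlations (variance explained in each trait by the instrument), the
#' scale on which [reliability_ratio()] integrates its volumes; `scale = "r"`
#' returns the plain corrected correlation difference. The two have identical
#' sign structure.
#'
#' @param r_gx_obs,r_gy_obs Observed correlation magnitudes, each in (0, 1).
#' @param rho_xxo,rho_yyo Hypothesised reliability correlations (vectorised).
#' @param scale `"r2"` (default) or `"r"`.
#' @return Predicted difference (rho_gy - rho_gx on the chosen scale).
#' @export
predicted_surface <- function(r_gx_obs, r_gy_obs, rho_xxo, rho_yyo,
                              scale = c("r2", "r")) {
  scale <- match.arg(scale)
  check_observed_pair(r_gx_obs, r_gy_obs)
  if (any(rho_xxo < r_gx_obs) || any(rho_yyo < r_gy_obs)) {
    stop("reliability below its admissible lower bound (the observed ",
         "instrument correlation): corrected correlation would exceed 1",
         call. = FALSE)
  }
  if (any(rho_xxo > 1) || any(rho_yyo > 1)) {
    stop("reliability correlations cannot exceed 1", call. = FALSE)
  }
  cx <- r_gx_obs / rho_xxo
  cy <- r_gy_obs / rho_yyo
  if (scale == "r2") cy^2 - cx^2 else cy - cx
}

check_observed_pair <- function(r_gx_obs, r_gy_obs) {
  if (!is.finite(r_gx_obs) || r_gx_obs <= 0 || r_gx_obs >= 1 ||
      !is.finite(r_gy_obs) || r_gy_obs <= 0 || r_gy_obs >= 1) {
    stop("observed correlations must lie in (0, 1)", call. = FALSE)
  }
  invisible(NULL)
}

#' Reliability ratio R of an inferred causal direction
#'
#' Integrates the predicted Steiger surface over every admissible
#' measurement-error value, assuming each value equally likely, and returns
#' the ratio of the volume supporting the inferred direction to the volume
#' opposing it. The admissible region is the rectangle
#' `[r_gx_obs, 1] x [r_gy_obs, 1]` of reliability correlations (each bounded
#' below by the observed instrument correlation, since the instrument is
#' known to explain at least that much of the observed trait). The surface is
#' evaluated on a deterministic endpoint-inclusive uniform lattice of
#' `grid_resolution` points per axis, on the variance-explained scale (see
#' [predicted_surface()]), and the supporting and opposing volumes are the
#' sums of |surface| over the cells on each side of zero, with exact zeros
#' split half-and-half.
#'
#' `R = 1` flags maximal sensitivity (the measurement-error space supports
#' each direction equally); large `R` means the inferred direction holds for
#' most admissible measurement-error values. When no lattice point opposes
#' the inferred direction, `R` is `Inf` and `opposed_empty` is set.
#'
#' The default resolution of 500 is part of the reported convention: the
#' lattice includes the admissible boundary, where the corrected exposure
#' correlation reaches 1, so the reported `R` carries a small
#' resolution-dependent boundary contribution (about 3% at 500 steps for
#' weak instruments) relative to the continuum integral. Values of `R`
#' should therefore be compared at a common resolution.
#'
#' @param r_gx_obs,r_gy_obs Observed correlation magnitudes, each in (0, 1).
#' @param grid_resolution Lattice points per axis (default 500).
#' @param weight Optional weighting function `f(rho_xxo, rho_yyo)` over the
#'   admissible rectangle (vectorised, non-negative); default uniform.
#' @return A `sensitivity_result` with elements `R`, `vol_support`,
#'   `vol_oppose`, `direction`, `grid_resolution`, `opposed_empty`.
#' @export
#' @examples
#' # instrument explains 1% of the exposure; exposure explains 10% of the
#' # outcome, so under the causal chain r_gy = r_gx * sqrt(0.1)
#' reliability_ratio(sqrt(0.01), sqrt(0.01) * sqrt(0.1))
reliability_ratio <- function(r_gx_obs, r_gy_obs, grid_resolution = 500,
                              weight = NULL) {
  check_observed_pair(r_gx_obs, r_gy_obs)
  if (grid_resolution < 2) stop("grid_resolution must be >= 2", call. = FALSE)
  direction <- if (r_gx_obs >= r_gy_obs) "x_causes_y" else "y_causes_x"
  xs <- seq(r_gx_obs, 1, length.out = grid_resolution)
  ys <- seq(r_gy_obs, 1, length.out = grid_resolution)
  # z on the variance-explained scale; outer() keeps memory at res^2 doubles
  cx2 <- (r_gx_obs / xs)^2
  cy2 <- (r_gy_obs / ys)^2
  z <- outer(-cx2, cy2, "+") # z[i, j] = cy2[j] - cx2[i]
  w <- if (is.null(weight)) 1 else {
    wm <- outer(xs, ys, weight)
    if (any(wm < 0)) stop("weights must be non-negative", call. = FALSE)
    wm
  }
  cell <- (1 - r_gx_obs) * (1 - r_gy_obs) / grid_resolution^2
  vol_pos <- sum((z * w)[z > 0]) * cell   # favours y -> x
  vol_neg <- -sum((z * w)[z < 0]) * cell  # favours x -> y
  # exact zeros carry |z| = 0 and so contribute nothing to either volume
  if (direction == "x_causes_y") {
    vol_support <- vol_neg
    vol_oppose <- vol_pos
  } else {
    vol_support <- vol_pos
    vol_oppose <- vol_neg
  }
  opposed_empty <- vol_oppose == 0
  structure(
    list(R = if (opposed_empty) Inf else vol_support / vol_oppose,
         vol_support = vol_support, vol_oppose = vol_oppose,
         direction = direction, grid_resolution = grid_resolution,
         opposed_empty = opposed_empty),
    class = "sensitivity_result"
  )
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Measurement-error sensitivity of the inferred direction\n")
  cat("  inferred direction:", x$direction, "\n")
  cat(sprintf("  supporting volume = %.4g   opposing volume = %.4g\n",
              x$vol_support, x$vol_oppose))
  cat(sprintf("  reliability ratio R = %.3f (lattice %d x %d)\n",
              x$R, x$grid_resolution, x$grid_resolution))
  if (x$opposed_empty) {
    cat("  (no admissible measurement-error value opposes the direction)\n")
  }
  invisible(x)
}

#' Export the predicted sensitivity surface as a long-format table
#'
#' Evaluates [predicted_surface()] on the admissible lattice and returns a
#' data frame suitable for contour or surface plotting.
#'
#' @inheritParams reliability_ratio
#' @param grid_resolution Lattice points per axis.
#' @return Data frame with columns `rho_xxo`, `rho_yyo`, `z`.
#' @export
sensitivity_surface <- function(r_gx_obs, r_gy_obs, grid_resolution = 100) {
  check_observed_pair(r_gx_obs, r_gy_obs)
  xs <- seq(r_gx_obs, 1, length.out = grid_resolution)
  ys <- seq(r_gy_obs, 1, length.out = grid_resolution)
  grid <- expand.grid(rho_xxo = xs, rho_yyo = ys)
  grid$z <- predicted_surface(r_gx_obs, r_gy_obs, grid$rho_xxo, grid$rho_yyo)
  grid
}
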