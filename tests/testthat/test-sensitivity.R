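test_that("attenuation factor behaves as the variance fraction", {
  expect_equal(attenuation_factor(1, 1, 0), 1)
  expect_equal(attenuation_factor(5, 1, 0), 1)  # pure rescaling is harmless
  expect_equal(attenuation_factor(1, 1, 1), 0.5)
  expect_equal(attenuation_factor(2, 3, 6), 12 / 18)
  expect_error(attenuation_factor(1, 0, 1), "var_x")
  expect_error(attenuation_factor(0, 1, 1), "beta_mx")
  # equals the squared reliability correlation of the measurement model
  set.seed(101)
  x <- rnorm(2e5)
  x_o <- 1.5 * x + rnorm(2e5, 0, sqrt(0.5))
  expect_equal(cor(x, x_o)^2, attenuation_factor(1.5, 1, 0.5),
               tolerance = 0.01)
})

test_that("residual covariance bias vanishes iff D = 1 and tracks simulation", {
  expect_equal(residual_cov_bias(0.4, 0.7, 1, 0.5, 1), 0)
  expect_equal(residual_cov_bias(0.4, -0.7, 1, 0.5, 0.5),
               -residual_cov_bias(0.4, 0.7, 1, 0.5, 0.5))
  # simulation oracle: empirical cov(g, y_o - y_o_hat) across a grid of
  # (D, beta_x), within 3 Monte-Carlo standard errors
  set.seed(102)
  n <- 1e5
  for (D in c(0.4, 0.6, 0.9)) {
    for (var_xy in c(0.2, 0.5, 0.8)) {
      sigma2_mx <- (1 - D) / D   # unit-variance x, beta_mx = 1
      d <- simulate_causal(sim_config(n = n, var_gx = 0.2, var_xy = var_xy,
                                      sigma2_mx = sigma2_mx))
      res <- d$y_o - fitted(lm(d$y_o ~ d$x_o))
      emp <- cov(d$g, res)
      mc_se <- sd((d$g - mean(d$g)) * res) / sqrt(n)
      beta_g <- sqrt(0.2 / 0.5)
      ana <- residual_cov_bias(beta_g, sqrt(var_xy), 1, 0.5, D)
      expect_lt(abs(emp - ana), 3 * mc_se)
    }
  }
})

test_that("the d statistic delimits the fallible region", {
  expect_equal(d_statistic(0.5, 0.9, 1), -0.4)
  # no exposure error: d >= 0 over the whole valid domain of the other args
  grid <- expand.grid(rho_xy = seq(-1, 1, by = 0.05),
                      rho_yyo = seq(0, 1, by = 0.05))
  expect_true(all(d_statistic(1, grid$rho_xy, grid$rho_yyo) >= 0))
  # the d < 0 region shrinks as the causal correlation weakens
  rel <- expand.grid(x = seq(0, 1, by = 0.05), y = seq(0, 1, by = 0.05))
  neg_area <- sapply(c(0.9, 0.6, 0.3), function(rxy) {
    mean(d_statistic(rel$x, rxy, rel$y) < 0)
  })
  expect_true(all(diff(neg_area) < 0))
  expect_error(d_statistic(-0.1, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("the predicted surface corrects observed correlations", {
  # no measurement error: the surface is just the observed difference
  expect_equal(predicted_surface(0.3, 0.2, 1, 1), 0.2^2 - 0.3^2)
  expect_equal(predicted_surface(0.3, 0.2, 1, 1, scale = "r"), -0.1)
  # equal observed correlations at a symmetric point: zero
  expect_equal(predicted_surface(0.25, 0.25, 0.6, 0.6), 0)
  # at the admissible lower bound the corrected correlation reaches 1
  expect_equal(predicted_surface(0.3, 0.2, 0.3, 1), 0.2^2 - 1)
  expect_error(predicted_surface(0.3, 0.2, 0.2, 1), "lower bound")
  expect_error(predicted_surface(0.3, 1.2, 1, 1), "\\(0, 1\\)")
})

test_that("surface sign agrees with the Steiger test at the population level", {
  r_gx <- 0.35
  r_gy <- 0.15
  xs <- seq(r_gx + 0.02, 0.99, length.out = 20)
  ys <- seq(r_gy + 0.02, 0.99, length.out = 20)
  for (a in xs) {
    for (b in ys) {
      z <- predicted_surface(r_gx, r_gy, a, b)
      true_gx <- r_gx / a
      true_gy <- r_gy / b
      # r_xy chosen so the population correlation matrix is positive
      # definite for every grid point (chain-consistent value)
      st <- steiger_one_sample(observed_correlations(
        true_gx, true_gy, r_xy = true_gx * true_gy, n = 1000))
      expected <- if (z > 0) "y_causes_x" else if (z < 0) "x_causes_y"
                  else "undetermined"
      expect_identical(st$direction, expected)
    }
  }
})

test_that("reliability ratio integrates the surface over admissible errors", {
  # equal observed correlations: perfectly ambiguous
  expect_equal(reliability_ratio(0.2, 0.2)$R, 1, tolerance = 1e-10)
  rr <- reliability_ratio(0.3, 0.12)
  expect_identical(rr$direction, "x_causes_y")
  expect_gt(rr$R, 1)
  expect_equal(rr$R, rr$vol_support / rr$vol_oppose)
  # swapping the observed pair transposes the lattice: the volume ratio
  # referred to a fixed direction (x -> y) inverts exactly
  sw <- reliability_ratio(0.12, 0.3)
  expect_identical(sw$direction, "y_causes_x")
  expect_equal(rr$vol_support / rr$vol_oppose, sw$vol_support / sw$vol_oppose,
               tolerance = 1e-10)
  expect_equal((rr$vol_support / rr$vol_oppose) *
                 (sw$vol_oppose / sw$vol_support), 1, tolerance = 1e-10)
  # weighting hook: uniform weights reproduce the default
  rw <- reliability_ratio(0.3, 0.12, weight = function(x, y) rep(2, length(x)))
  expect_equal(rw$R, rr$R, tolerance = 1e-12)
})

test_that("lattice integration agrees with a Monte-Carlo oracle", {
  r_gx <- sqrt(0.01)
  r_gy <- r_gx * sqrt(0.1)
  fine <- reliability_ratio(r_gx, r_gy, grid_resolution = 4000)
  set.seed(103)
  nmc <- 2e6
  x <- runif(nmc, r_gx, 1)
  y <- runif(nmc, r_gy, 1)
  z <- (r_gy / y)^2 - (r_gx / x)^2
  mc <- sum(-z[z < 0]) / sum(z[z > 0])
  expect_equal(fine$R, mc, tolerance = 0.01)
})
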