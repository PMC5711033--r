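test_that("fisher_z is the odd closed-form transform", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  for (r in seq(0.1, 0.9, by = 0.1)) {
    expect_equal(fisher_z(-r), -fisher_z(r))
  }
  expect_error(fisher_z(1), "\\|r\\| < 1")
})

test_that("one-sample Steiger Z matches an independent formulation", {
  cases <- list(c(0.3162, 0.1, 0.3162, 1000),
                c(0.5, 0.2, 0.4, 200),
                c(0.7, 0.65, -0.3, 50))
  for (p in cases) {
    obs <- observed_correlations(p[1], p[2], r_xy = p[3], n = p[4])
    st <- steiger_one_sample(obs)
    expect_equal(st$z_stat, oracle_steiger_z(p[1], p[2], p[3], p[4]),
                 tolerance = 1e-12)
  }
  st <- steiger_one_sample(
    observed_correlations(0.3162, 0.1, r_xy = 0.3162, n = 1000))
  expect_gt(st$z_stat, 0)
  expect_identical(st$direction, "x_causes_y")
})

test_that("one-sample Steiger handles ties, sample-size scaling and degeneracy", {
  tie <- steiger_one_sample(observed_correlations(0.4, 0.4, r_xy = 0.2,
                                                  n = 500))
  expect_equal(tie$z_stat, 0)
  expect_equal(tie$p_steiger, 1)
  expect_identical(tie$direction, "undetermined")

  n <- 800
  z1 <- steiger_one_sample(
    observed_correlations(0.45, 0.2, r_xy = 0.3, n = n))$z_stat
  z2 <- steiger_one_sample(
    observed_correlations(0.45, 0.2, r_xy = 0.3, n = 2 * n))$z_stat
  expect_equal(z2 / z1, sqrt((2 * n - 3) / (n - 3)), tolerance = 1e-9)

  expect_error(
    steiger_one_sample(observed_correlations(0.4, 0.2, r_xy = 1, n = 100)),
    "r_xy")
})

test_that("one-sample Steiger p-value is calibrated under the null", {
  # trivariate normal with rho_gx = rho_gy: rejection rate should sit at the
  # nominal level (Monte-Carlo oracle independent of the Z formula)
  set.seed(73)
  S <- matrix(c(1, 0.3, 0.3,
                0.3, 1, 0.5,
                0.3, 0.5, 1), 3)
  rej <- replicate(1500, {
    m <- MASS::mvrnorm(150, rep(0, 3), S)
    st <- steiger_one_sample(correlations_from_individual(m[, 1], m[, 2],
                                                          m[, 3]))
    st$p_steiger < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("two-sample Steiger evaluates the independent-correlations formula", {
  obs <- observed_correlations(0.3, 0.1, n1 = 500, n2 = 500)
  st <- steiger_two_sample(obs)
  expect_equal(st$z_stat, (atanh(0.3) - atanh(0.1)) * sqrt(497 / 2),
               tolerance = 1e-9)
  expect_equal(steiger_two_sample(
    observed_correlations(0.2, 0.2, n1 = 100, n2 = 900))$z_stat, 0)
  # antisymmetry under swapping (r, N) pairs
  a <- steiger_two_sample(observed_correlations(0.35, 0.15, n1 = 300,
                                                n2 = 700))
  b <- steiger_two_sample(observed_correlations(0.15, 0.35, n1 = 700,
                                                n2 = 300))
  expect_equal(a$z_stat, -b$z_stat)
  expect_equal(a$p_steiger, b$p_steiger)
  expect_error(steiger_two_sample(observed_correlations(0.3, 0.1, n1 = 3,
                                                        n2 = 100)), "N1")
})

test_that("one- and two-sample Z agree up to the documented h factor", {
  # with r_xy = 0 and equal N the ratio of the two statistics is 1/sqrt(h)
  for (p in list(c(0.3, 0.1), c(0.5, 0.2), c(0.4, 0.35))) {
    rm2 <- (p[1]^2 + p[2]^2) / 2
    f <- 1 / (2 * (1 - rm2))
    h <- (1 - f * rm2) / (1 - rm2)
    z1 <- steiger_one_sample(observed_correlations(p[1], p[2], r_xy = 0,
                                                   n = 1000))$z_stat
    z2 <- steiger_two_sample(observed_correlations(p[1], p[2], n1 = 1000,
                                                   n2 = 1000))$z_stat
    expect_equal(z1 / z2, 1 / sqrt(h), tolerance = 1e-12)
  }
})

test_that("the Steiger p-value uses the absolute-correlation convention", {
  a <- steiger_one_sample(observed_correlations(0.4, 0.2, r_xy = 0.3,
                                                n = 400))
  b <- steiger_one_sample(observed_correlations(-0.4, -0.2, r_xy = 0.3,
                                                n = 400))
  expect_equal(a$p_steiger, b$p_steiger)
  expect_equal(a$z_stat, b$z_stat)
})

test_that("independent instruments aggregate on the variance scale", {
  expect_equal(aggregate_instruments(0.42), 0.42)
  expect_equal(aggregate_instruments(c(0.3, 0.4)), 0.5)
  expect_equal(aggregate_instruments(rep(0.1, 10)), sqrt(0.1))
  expect_error(aggregate_instruments(c(0.9, 0.9)), "exceeds 1")
})

test_that("the combined decision rule needs both tests significant", {
  st_pos <- steiger_one_sample(observed_correlations(0.4, 0.1, r_xy = 0.2,
                                                     n = 1000))
  st_neg <- steiger_one_sample(observed_correlations(0.1, 0.4, r_xy = 0.2,
                                                     n = 1000))
  expect_identical(infer_direction(0.001, st_pos, 0.05)$outcome, "x_causes_y")
  expect_identical(infer_direction(0.001, st_neg, 0.05)$outcome, "y_causes_x")
  expect_identical(infer_direction(0.5, st_pos, 0.05)$outcome, "no_call")
  weak <- steiger_one_sample(observed_correlations(0.21, 0.2, r_xy = 0.2,
                                                   n = 50))
  expect_identical(infer_direction(0.001, weak, 0.05)$outcome, "no_call")
  expect_error(infer_direction(0.01, st_pos, alpha = 1), "alpha")
})

test_that("direction calls converge to the true direction under the causal model", {
  set.seed(74)
  calls <- replicate(200, {
    d <- draw_causal(1e4)
    st <- steiger_one_sample(correlations_from_individual(d$g, d$x_o, d$y_o))
    infer_direction(tsls(d$g, d$x_o, d$y_o)$p_mr, st)$outcome
  })
  made <- calls[calls != "no_call"]
  expect_gte(mean(made == "x_causes_y"), 0.99)
})
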