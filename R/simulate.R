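# Generative models for the method-comparison experiments, and the fixture
# generator for the summary-statistic pipeline.
#
# Causal model:   g ~ Binom(2, maf);  x = beta_g g + eps_g;  y = beta_x x + eps_x
# Measurement:    x_o = alpha_mx + beta_mx x + eps_mx,  eps_mx ~ N(0, sigma2_mx)
#                 (same for y_o)
# Non-causal:     x and y each depend on g through separate paths and are not
#                 causally related: cor(x, y | g) = 0.
#
# Effect sizes are solved in closed form so that population cor(g,x)^2 and
# cor(x,y)^2 hit their targets with unit-variance true traits; sigma2_m*
# values are then directly interpretable as imprecision relative to unit
# trait variance (sigma2 = 1 gives reliability cor(x, x_o)^2 = 0.5).

#' Simulation configuration
#'
#' @param n Sample size (>= 4).
#' @param var_gx Target population cor(g, x)^2, in `[0, 1)`.
#' @param var_xy Target population cor(x, y)^2 under the causal model, in
#'   `[0, 1)`; under the non-causal model it sets the instrument-outcome
#'   variance explained, cor(g, y)^2 = `var_gx * var_xy`, mirroring the
#'   causal chain.
#' @param sigma2_mx,sigma2_my Measurement imprecision variances (>= 0).
#' @param alpha_mx,beta_mx,alpha_my,beta_my Scale-error intercepts and slopes
#'   of the measurement model (defaults 0 and 1: identity scale).
#' @param model `"causal"` or `"noncausal"`.
#' @param maf Allele frequency of the instrument, in (0, 1).
#' @param latent_u Non-causal model only: if `TRUE`, realise the confounder
#'   as an explicit latent variable u (g -> u -> x, g -> u -> y) rather than
#'   the minimal g -> x, g -> y structure.
#' @param seed Optional integer seed applied when the dataset is drawn.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n, var_gx = 0.1, var_xy = 0.2,
                       sigma2_mx = 0, sigma2_my = 0,
                       alpha_mx = 0, beta_mx = 1,
                       alpha_my = 0, beta_my = 1,
                       model = c("causal", "noncausal"),
                       maf = 0.5, latent_u = FALSE, seed = NULL) {
  model <- match.arg(model)
  if (n < 4) stop("n must be >= 4", call. = FALSE)
  if (var_gx < 0 || var_gx >= 1 || var_xy < 0 || var_xy >= 1) {
    stop("var_gx and var_xy must lie in [0, 1)", call. = FALSE)
  }
  if (sigma2_mx < 0 || sigma2_my < 0) {
    stop("imprecision variances must be >= 0", call. = FALSE)
  }
  if (maf <= 0 || maf >= 1) stop("maf must lie in (0, 1)", call. = FALSE)
  structure(
    list(n = n, var_gx = var_gx, var_xy = var_xy,
         sigma2_mx = sigma2_mx, sigma2_my = sigma2_my,
         alpha_mx = alpha_mx, beta_mx = beta_mx,
         alpha_my = alpha_my, beta_my = beta_my,
         model = model, maf = maf, latent_u = latent_u, seed = seed),
    class = "sim_config"
  )
}

draw_genotype <- function(n, maf) {
  g <- stats::rbinom(n, 2, maf)
  if (stats::var(g) == 0) g[1] <- 2 - g[1] # guard tiny-n degenerate draws
  g
}

apply_measurement <- function(true, alpha_m, beta_m, sigma2_m) {
  alpha_m + beta_m * true +
    if (sigma2_m > 0) stats::rnorm(length(true), 0, sqrt(sigma2_m)) else 0
}

maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
}

#' Simulate from the causal model
#'
#' @param config A [sim_config()] with `model = "causal"`.
#' @return A `sim_dataset` list with elements `g`, `x`, `y`, `x_o`, `y_o`,
#'   `config`.
#' @export
simulate_causal <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$model != "causal") {
    stop("config is not a causal-model configuration", call. = FALSE)
  }
  maybe_seed(config$seed)
  n <- config$n
  var_g <- 2 * config$maf * (1 - config$maf)
  g <- draw_genotype(n, config$maf)
  beta_g <- sqrt(config$var_gx / var_g)
  x <- beta_g * g + stats::rnorm(n, 0, sqrt(1 - config$var_gx))
  beta_x <- sqrt(config$var_xy)
  y <- beta_x * x + stats::rnorm(n, 0, sqrt(1 - config$var_xy))
  finish_dataset(g, x, y, config)
}

#' Simulate from the non-causal (genetically confounded) model
#'
#' x and y are not causally related but share the instrument: the SNP
#' influences each through separate paths (or, with `latent_u = TRUE`,
#' through an explicit confounder u), inducing a marginal x-y correlation
#' with population cor(x, y | g) = 0 in the default structure.
#'
#' @param config A [sim_config()] with `model = "noncausal"`.
#' @return A `sim_dataset`.
#' @export
simulate_noncausal <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$model != "noncausal") {
    stop("config is not a non-causal-model configuration", call. = FALSE)
  }
  maybe_seed(config$seed)
  n <- config$n
  var_g <- 2 * config$maf * (1 - config$maf)
  g <- draw_genotype(n, config$maf)
  var_gy <- config$var_gx * config$var_xy
  if (config$latent_u) {
    # g -> u, then u loads on both traits; trait variance explained by u is
    # var_gx for x and var_gx * var_xy for y, so the g-trait correlations
    # match the minimal structure scaled by cor(g, u)
    beta_gu <- sqrt(config$var_gx / var_g)
    u <- beta_gu * g + stats::rnorm(n, 0, sqrt(1 - config$var_gx))
    x <- sqrt(config$var_gx) * u +
      stats::rnorm(n, 0, sqrt(1 - config$var_gx))
    y <- sqrt(var_gy) * u + stats::rnorm(n, 0, sqrt(1 - var_gy))
  } else {
    beta_gx <- sqrt(config$var_gx / var_g)
    beta_gy <- sqrt(var_gy / var_g)
    x <- beta_gx * g + stats::rnorm(n, 0, sqrt(1 - config$var_gx))
    y <- beta_gy * g + stats::rnorm(n, 0, sqrt(1 - var_gy))
  }
  finish_dataset(g, x, y, config)
}

finish_dataset <- function(g, x, y, config) {
  structure(
    list(
      g = g, x = x, y = y,
      x_o = apply_measurement(x, config$alpha_mx, config$beta_mx,
                              config$sigma2_mx),
      y_o = apply_measurement(y, config$alpha_my, config$beta_my,
                              config$sigma2_my),
      config = config
    ),
    class = "sim_dataset"
  )
}

#' Simulate from a configuration
#'
#' Dispatches to [simulate_causal()] or [simulate_noncausal()].
#' @param config A [sim_config()].
#' @return A `sim_dataset`.
#' @export
simulate_dataset <- function(config) {
  if (config$model == "causal") simulate_causal(config)
  else simulate_noncausal(config)
}

#' Population d value implied by a causal-model configuration
#'
#' Computes the exact population `d = rho_x,xo - rho_xy * rho_y,yo` from the
#' configured variance parameters: with unit-variance true traits,
#' `rho_x,xo = beta_mx / sqrt(beta_mx^2 + sigma2_mx)` (and analogously for
#' y), and `rho_xy = sqrt(var_xy)`.
#'
#' @param config A causal-model [sim_config()].
#' @return The population d.
#' @export
population_d <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$model != "causal") {
    stop("d is defined under the causal model", call. = FALSE)
  }
  rho_xxo <- sqrt(attenuation_factor(config$beta_mx, 1, config$sigma2_mx))
  rho_yyo <- sqrt(attenuation_factor(config$beta_my, 1, config$sigma2_my))
  d_statistic(rho_xxo, sqrt(config$var_xy), rho_yyo)
}

#' Default simulation parameter grid
#'
#' The full factorial grid used for the method comparison:
#' `cor(g,x)^2 = 0.1`; `cor(x,y)^2` in 0.2, 0.4, 0.6, 0.8; exposure and
#' outcome imprecision variances each in 0, 0.2, ..., 1; and sample sizes
#' 100, 1000, 10000 - 432 combinations in all.
#'
#' @param n Sample sizes.
#' @param var_gx Instrument-exposure variance explained.
#' @param var_xy Causal variance explained values.
#' @param sigma2_mx,sigma2_my Imprecision variance values.
#' @return Data frame with one row per parameter combination.
#' @export
default_grid <- function(n = c(100, 1000, 10000),
                         var_gx = 0.1,
                         var_xy = c(0.2, 0.4, 0.6, 0.8),
                         sigma2_mx = seq(0, 1, by = 0.2),
                         sigma2_my = seq(0, 1, by = 0.2)) {
  expand.grid(n = n, var_gx = var_gx, var_xy = var_xy,
              sigma2_mx = sigma2_mx, sigma2_my = sigma2_my,
              KEEP.OUT.ATTRS = FALSE)
}

# Stable 31-bit hash of a cell's parameter tuple, so per-cell seed streams do
# not move when cells are added to or removed from a grid.
cell_hash <- function(...) {
  s <- paste(vapply(list(...), function(v) formatC(v, digits = 15,
                                                   format = "g"),
                    character(1)), collapse = "|")
  h <- 7
  for (code in utf8ToInt(s)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

classify_mr_call <- function(outcome, model) {
  if (model == "causal") {
    switch(outcome, x_causes_y = "correct", y_causes_x = "wrong", "none")
  } else {
    if (outcome == "no_call") "none" else "wrong"
  }
}

classify_cit_call <- function(code, model) {
  if (model == "causal") {
    switch(code, model1_accepted = "correct", model2_accepted = "wrong",
           "none")
  } else {
    if (code %in% c("model1_accepted", "model2_accepted")) "wrong" else "none"
  }
}

#' Run the method-comparison experiment over a parameter grid
#'
#' For each grid cell and replicate, draws a dataset, applies the requested
#' methods to the *observed* traits at threshold `alpha`, classifies each
#' call as correct-direction, wrong-direction or no-call, and aggregates to
#' per-cell rates. Per-cell seeds are derived from the master seed and a
#' stable hash of the cell's parameters, so results are reproducible and
#' unchanged by adding cells.
#'
#' @param grid Data frame of cell parameters (columns `n`, `var_gx`,
#'   `var_xy`, `sigma2_mx`, `sigma2_my`), e.g. [default_grid()].
#' @param reps Replicates per cell.
#' @param methods Any of `"mr_steiger"`, `"cit"`.
#' @param seed Master seed.
#' @param model `"causal"` or `"noncausal"`.
#' @param alpha Significance threshold for calls.
#' @param n_null CIT condition-4 null simulation count.
#' @return Data frame with one row per cell x method: the cell parameters,
#'   `method`, `rate_correct`, `rate_wrong`, `rate_none`, `reps`, and the
#'   population `d_pop` (NA for the non-causal model).
#' @export
run_grid <- function(grid = default_grid(), reps = 100,
                     methods = c("mr_steiger", "cit"), seed = 1,
                     model = "causal", alpha = 0.05, n_null = 500) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(reps >= 1)
  rows <- vector("list", nrow(grid) * length(methods))
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    config <- sim_config(
      n = cell$n, var_gx = cell$var_gx, var_xy = cell$var_xy,
      sigma2_mx = cell$sigma2_mx, sigma2_my = cell$sigma2_my,
      model = model
    )
    d_pop <- if (model == "causal") population_d(config) else NA_real_
    cell_seed <- (cell_hash(cell$n, cell$var_gx, cell$var_xy,
                            cell$sigma2_mx, cell$sigma2_my) +
                    as.integer(seed)) %% 2147483647L
    set.seed(cell_seed)
    counts <- matrix(0L, nrow = length(methods), ncol = 3,
                     dimnames = list(methods, c("correct", "wrong", "none")))
    for (r in seq_len(reps)) {
      dat <- simulate_dataset(config)
      if ("mr_steiger" %in% methods) {
        obs <- correlations_from_individual(dat$g, dat$x_o, dat$y_o)
        st <- steiger_one_sample(obs)
        p_mr <- tsls(dat$g, dat$x_o, dat$y_o)$p_mr
        cls <- classify_mr_call(infer_direction(p_mr, st, alpha)$outcome,
                                model)
        counts["mr_steiger", cls] <- counts["mr_steiger", cls] + 1L
      }
      if ("cit" %in% methods) {
        cit <- cit_bidirectional(dat$g, dat$x_o, dat$y_o, alpha = alpha,
                                 n_null = n_null)
        cls <- classify_cit_call(cit$outcome_code, model)
        counts["cit", cls] <- counts["cit", cls] + 1L
      }
    }
    for (m in methods) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        cell[, c("n", "var_gx", "var_xy", "sigma2_mx", "sigma2_my")],
        method = m,
        rate_correct = counts[m, "correct"] / reps,
        rate_wrong = counts[m, "wrong"] / reps,
        rate_none = counts[m, "none"] / reps,
        reps = reps, d_pop = d_pop,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate paired two-cohort summary-statistic fixture tables
#'
#' Emulates the two-sample setting of paired cis-QTL summary tables: two
#' independent cohorts are drawn from `config`; the observed exposure is
#' regressed on the genotype in cohort 1 and the observed outcome on the
#' genotype in cohort 2, and each regression is written as a one-row
#' summary-statistic table. A sidecar manifest records the generating
#' parameters and the true causal direction. All files are plain
#' tab-delimited text.
#'
#' @param config A [sim_config()]; its `seed` (if any) fixes the draw.
#' @param out_dir Directory to write into (created if needed).
#' @param snp_id,exposure_id,outcome_id Identifiers used in the tables.
#' @return Invisibly, a list with `exposure`, `outcome` and `manifest` file
#'   paths.
#' @export
make_fixture_summary_tables <- function(config, out_dir,
                                        snp_id = "rs1",
                                        exposure_id = "exposure",
                                        outcome_id = "outcome") {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  maybe_seed(config$seed)
  cfg <- config
  cfg$seed <- NULL
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  row_for <- function(g, trait_values, trait_id) {
    fit <- stats::summary.lm(stats::lm(trait_values ~ g))$coefficients
    summary_assoc(
      snp = snp_id, trait = trait_id,
      beta = fit["g", "Estimate"], se = fit["g", "Std. Error"],
      pval = fit["g", "Pr(>|t|)"], n = length(g), effect_allele = "A"
    )
  }
  exp_tab <- row_for(d1$g, d1$x_o, exposure_id)
  out_tab <- row_for(d2$g, d2$y_o, outcome_id)
  paths <- list(
    exposure = file.path(out_dir, paste0(exposure_id, ".tsv")),
    outcome = file.path(out_dir, paste0(outcome_id, ".tsv")),
    manifest = file.path(out_dir, "manifest.tsv")
  )
  write_summary_table(exp_tab, paths$exposure)
  write_summary_table(out_tab, paths$outcome)
  manifest <- data.frame(
    true_direction = if (config$model == "causal") "x_causes_y" else "none",
    model = config$model, n = config$n, var_gx = config$var_gx,
    var_xy = config$var_xy, sigma2_mx = config$sigma2_mx,
    sigma2_my = config$sigma2_my
  )
  utils::write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
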