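---
title: "Inferring causal direction between imprecisely measured traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring causal direction between imprecisely measured traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(mrsteiger)
```

## The problem

Two molecular traits — say a DNA methylation probe and the expression of an
adjacent gene — are correlated, and a single cis-acting SNP associates with
both. Which trait does the SNP act on most proximally? Answering this orients
the causal arrow between the traits, but the SNP's biology is usually unknown,
and both traits are measured with platform-specific error. This package
implements an instrumental-variable answer (the MR Steiger test), its
measurement-error sensitivity analysis, a mediation-based comparator (the
CIT), and the simulation machinery to study when each fails.

## Model

The generative system is linear with additive genetic effects:

$$x = \beta_g g + \epsilon_g, \qquad y = \beta_x x + \epsilon_x,$$

with $g \sim \mathrm{Binom}(2, \mathrm{maf})$. Non-differential measurement
error maps each true trait to its observed value through a scale change and
added imprecision:

$$x_o = \alpha_{mx} + \beta_{mx} x + \epsilon_{mx}, \qquad
  \epsilon_{mx} \sim N(0, \sigma^2_{mx}),$$

and likewise for $y_o$. The genotype is assumed measured without error, and
the two traits' measurement errors are independent. A "non-causal" variant
replaces the $x \to y$ edge with independent paths $g \to x$ and $g \to y$
(optionally through an explicit latent confounder $u$), so the traits are
correlated but not causally related.

## The MR Steiger test

MR estimates the causal effect by scaling the SNP-outcome association by the
SNP-exposure association (`wald_ratio()` on summary data, `tsls()` on
individual data; with one instrument the two coincide). The associated
p-value $p_{MR}$ answers *whether* a causal relationship exists, but is
essentially symmetric in the two orientations, so it cannot say *which way*
it points.

Direction comes from asking which trait has the larger absolute correlation
with the instrument. With all variables in one sample, the test for a
difference between the two correlations sharing the variable $g$ is

$$Z = (Z_{gx} - Z_{gy})\sqrt{\frac{N-3}{2(1-\rho_{xy})h}},$$

where $Z_{g\cdot}$ are Fisher-transformed correlations,
$r_m^2 = (\rho_{gx}^2 + \rho_{gy}^2)/2$,
$f = (1-\rho_{xy})/(2(1-r_m^2))$ and $h = (1 - f r_m^2)/(1 - r_m^2)$
(`steiger_one_sample()`). The test suite validates this statistic against an
algebraically distinct pooled-covariance formulation of the same test, and
against a Monte-Carlo null (trivariate normal with equal instrument-trait
correlations).

With the two associations estimated in independent cohorts — the two-sample
setting, where only GWAS summary statistics are available — the
independent-correlations variant applies, and tolerates $N_1 \neq N_2$:

$$Z = \frac{Z_{gx} - Z_{gy}}{\sqrt{1/(N_1-3) + 1/(N_2-3)}}.$$

Summary statistics enter on the correlation scale through `r_from_pn()`,
which inverts the two-sided t-test of a regression slope:
$t = F^{-1}_{t,\,n-2}(1 - p/2)$, $|r| = t/\sqrt{t^2 + n - 2}$. We chose the
p+n inversion (rather than a beta/se/allele-frequency route) because p-values
and sample sizes are the fields reliably present in published summary tables;
the applied two-sample setting this package targets lists exactly those
fields. Instrument-trait correlations enter the tests as absolute values —
the question is which trait the instrument explains more of — while
$\rho_{xy}$ enters signed; raw signs are kept for reporting. A tie ($Z = 0$
exactly) yields "undetermined" rather than a tie-break.

The combined decision rule (`infer_direction()`) accepts a direction only
when both tests clear the threshold: $p_{Steiger} < \alpha$ and
$p_{MR} < \alpha$, with the direction given by $\mathrm{sign}(Z)$; otherwise
no call is made. The default $\alpha = 0.05$ mirrors the usual convention for
compiling simulation results; for real analyses a fixed threshold should not
carry inferential weight.

Multiple independent instruments are supported only at the correlation level:
`aggregate_instruments()` combines per-SNP correlations as
$\sqrt{\sum_i r_i^2}$ under independence. Effect meta-analysis across
instruments (IVW and relatives) and pleiotropy-robust estimators are out of
scope.

## Measurement-error sensitivity

Imprecision in $x$ attenuates every correlation involving it. Three analytic
objects quantify the consequences:

* **Attenuation factor** `attenuation_factor()`:
  $D = \beta_{mx}^2\mathrm{var}(x) / (\beta_{mx}^2\mathrm{var}(x) +
  \mathrm{var}(\epsilon_{mx}))$, the squared reliability correlation
  $\rho_{x,x_o}^2$. Pure rescaling leaves $D = 1$; only imprecision lowers it.
* **Residual covariance** `residual_cov_bias()`:
  $\mathrm{cov}(g, y_o - \hat y_o) = \beta_{my}\beta_g\beta_x
  \mathrm{var}(g)(1 - D)$. Mediation-based tests require this to be zero, so
  any exposure imprecision ($D < 1$) leaves a residual SNP-outcome
  association and misleads them — increasingly so at larger sample sizes.
* **The d statistic** `d_statistic()`:
  $d = \rho_{x,x_o} - \rho_{xy}\,\rho_{y,y_o}$. When $d > 0$ the observed
  correlations rank the traits as the true ones do and the Steiger call is
  expected to be correct; $d < 0$ marks the regime where it is liable to
  flip. A perfectly measured exposure forces $d \ge 0$.

### The reliability ratio R

The observed correlations bound the possible measurement error: since the
instrument explains $\rho_{g,x_o}^2$ of the *observed* exposure, the
reliability correlation $\rho_{x,x_o}$ cannot be below $\rho_{g,x_o}$
(otherwise the corrected correlation $\rho_{g,x} = \rho_{g,x_o}/\rho_{x,x_o}$
would exceed 1). `predicted_surface()` evaluates, for every admissible
reliability pair, what the Steiger comparison would have been had that much
measurement error been present. `reliability_ratio()` integrates this surface
over the admissible rectangle
$[\rho_{g,x_o}, 1] \times [\rho_{g,y_o}, 1]$, weighting every
measurement-error value equally, and reports

$$R = \frac{\text{volume supporting the inferred direction}}
           {\text{volume opposing it}}.$$

$R = 1$ flags maximal sensitivity; large $R$ means most admissible
measurement-error values leave the inference intact. A user-supplied
`weight` function can replace the uniform measure.

Two conventions deserve explanation because the design was genuinely open:

1. **Scale of the surface.** The volumes are integrated on the
   variance-explained scale, $z = (\rho_{g,y_o}/\rho_{y,y_o})^2 -
   (\rho_{g,x_o}/\rho_{x,x_o})^2$, not the plain correlation difference. The
   sign structure (hence every directional statement) is identical on either
   scale; the $r^2$ scale weights each measurement-error value by how much
   explained variance it would reassign, and is the convention under which
   the package's worked example reproduces the reference value
   $R = 4.40$ for $\rho_{gx}^2 = 0.01$, $\rho_{xy}^2 = 0.1$.
2. **Deterministic endpoint-inclusive lattice, default 500 steps/axis.** A
   deterministic grid makes $R$ reproducible without seeds; Monte-Carlo
   integration is retained in the tests as an independent oracle. The lattice
   includes the admissible boundary, where the corrected exposure correlation
   reaches exactly 1. Because the surface is steep there, the reported $R$
   retains a small resolution-dependent boundary contribution (for the
   worked example, 4.398 at 500 steps versus 4.56 in the continuum limit),
   so $R$ values should be compared at a common resolution; the default of
   500 is the package's reporting convention. Lattice points where the
   surface is exactly zero contribute no volume to either side.

```{r}
r_gx <- sqrt(0.01)
r_gy <- r_gx * sqrt(0.1)
reliability_ratio(r_gx, r_gy)
```

Swapping the observed pair transposes the lattice exactly, so the volume
ratio referred to a fixed direction inverts: the analysis cannot prefer a
direction merely through the labelling of the traits.

## The CIT comparator

The causal inference test combines four conditions for the orientation
"exposure mediates the SNP's effect on the outcome": (1) the SNP associates
with the outcome; (2) the SNP associates with the exposure given the outcome;
(3) the exposure associates with the outcome given the SNP; (4) the SNP is
independent of the outcome given the exposure. The omnibus p-value is the
largest of the four, and `cit_bidirectional()` runs both orientations,
classifying the pair of omnibus p-values into accepted model 1, accepted
model 2, no evidence, or potential confounding (both significant, no call).

Conditions 1-3 are single-df F-tests of the focal covariate. Condition 4 is
an equivalence problem — the interesting hypothesis is a *null* conditional
association — and is estimated by simulation: null datasets replace the
exposure by its genotype-fitted values plus permuted residuals, preserving
the SNP's non-mediated path to the outcome while severing the exposure's
residual association with it. A noncentral F distribution (numerator df 1,
denominator df $n-3$, noncentrality fitted by the method of moments) is then
fitted to the simulated statistics, and $p_4$ is its lower-tail probability
at the observed F. Small $p_4$ therefore means the residual SNP-outcome
association is consistent with full mediation; large $p_4$ means residual
association persists. The continuous tail (rather than a raw permutation
proportion, which is floored at $1/(n_{null}+1)$) is what lets the gradual
loss of mediation evidence under growing exposure imprecision show up as a
monotone trend in the forward omnibus p-value. The default `n_null = 500`
balances the granularity of the noncentrality estimate against runtime, and
permutation streams are seedable.

Equivalence with the reference CIT implementation is behavioural, not
numerical: the package asserts calibration under the null, power under full
mediation, the degradation and eventual reversal of the favoured orientation
as exposure imprecision grows, and the both-ways-significant signature of
strong latent confounding — not agreement of p-values to any tolerance,
since the reference empirical-null construction is not specified to that
level of detail.

## Simulation design

`sim_config()` fixes a parameter cell; `simulate_causal()` /
`simulate_noncausal()` draw datasets; `run_grid()` runs the
method-comparison experiment and reports per-cell rates of correct-direction,
wrong-direction and no-call outcomes, stratified by the population
`population_d()` value.

Choices worth recording:

* **Unit-variance parameterisation.** Effect sizes are solved in closed form
  so that the population $\mathrm{cor}(g,x)^2$ and $\mathrm{cor}(x,y)^2$ hit
  their targets with unit-variance true traits
  ($\beta_g = \sqrt{\mathrm{var}_{gx}/\mathrm{var}(g)}$,
  $\beta_x = \sqrt{\mathrm{var}_{xy}}$). This keeps the imprecision variances
  $\sigma^2_{m*} \in [0, 1]$ on a directly interpretable scale —
  $\sigma^2_{mx} = 1$ gives reliability $\rho^2_{x,x_o} = 0.5$ — and makes
  population quantities such as $d$ exact, which the grid stratification
  needs.
* **Default grid.** $\mathrm{cor}(g,x)^2 = 0.1$;
  $\mathrm{cor}(x,y)^2 \in \{0.2, 0.4, 0.6, 0.8\}$; $\sigma^2_{mx}$ and
  $\sigma^2_{my}$ each in $\{0, 0.2, \ldots, 1\}$;
  $n \in \{100, 1000, 10000\}$ — 432 cells. `maf` defaults to 0.5.
* **Non-causal magnitudes.** The instrument explains $\mathrm{var}_{gx}$ of
  $x$ and $\mathrm{var}_{gx}\cdot\mathrm{var}_{xy}$ of $y$, mirroring the
  instrument-outcome variance the causal chain would imply; this is a
  convention, chosen so the two models are power-matched at the instrument.
  The minimal structure draws independent residuals
  ($\mathrm{cor}(x,y\,|\,g) = 0$); `latent_u = TRUE` adds an explicit
  confounder so the traits remain correlated given the SNP, the structure
  under which the CIT's both-ways-significant confounding signature appears.
* **Seeding.** Per-cell seeds are derived from the master seed plus a stable
  hash of the cell's parameter tuple, so enlarging a grid never perturbs
  existing cells and identical seeds reproduce results bit-for-bit.
* **Problem sizes.** The test suite runs the experiment at reduced scale —
  tens of replicates per cell and condition-4 null counts of 150-500 —
  chosen so the whole suite completes in a few minutes while keeping
  Monte-Carlo error well inside the asserted tolerances; the headline
  calibration checks use 500 replicates.

`make_fixture_summary_tables()` closes the loop for the two-sample pipeline:
it draws two independent cohorts, regresses each observed trait on the
genotype in its own cohort, and writes one-row summary-statistic tables plus
a manifest, emulating the paired cis-mQTL/cis-eQTL tables of a real
two-sample analysis.

### What the generator does and does not emulate

The generator covers additive single-SNP effects, linear trait relationships,
Gaussian noise, and non-differential measurement error in both traits. It
does not emulate horizontal pleiotropy beyond the single-SNP confounding
model, binary traits (no liability-scale conversion), winner's curse in the
discovery of instruments, correlated measurement errors, or LD between
instruments. Passing tests therefore demonstrate correctness of the
implementation under the stated model, and the documented sensitivities to
measurement error and confounding within it — not robustness of the method
on real data, where these excluded features are present.

## Numerical notes and degenerate inputs

* `fisher_z()` requires $|r| < 1$; the one-sample test rejects
  $|\rho_{xy}| = 1$ (the $h$ term is undefined) and both tests require
  $N > 3$.
* `r_from_pn(1, n) = 0` exactly; p-values of 0 are rejected as invalid
  rather than clamped.
* Zero-variance inputs, collinear CIT covariates, and zero first-stage
  slopes raise errors naming the degeneracy instead of returning NaN.
* Wald-ratio p-values use the normal reference distribution (summary-data
  convention, large-sample regime); 2SLS standard errors use the IV form
  with residuals against the observed exposure, which is what keeps the
  estimator consistent under exposure imprecision.
* `reliability_ratio()` reports `R = Inf` with an `opposed_empty` flag when
  no admissible lattice point opposes the inferred direction.

## Limitations

The package tests direction between exactly two traits sharing one
instrument (plus independent-instrument aggregation of correlations); it
assumes no horizontal pleiotropy and cannot distinguish the causal model
from pleiotropic confounding with a single instrument — the CIT is included
precisely because its outcome space contains that extra call. The analytic
confounding-region surface is not implemented; confounding sensitivity is
explored only through the non-causal simulation model. Binary traits,
dosage genotypes, VCF parsing, LD lookup and allele-frequency-based
standardisation are out of scope.
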