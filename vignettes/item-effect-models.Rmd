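---
title: "Multi-state models with person-specific item effects: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-state models with person-specific item effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lstitem)
```

## The measurement model

`lstitem` fits two nested-in-spirit measurement models to an $I$-item,
$T$-occasion panel ($T \ge 3$), ordered item-major within ascending
occasion blocks.

The **states-only** model assumes one common latent state $\eta_t$ per
occasion with congeneric, time-invariant measurement (strong/scalar
invariance):
$$Y_{it} = \alpha_i + \lambda_i \eta_t + \varepsilon_{it}, \qquad
  \alpha_r = 0,\ \lambda_r = 1,$$
for a reference item $r$.  The **item-effects** model fixes all loadings to
1 and intercepts to 0 and adds stable person-specific latent difference
variables:
$$Y_{it} = \eta_t + \delta_i + \varepsilon_{it}, \qquad \delta_r \equiv 0.$$
Here $\eta_t$ is the reference item's true score at occasion $t$ and
$\delta_i$ the time-constant difference between item $i$'s true score and
the reference item's.  At least three occasions are required for the
$\delta_i$ to be identified longitudinally, which `panel_design()` enforces.

Residual variances are free per item $\times$ occasion (15 in the 5×3
design) and residual covariances are zero.  This is the only residual
structure consistent with the published degrees of freedom (103 and 85 for
5×3): `count_df()` reproduces both from pure parameter counting, and the
package treats that arithmetic as normative.

## Identification and the reference switch

The choice of $r$ is an identification constraint, not a substantive one:
with new reference $s$,
$$\eta'_t = \eta_t + \delta_s,\quad
  \delta'_i = \delta_i - \delta_s\ (i \neq r, s),\quad
  \delta'_r = -\delta_s$$
is an exact linear bijection of the latent space that leaves
$\mu(\theta), \Sigma(\theta)$ untouched.  `reference_switch()` applies the
map to a latent moment table; `switch_parameters()` applies it to a
parameter vector.  Two consequences are tested as invariants: fitted
log-likelihoods and all fit indices agree across references, and moments
mapped from one fit agree with the directly re-estimated moments under the
other reference.  The map is an involution, which is also tested.

The published reference-3 moment tables for the two measurement periods
(complete sample, $N = 2{,}543$) ship with the package
(`published_latent_moments()`).  They are inputs, not package output: the
raw panel data are access-restricted, so derived quantities (the whole
reference-5 table) are recomputed from these printed estimates.

## Estimation

Both estimators reduce to one computation: rows are grouped by missingness
pattern, each group is summarized by its mean and ML-divisor covariance,
and the log-likelihood is the sum of multivariate-normal group
contributions on the corresponding submatrices of $(\mu, \Sigma)$.
Complete-data ML is the single-group special case, so "FIML equals ML on
complete data" is an identity of the code path.  Listwise deletion is an
explicit preprocessing option mirroring complete-case analyses.

Numerical choices:

* **Parameterization.** $\Phi$ through its Cholesky factor with logged
  diagonal, $\theta$ on the log scale: every optimizer iterate is
  admissible, so no constraints or penalties are needed.
* **Gradients.** Analytic throughout (accumulated per pattern group in
  $(\mu, \Sigma)$, chained through the moment structure and the
  transforms); verified against central differences in the tests.
* **Starting values.** Method of moments: state means from the reference
  item's observed means; state covariances from the reference item's
  cross-wave covariances (error-free because residuals do not repeat over
  waves); item-effect moments from difference-score cross-wave
  covariances; $\theta$ at half the observed variances.  The start matrix
  is floored to be safely positive definite.  Starts are deterministic, so
  fits need no seed.
* **Convergence.** `nlminb` with `rel.tol = 1e-14` (up to 1000
  iterations).  This is tighter than typical SEM defaults on purpose: the
  package asserts agreement of *independently optimized* equivalent
  parameterizations to $10^{-6}$ relative (including structural $R^2$),
  and a $10^{-9}$–$10^{-10}$ stop measurably misses that (observed $R^2$
  gap $\approx 2\times10^{-6}$ at `rel.tol = 1e-10` versus
  $3\times10^{-9}$ at `1e-14`).  With analytic gradients the extra
  iterations are cheap.  Non-convergence is a flagged result, not an
  error; residual variances near zero are recorded as boundary warnings.
* **Standard errors.** Inverse observed information, computed as central
  differences of the analytic gradient in the natural parameterization
  $(\kappa, \mathrm{vech}\,\Phi, \lambda, \alpha, \theta)$.  A singular
  information matrix raises a message naming the parameters loading on the
  non-identified direction.

## Fit evaluation

* $\chi^2 = N F_{ML}$ by default, with an $(N-1)$ option; the RMSEA
  denominator is always $df\,(N-1)$ (both published RMSEA checks, .043 and
  .111, pass at three decimals under either $\chi^2$ multiplier).
* The RMSEA 90% CI inverts the noncentral $\chi^2$ distribution in the
  noncentrality parameter by bisection on $[0, 10\chi^2]$ to $10^{-8}$.
* SRMR uses covariance residuals only (the mean structure is saturated in
  the item-effects model), over the $p(p+1)/2$ lower-triangle cells.
* CFI/TLI use the independence baseline with free means and variances
  ($df_b = p(p-1)/2$).  Under FIML the baseline is fitted per variable on
  its observed entries and the model $\chi^2$ is the likelihood ratio
  against the saturated model, whose ML solution is obtained by an EM
  algorithm for the unstructured multivariate normal.  Which baseline
  commercial software uses under FIML is not standardized; this choice is
  documented rather than configurable.
* Threshold labels follow the conventional cutoffs: good at
  CFI/TLI $\ge .97$, RMSEA $\le .05$, SRMR $\le .05$; acceptable at
  .95/.95/.08/.10.
* `lr_test()` permits zero difference in free parameters (statistic 0,
  p undefined) so equivalent reparameterizations can be compared; actual
  nesting of the two variants is the caller's assertion, since the
  congeneric states-only model is not a parametric submodel of the
  item-effects model in the strict sense.

## Inference on latent moments

Significance flags reproduce the shape of published moment tables: means
by direct Wald $z$; correlations by Fisher-$z$ with delta-method standard
errors; standard deviations via the Wald $z$ of the *variance* against
zero.  A log-scale variance test was considered and rejected: the
statistic $\log\hat\sigma^2 / se(\log\hat\sigma^2)$ tests
$\sigma^2 = 1$, not $\sigma^2 = 0$, and a log-scale confidence interval
can never contain zero, making the hypothesis degenerate on that scale.
Delta-method SE calibration is itself tested (empirical SD of estimates
across replications versus mean reported SE).

## Structural models and incremental validity

Outcome composites (built by averaging available item responses,
`build_composite()`) enter as a single manifest variable $Z$ regressed on
the latent variables *inside* one simultaneous ML fit — not factor-score
regression:
$$Z = \nu + \textstyle\sum_j \gamma_j \zeta_j + \varepsilon_Z, \qquad
  R^2 = \frac{\gamma'\Phi\gamma}{\gamma'\Phi\gamma +
  \mathrm{var}(\varepsilon_Z)},$$
with standardized coefficients
$\beta_j = \gamma_j\,\mathrm{SD}(\zeta_j)/\mathrm{SD}(Z)$ using the
model-implied outcome SD.  Predictor sets are the states alone or states
plus all item-effect variables; $\Delta R^2$ compares the two, alongside
their likelihood-ratio test.  Multiple outcomes are analyzed in separate
models.  Standardized coefficients can exceed 1 in magnitude under
predictor collinearity; the result object flags this rather than clamping.

Two properties are worth keeping in mind (both tested): the full-model
$R^2$ is invariant to the reference item, but the states-only $R^2$ is
not — under different references the states *are* different variables.

## The synthetic-data generator

The generator is a first-class module stating a fixed world, not a tuning
dial:

* **Latent truth** `default_true_parameters()`: $\kappa, \Phi$ equal the
  published reference-3 moment table of the chosen period (state means
  ≈ 5.5, SDs ≈ 1.0, state correlations .70–.79; item-effect means −0.21 to
  −0.99, SDs 0.39–0.90).  Residual variances are 0.5 throughout — chosen
  once so that all implied observed-item SDs fall inside the reported
  1.08–1.63 range (verified by a test, not adjusted afterwards).
* **Responses** are continuous by default; the analysis model is
  linear-normal and the published analysis treated the 7-point responses
  as continuous.  `discretize = TRUE` rounds and clips to 1..7 as a
  deliberate model-mismatch mode for robustness experiments.
* **Outcomes** are generated from the same latent draws with target
  standardized coefficients (defaults use the published full-model
  magnitudes), rescaled to the reported composite scales (mean 2.20 /
  SD 0.82 and mean 1.20 / SD 0.34), and passed through a monotone
  right-skew transform $\exp(s\,u)$ (strength 0.5 by default, then
  re-standardized), matching the reported right skew of both composites.
  Because the latents and the linear index are jointly normal, Stein's
  lemma makes every covariance with the transformed outcome proportional
  to its linear counterpart — so the transform attenuates coefficients
  uniformly but cannot create spurious partial effects; in particular the
  null-$\Delta R^2$ property is unaffected.  Tests that check exact
  coefficient recovery switch the transform off explicitly.
* **Missingness** is wave-level unit nonresponse, MCAR at a per-wave
  rate, never removing a respondent's last remaining wave — matching
  panel nonresponse rather than item skipping (the emulated study
  reported no item-level missingness among completers).
* **Determinism**: one seed fixes the panel, the outcomes and the
  missingness mask (R's default Mersenne-Twister stream).

What a green test establishes — and what it does not: the generator shares
the analysis model's functional form (apart from the optional skew and
discretization), so recovery and calibration results certify the
estimation machinery, not the model's adequacy for any real scale.  Real
panel data bring ordinal responses, MAR-at-best nonresponse tied to the
outcomes, sample refreshment, and item-effect structures that may drift
over time; none of these are represented.

## Simulation scale in the shipped tests

The test suite keeps the published simulation designs but runs them at
desk scale: parameter recovery and FIML-bias checks use 100 replications
at $N = 2{,}000$, the $\chi^2$ calibration 500 replications, the
null-$\Delta R^2$ check 40 replications at $N = 5{,}000$ (reduced from
100; the median criterion is unchanged).  The full suite completes in
roughly two minutes on one CPU.

## Known limitations

* No robust/scaled test statistics, sandwich SEs, or bootstrap intervals.
* Ordinal/categorical measurement models are out of scope; so are
  autoregressive state structures and partial-invariance variants.
* The FIML $\chi^2$/baseline construction (EM saturated model,
  per-variable baseline) is one defensible convention among several;
  comparisons with software using another baseline can differ in CFI/TLI
  under missingness.
* Wald flags use plain observed-information SEs; no small-sample or
  robust corrections.
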