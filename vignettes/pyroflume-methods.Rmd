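---
title: "Methods: models, generators and numerical choices in pyroflume"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generators and numerical choices in pyroflume}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyroflume)
```

## The experiment this package models

pyroflume analyzes paired control-versus-treatment in-stream flume
experiments on pyrogenic carbon (PyC, wildfire charcoal) inputs to
rivers. Ten streamside flumes are fed by river water; five receive a
pulse of charcoal in mesh bags, five receive blank bags. Water is
sampled at each outflow at 1, 2, 3, 4, 6 and 8 h for dissolved organic
carbon (DOC), absorbance (SUVA254) and fluorescence (EEMs); benthic
biofilm enzyme activities are assayed at the end; complementary
laboratory bottle leachings close the carbon mass balance.

All stages run from synthetic data with the statistical structure the
analysis assumes, so the full pipeline is testable without any field
download.

## Repeated-measures Gaussian-process treatment model

Each flume's time series is one draw from a multivariate normal with a
linear mean and a temporally decaying covariance:

$$ y_{f}(t) = \beta_0 + \beta_T T_f + \varepsilon_f(t), \qquad
\mathrm{Cov}\left[\varepsilon_f(t_i), \varepsilon_f(t_j)\right]
= \alpha^2 \exp\!\left(-\frac{(t_i - t_j)^2}{2\rho^2}\right)
+ \sigma^2 \delta_{ij}, $$

where $T_f$ is the treatment indicator (control = 0, treatment = 1),
$\alpha$ (response units) is the process amplitude, $\rho$ (hours) the
temporal bandwidth and $\sigma$ the residual SD. Flumes are mutually
independent and share a single hyperparameter set. The kernel
convention is the standard squared-exponential with the factor of 2 in
the denominator — the correlation $\rho$ hours apart is $e^{-1/2}$ —
and it is isolated in `kernel_matrix()` so the convention is auditable
in one place.

**Priors.** The source analysis does not publish priors, so the
package's own choice is weakly informative and scale-adapted:
$\beta_0 \sim N(\bar y, 2 s_y)$, $\beta_T \sim N(0, 2 s_y)$,
$\alpha, \sigma \sim \text{half-}N(s_y)$, and
$\rho \sim \text{half-}N(\text{span}/2)$ where span is the sampled time
range. All are proper; with 60 observations the likelihood dominates.

**Sampling.** `fit_gp()` runs an affine-invariant ensemble sampler
(stretch moves, 10 walkers per ensemble) on
$(\beta_0, \beta_T, \log\alpha, \log\rho, \log\sigma)$. The stretch
move was chosen over random-walk Metropolis because $\rho$ and $\sigma$
trade off along a curved ridge when the bandwidth is weakly identified
at six time points, and affine invariance handles that geometry without
hand-tuned proposal covariances. Four independent ensembles of 5000
post-warmup draws each are compared by split-$\hat R$; a maximum above
1.05 sets `converged = FALSE` and raises a warning — never a silent
success. A Laplace (posterior mode + Gaussian) backend,
`method = "laplace"`, exists for simulation studies that need hundreds
of fits; coverage and recovery tests use it, headline fits use MCMC.

**Interval convention.** All intervals are equal-tailed 90% credible
intervals, matching the 90% bands the motivating study reports. The
treatment effect equals, draw for draw, the difference between
treatment and control predicted means, so `predict_group_means()` and
the effect posterior can never disagree.

**Numerics.** A jitter of $10^{-9}\alpha^2$ is added to the kernel
diagonal before Cholesky factorization; `rho = 0` with distinct times
is rejected as a degenerate bandwidth rather than silently producing a
white-noise kernel.

**GLM comparison.** `fit_glm()` is ordinary least squares of the value
on the treatment dummy, ignoring time. When data are generated with
$\alpha = 0$ the two models must agree (a property test asserts
agreement within 2 combined SEs), reproducing the "similar parameter
estimates" sanity check of the source analysis.

## Synthetic flume generator

`simulate_flume_series()` draws each flume directly from the model
above; its defaults are the study's stated world: 5 + 5 flumes, times
{1, 2, 3, 4, 6, 8} h, DOC baseline 3.32 mg/L with effect +0.40 mg/L,
SUVA254 baseline 3.84 with effect −0.31. The covariance scales
($\alpha = 0.25$, $\rho = 2$ h, $\sigma = 0.25$ for DOC and SUVA254)
are not printed in the source; they were fixed once at values that give
within-flume autocorrelation over a couple of hours and marginal SDs of
≈0.35 response units, consistent with the reported DOC range
(2.61–4.17 mg/L in controls) and reported effect-size SDs (±0.20,
±0.15). pH has no published variance decomposition; it reuses the same
GP structure by analogy with baseline 8.0 (typical for a circumneutral
forest stream), effect +0.25 and tighter scales
($\alpha = 0.08$, $\sigma = 0.05$), a choice the package documents but
cannot cite.

What a green recovery test establishes: that the estimator finds
effects planted under the model's own assumptions. It does not
establish robustness to non-Gaussian noise, flume-to-flume
heteroscedasticity, or drift unmodelled by the kernel — none of which
the synthetic world contains.

## EEM chemometrics

**SUVA254** is the decadal absorption coefficient at 254 nm (absorbance
divided by path length in metres) divided by DOC, in
L mg-C$^{-1}$ m$^{-1}$; absorbance is linearly interpolated between the
250 and 255 nm points of the 5 nm instrument grid.

**Scatter handling.** Raman-type scatter is removed by subtracting a
Milli-Q blank EEM measured on the identical grid; Rayleigh bands are
*masked* — cells with $|em - ex| \le w$ or $|em - 2ex| \le w$ are set
missing, not interpolated — because deletion is what the source
procedure describes, and missing-data ALS avoids inventing intensities.
The half-width default $w = 10$ nm is the package's own choice (no
width is published); it is exposed in the configuration.

**PARAFAC.** `fit_parafac()` decomposes the samples × excitation ×
emission cube as $x_{ijk} \approx \sum_r a_{ir} b_{jr} c_{kr}$ with
nonnegativity on all three modes (standard for fluorescence), by
hierarchical alternating least squares: each component column has a
closed-form nonnegative update, so every block update is non-increasing
in the objective. Masked cells are handled by
expectation-maximization — imputed from the current model at the top of
each iteration and excluded from the reported SSE — which keeps the
observed-cell objective monotone. Defaults: best of 10 random starts,
relative SSE tolerance $10^{-8}$, 2500 iteration cap; non-convergence
returns the model with a `converged = FALSE` flag. After fitting,
spectral loadings are normalized to unit Euclidean norm (magnitude
lives in the sample mode) and components are ordered by energy,
descending. Peak reporting breaks ties toward the shorter wavelength.

**Outliers.** Sample leverage is the diagonal of the hat projector of
the sample-loading matrix; values sum to the component count.
`flag_outliers()` flags leverage > 0.15 or > 2× the mean. The original
exclusion (60 → 54 EEMs) was interactive and not exactly reproducible,
so the thresholds are explicit configuration, and a split-half
congruence diagnostic is provided as an optional check on the component
number.

**Synthetic EEMs.** Components are Gaussian in both excitation and
emission — the simplest line shape with clean, recoverable maxima; the
source describes no line shapes, only peak positions (250/425, 360/465,
285/500, 265/335 nm), which are the generator defaults together with
the instrument grids (ex 250–550, em 250–600, 5 nm). Sample loadings
default to i.i.d. Uniform(0.5, 1.5) — moderate between-sample contrast,
as in a short field campaign where composition varies less than
concentration. A consequence worth knowing: with few samples (≲ 12) and
heavily overlapping spectra this low contrast can make ALS collapse two
components into one; the packaged 30-sample default is comfortably
identifiable, and unit tests that probe small cubes pass explicit
higher-contrast loadings instead of quietly widening the default.
Optional scatter injection places triangular ridges at $em = ex$ and
$em = 2ex$ (half-width 10 nm, second order at half amplitude). Width
defaults (ex 25–35 nm, em 35–50 nm) were fixed once to give visibly
overlapping but resolvable components.

## Enzyme activity ratios

Eight enzymes are tracked (Glu, Xyl, Cbh, NAG, Pho, Lip, Pep, Pox);
activities are biomass-unnormalized, so inference is restricted to the
six biomass-independent ratio indices: Xyl/Glu, (Glu+Xyl)/Cbh, Glu/Pep,
Glu/Pox (the recalcitrance index), Pep/Pho and NAG/Pox. Ratio
computation is scale-invariant by construction and property-tested;
zero denominators yield `NA` with a warning, never infinities.

Group comparison defaults to a *paired* t test on per-pair differences
with df = n − 1: with five flumes per group the published df = 4
implies pairing (a pooled two-sample test would give df = 8). Which
flumes were paired is not published; the package pairs by index and
offers Welch mode for the unpaired reading.

The synthetic plate draws lognormal activities (positivity guaranteed;
no error model is published) with CV 0.15 and treatment multipliers
whose directions mirror the reported shifts (Pox up, Glu down, hence a
lower recalcitrance index); magnitudes are the package's choice.

## Leaching mass balance

Field release per flume is $m = Q \, t \, \Delta\mathrm{DOC}$
(L/min × min × mg/L = mg) with defaults Q = 0.47 L/min, t = 480 min and
the modelled DOC effect; per-gram release divides by 225 g of charcoal
(15 bags × 15 g). The worked example gives 0.47 × 480 × 0.40 = 90.24
mg, 1% above the printed 89.45 mg — attributed to rounding of the
printed inputs, and asserted as such: tests require 1% agreement with
the printed value when printed inputs are used, and exact arithmetic
otherwise. POC is estimated as laboratory TOC per gram (0.84) minus
field DOC per gram; a negative difference is flagged as inconsistent,
never clipped.

## Reproducibility machinery

Every generator and fit takes an explicit integer seed and restores the
caller's RNG state; the pipeline (`run_full_analysis()`) derives
per-stage sub-seeds from one master seed and regenerates every output
file byte-identically. Configurations are JSON with defaults filled in
for absent fields; the run log records seeds, versions and the kernel
convention so divergences from the unpublished original settings remain
auditable.

## Known limitations

* The printed forms of the source's model equations are images in the
  extracted text; the kernel and mean structure follow the prose, so
  reproduction of the original intervals is approximate by
  construction.
* Field quantities that depend on the raw campaign data (observed DOC
  ranges, the exact 60 → 54 EEM exclusion, published p-values) are out
  of reach of the synthetic world; tests cover them with property-based
  substitutes instead.
* The GP assumes Gaussian residuals, a shared hyperparameter set and
  zero between-flume covariance; $\rho$ is weakly identified from six
  time points and is asserted only to an order of magnitude in recovery
  tests.
* Inner-filter correction, Raman normalization and OpenFluor matching
  are deliberately out of scope.
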