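---
title: "Methods: the geofuse Bayesian fusion model"
author: "geofuse authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the geofuse Bayesian fusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Annual-mean NO2 is measured at points by two kinds of instrument —
sparse, precise automatic monitors and abundant, cheaper passive
diffusion tubes — while atmospheric dispersion models supply a complete
but uncalibrated background surface on a regular 1 km grid. Epidemiology
needs concentration estimates, with uncertainty, everywhere in a study
region. `geofuse` fuses the three sources: the point measurements are
regressed on the log of the gridded modelled surface (and site
metadata), a spatial random effect absorbs what the covariates miss, and
Bayesian kriging carries the fitted relationship, with full parameter
uncertainty, onto the grid.

## The model

With $Y(s_i)$ the natural-log concentration at site $s_i$,
$i = 1, \dots, m$:

$$Y(s_i) \sim \mathrm{N}\!\big(z(s_i)^{T}\alpha + \phi(s_i),\;
\nu^2 \sigma^2\big), \qquad
\phi \sim \mathrm{N}\!\big(0,\; \sigma^2 \Sigma(\rho)\big),
\qquad \Sigma(\rho) = \exp(-\rho D),$$

where $D$ is the matrix of inter-site Euclidean distances, $\sigma^2$
the spatial variance, $\nu^2 \in (0,1)$ the noise-to-signal ratio (so
$\nu^2\sigma^2$ is the nugget: measurement error plus micro-scale
variation), and $\rho$ the spatial decay (effective range $\approx
3/\rho$). The covariate vector $z(s_i)$ always contains an intercept
and, per `covariate_spec()`, the log modelled concentration, a
monitor/tube indicator (reference: tube), the local-environment class
(kerbside, roadside, rural, special, urban background; reference:
kerbside), and optionally interactions of log modelled with the easting
and northing coordinates, which let the calibration of the modelled
surface drift smoothly over space.

Priors: $\alpha \sim \mathrm{N}(0, 1000\, I)$ (the variance is an
implementation default for a deliberately weak prior),
$\sigma^2 \sim \mathrm{InvGamma}(0.001, 0.001)$, $\nu^2 \sim
\mathrm{U}(0,1)$, and a *discrete* uniform prior for $\rho$ over $r =
50$ candidates. The discrete prior is the computational heart of the
method: every $\Sigma(\rho_k)$ is factorised exactly once, up front, in
`build_correlation_cache()`, so the $O(m^3)$ work is $r$ factorisations
per fitted dataset regardless of chain length (the cache exposes a
counter, and the test suite pins it to $r$).

**Units.** Coordinates are stored in metres in all files and converted
to kilometres at one boundary (`distance_matrix()`), so $\rho$ is per
km. The distance unit of the decay parameter is a pure convention, and
per km is the only reading under which the reference fit's decay
(posterior median 12.852, i.e. an effective range of about 230 m) is
dimensionally sensible; the package adopts it throughout and flags it
here as a choice.

**Decay grid.** The default `default_rho_grid()` places 50
geometrically spaced candidates so the effective range $3/\rho$ spans
2%–200% of the maximum inter-site distance — a wide, data-adapted support
that lets the data place the range anywhere from far below the typical
site spacing to beyond the region size.

## Inference

`fit_fusion(..., method = "mcmc")` runs a systematic-scan sampler,
order $\alpha \to \phi \to \sigma^2 \to \nu^2 \to \rho$ (any fixed scan
is valid; this order maximises reuse of per-iteration quantities):

* $\alpha$: conjugate Gaussian draw given $Y - \phi$.
* $\phi$: exact multivariate Gaussian draw with precision
  $\sigma^{-2}(\Sigma^{-1} + \nu^{-2} I)$.
* $\sigma^2$: inverse-gamma draw with shape $a + m$ — both the spatial
  and the nugget likelihood scale with $\sigma^2$, so each contributes
  $m/2$; this follows algebraically from the model though it is rarely
  written out — and scale
  $b + \tfrac12[\phi^{T}\Sigma^{-1}\phi + \nu^{-2}\lVert Y - Z\alpha -
  \phi\rVert^2]$.
* $\nu^2$: random-walk Metropolis on the logit scale (Jacobian
  included). The step size is adapted towards a 20–50% acceptance rate
  during burn-in *only* and frozen afterwards, preserving detailed
  balance of the retained chain. The proposal family is the
  package's choice; any random-walk proposal on a bijection of (0,1)
  would do.
* $\rho$: exact draw from its discrete full conditional, computed with a
  log-sum-exp guard from the cached inverses and log-determinants.

Every full conditional is tested against an independent brute-force
oracle (closed-form algebra, joint-Gaussian conditioning, grid
quadrature, or enumerate-and-normalise) on toy problems.

Convergence reporting follows single-chain trace-plot practice: the
summary prints a Geweke-style stationarity z-score for $\sigma^2$ and
$\nu^2$ and the `plot()` method draws the traces; a single chain is
used. Burn-in length is the user's choice (`n_burn`); the package
defaults to 2000 with 1000 retained for interactive use, and the
simulation studies below state the lengths they use.

Comparators: `method = "reml"` maximises the restricted log-likelihood
of the marginal model $Y \sim \mathrm{N}(Z\alpha, \sigma^2[\Sigma(\rho)
+ \nu^2 I])$ — $\sigma^2$ profiled in closed form, $\nu^2$ by 1-D
optimisation, $\rho$ by profile search over the same discrete grid —
and then treats the estimates as fixed and known when predicting, which
is exactly the contrast the Bayesian fit is meant to expose (narrower,
slightly under-covering intervals). `method = "ols"` ignores spatial
autocorrelation entirely (`stats::lm`, t-based prediction intervals).

## Prediction

Prediction is the two-step procedure, applied per retained draw. First
the spatial effects are kriged: given a draw $(\phi, \sigma^2, \rho)$,

$$\phi^* \mid \phi \sim \mathrm{N}\!\big(C\,\Sigma^{-1}\phi,\;
\sigma^2[\Sigma_{pred} - C\,\Sigma^{-1}C^{T}]\big),$$

with $C$ the prediction-to-observation correlation matrix — the
standard conditional multivariate Gaussian, equivalent to ordinary
kriging of the noiseless field. (Two-step kriging is sometimes written
with the $N \times N$ prediction-set correlation matrix inverted inside
both moments, a form that cannot be evaluated dimensionally; the
conditional-MVN form is the only shape-consistent reading and is the
one that is genuinely equivalent to ordinary kriging.) Second, the
observation model adds the covariate mean and nugget: $Y^* \sim \mathrm{N}(z^{*T}\alpha + \phi^*,
\nu^2\sigma^2)$.

Grid cells are predicted in batches (default 250) so the conditional
covariance never exceeds memory; conditioning is only on $\phi$, so
draws are exact and independent across batches. Draws sharing a decay
candidate share their kriging weights and covariance factor, which
makes whole-grid prediction cheap. Conditional covariances at or near
observation sites are exactly singular; a Cholesky attempt falls back
to an eigendecomposition with negative eigenvalues clipped at zero
(warning if the deficit exceeds `1e-8` relative).

Point estimate and intervals are the per-cell posterior median and
central 95% of the $Y^*$ draws on the log scale; medians and endpoints
are exponentiated to concentrations, so the concentration-scale median
is exactly the exponential of the log-scale median (monotone-transform
equivariance — the package never interpolates quantiles on the
concentration scale). The reported "standard error" is the log-scale
predictive standard deviation. Following standard exposure-assessment
practice, `predict_grid()` forces each cell's
environment to urban background (urban cells) or rural, and the source
indicator to its reference (tube): kerbside or roadside concentrations
are not representative of a 1 km average or of population exposure.

## Validation

`loocv()` removes each site in turn, refits, and predicts it, reporting
mean bias, RMSPE and the coverage of the central 95% prediction
intervals — all on the **log scale**, the modelling scale (reported validation
magnitudes of ~0.25 are log-scale quantities even when casually
labelled in concentration units; the package states the scale
explicitly everywhere). Intervals are treated
as closed. When a held-out site is co-located with another, the
retained twin stays in the training set. A fold whose design cannot be
built (e.g. the held-out site carries the only instance of an
environment level) is skipped with a warning; more than 5% skipped
folds is an error.

`compare_models()` reproduces the nine-model design (three estimation
methods on the full covariate set, six Bayesian covariate variants);
`compare_data_sources()` fits on monitors only / tubes only / both and
predicts every site (out-of-subset sites from the subset fit,
in-subset sites by leave-one-out refits); `pcm_baseline()` is the
no-spatial-model reference: log modelled value plus an OLS
roadside-or-kerbside additive adjustment.

## The synthetic generator

No real monitoring data ship with the package; `synthetic_config()` /
`generate_grid()` / `generate_sites()` / `simulate_observations()`
generate data with the structure the analysis assumes:

* **Network composition.** Defaults mirror the reference urban
  network the generator emulates: 230 tubes, 16 monitors, environment
  proportions 142/34/8/60/2 (roadside/kerbside/special/urban
  background/rural). Eight of the monitors are co-located with tubes —
  co-location without a published count; half the monitors is the
  package's one-time choice.
  Tube environments are a multinomial draw; non-co-located monitors
  cycle through the five classes first, emulating deliberate network
  design (and keeping small monitor subsets estimable).
* **Modelled surface.** The exponential of a smooth Gaussian random
  field (sd 0.25, range 2 km) plus a Gaussian urban bump (amplitude 1.1
  on the log scale, radius 2 km) over a rural base of 4.8 ug/m3,
  giving urban-to-rural contrasts and a value range comparable to a
  real 1 km background surface (mean about 7.6 ug/m3). Cells within 2.2 km
  of the synthetic city centre are flagged urban; the real population
  based urban–rural classification is external data and out of scope.
* **Preferential siting.** Site cells are drawn with probability
  proportional to the cell's modelled value, uniform within the cell —
  monitoring networks over-sample polluted places.
* **Observations.** Drawn *exactly* from the model above, with the
  generating spatial effects retained as an attribute so tests can
  check against the truth. Default parameters are the posterior medians
  of the reference full-scale fit ($\sigma^2 = 0.057$, $\nu^2 = 0.232$,
  $\rho = 12.852$ per km, and the fitted coefficient vector).
* **Extent.** The default region is 7 km x 7 km. A real conurbation is
  far larger, but with $\rho = 12.852$ per km the effective range is
  only ~230 m: the extent is chosen once so that (a) the default decay
  grid always brackets the generating $\rho$ (maximum inter-site
  distance below 9.9 km puts the top candidate above 15 per km), and
  (b) preferentially clustered sites sit close enough together that the
  spatial component is genuinely present in — and recoverable from —
  the data. A generator whose spatial signal the sampler could never
  see would make the calibration studies vacuous.

What the generator does **not** emulate: real road-network geometry,
preferential siting driven by regulatory exceedances rather than
modelled values, instrument-specific bias needing co-location
calibration, missing-data patterns, or temporal aggregation error.
Passing tests therefore demonstrate internal correctness and
calibration of the method under its own assumptions, not performance on
real networks.

**Co-location and singularity.** Co-located pairs share exact
coordinates in the site table; before any correlation matrix is formed
a deterministic 1 m jitter separates duplicates (the j-th duplicate
moves 1 m along compass direction $2\pi(j-2)/8$), since
$\exp(-\rho D)$ is singular at duplicated points. One metre is far
below any spacing of scientific interest and keeps every run
reproducible.

**Numerical choices.** Interaction coordinates are centred at the site
centroid and scaled to 10 km units before multiplying (raw metre
coordinates of order $10^5$ would ill-condition the design matrix); the
centring constants are stored and reapplied verbatim at prediction
locations. Concentrations of exactly zero are rejected, not offset.
Constant non-intercept columns (e.g. the source indicator in a
single-source subset) are dropped, and the dropped set is remembered so
prediction rebuilds the identical matrix. Dummy references fall back to
the first present level when the nominal reference is absent from a
training subset.

## Simulation studies and their sizes

Two packaged studies quantify calibration; their problem sizes are the
package's scaled-down defaults, chosen once:

* `nominal_coverage_study()`: 5 replicate networks of 60 sites at the
  reference-fit parameters, LOOCV with 1,500 iterations per fold (500
  burn-in). With the generating and fitting model identical, pooled
  95%-interval coverage should sit near 95%; `scripts/acceptance.R`
  reports it.
* Parameter recovery (in the test suite): 20 replicates at the full
  network size (246 sites), 2,000 retained draws after a 300-iteration
  burn-in, checking that the 95% credible intervals cover the
  generating coefficients and variance parameters at close to their
  nominal rate. Short burn-in suffices here because the chains are
  initialised at the OLS solution and mix quickly at this data size.
* Directional comparisons (in the test suite): 10 replicates of a
  40-site network (30 tubes, 10 monitors), 500-iteration chains,
  checking the orderings expected at full scale — spatial beats
  non-spatial OLS, the fused model beats the adjusted modelled-surface
  baseline, and tubes-only beats monitors-only. These replicates are
  generated on *spatially dominated* data ($\sigma^2 = 0.15$, $\nu^2 =
  0.15$, $\rho = 1$ per km, an effective range of 3 km comparable to
  the network extent): at the reference-fit decay the effective range is
  ~230 m, so a 40-site network contains almost no spatial information
  and the estimation-method comparison would be uninformative noise.
  The data-source comparison uses the interaction spec without the
  environment factor: a 10-monitor subset cannot support five factor
  levels, and both subsets use the same spec so the ordering is
  unaffected.

## Known limitations

* Single-chain inference; no multi-chain convergence machinery.
* Exponential covariance only, isotropic; no Matern or anisotropy.
* The discrete decay grid bounds how well $\rho$ itself can be
  resolved; with short-range fields and sparse networks, $\sigma^2$ and
  $\nu^2$ are only weakly separated (wide, honest intervals — visible
  in the reference fit's own extremely wide $\nu^2$ interval).
* Predictions are background averages at the grid resolution; local
  (roadside) increments are deliberately outside the prediction
  convention.
* LOOCV refits the model per fold; at full scale with long chains this
  is expensive, and the packaged defaults are the scaled-down settings
  above with full-scale settings available through the arguments.
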