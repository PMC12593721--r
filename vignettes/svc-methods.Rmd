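---
title: "Methods: spatially varying productivity-richness models"
author: "svcspde"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially varying productivity-richness models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svcspde)
```

## The scientific problem

Whether vegetation productivity limits species richness — and in what
direction — appears to depend on where you look and on the spatial extent of
the comparison. Instead of binning study areas into coarse distance classes,
this package treats the productivity-species-richness relationship (PSRR) as
a *spatially varying coefficient* (SVC) surface and asks two quantitative
questions: over what geographic distance does the local relationship remain
correlated (the *spatial range*), and where is the local relationship
positive, negative, or statistically indistinguishable from zero?

The observation model for mean estimated richness $S_i$ at survey site $s_i$
with standardized productivity covariate $PM_i$ is

$$S_i = \alpha(s_i) + \beta(s_i)\, PM_i + \varepsilon_i, \qquad
\varepsilon_i \sim N(0, \tau_\varepsilon^{-1}),$$

where $\alpha(\cdot)$ and $\beta(\cdot)$ are independent Gaussian random
fields, each decomposed as a fixed mean level plus a zero-mean Matern field
(smoothness $\nu = 1$). The slope field's range is the quantity of primary
scientific interest: the distance at which PSRR form changes.

## Productivity inputs: dynamic habitat indices

Intra-annual gross primary productivity (GPP) composites are summarized into
the three dynamic habitat indices per pixel and year, then averaged across
years:

* **sum** — annual total (kg C/m^2/year), available energy;
* **minimum** — lowest monthly value (kg C/m^2/month), the intra-annual
  bottleneck;
* **seasonality** — coefficient of variation of the monthly values
  (dimensionless), resource instability.

Design choices a user should know about:

* Composites are assigned to the calendar month containing their start date
  and scaled by `days_in_month / 8` to a monthly total. The source analyses
  say only "monthly average"; this dialect approximately preserves annual
  totals and is isolated inside `aggregate_to_monthly()`.
* The coefficient of variation uses the sample (n−1) standard deviation, and
  a pixel with zero mean GPP gets seasonality 0, not NaN — deserts belong at
  the low end of the seasonality scale, and published seasonality maps span
  a finite range starting at 0.
* Landscape summaries are plain means over raster cells whose *centers* fall
  within a 39.4-km-radius buffer of a route start point (the common zonal-
  statistics membership rule, cheap to verify against brute-force
  enumeration). Covariates are standardized with the sample standard
  deviation; the transform is returned so prediction locations can be
  projected onto the same scale.
* Route retention mirrors the field protocol: a route is kept when
  human-dominated classes (croplands, urban, cropland/natural mosaic) cover
  strictly less than 50% of the buffer, and when the entire buffer lies
  inside the study boundary (distance to the boundary at least the radius,
  ties kept). Categorical aggregation to the working resolution uses the
  majority class per block.

## The SPDE representation

Each Matern field is represented on a triangulated mesh through the
stochastic partial differential equation (SPDE) approach: with piecewise
linear finite elements, lumped mass matrix $C$ and stiffness matrix $G$, the
vector of vertex weights is a Gaussian Markov random field with sparse
precision

$$Q(\rho, \sigma) = \tau^2\left(\kappa^4 C + 2\kappa^2 G + G C^{-1} G\right),
\qquad \kappa = \sqrt{8}/\rho,\quad
\tau^2 = \frac{1}{4\pi\kappa^2\sigma^2},$$

so that the interior marginal variance is $\sigma^2$ and the correlation at
distance $\rho$ is about 0.13. Values at arbitrary locations are barycentric
interpolations of the vertex weights (rows of the projector matrix are
convex weights).

Mesh construction follows the same logic as the reference analysis: survey
points are mesh vertices; filler vertices come from a jittered hexagonal
lattice; triangle edges are refined until none exceeds `max_edge_km`
(default: one tenth of the maximum inter-point distance, the rule that gives
449 km for the continental survey data); and the domain is the nonconvex
hull of the points dilated by `hull_buffer_km` (default `max_edge_km`) so
the Neumann boundary artifacts of the SPDE sit away from the data. Two
implementation details matter for robustness: the filler lattice extends two
cells beyond the domain so that boundary triangles never border vertex-free
space (otherwise arbitrarily long sliver edges appear along the boundary),
and edge-refinement midpoints are nudged toward the nearest data point,
which breaks exact collinearity (a degenerate case for floating-point
incircle tests) and forces boundary-hugging edges to flip inward.

## Priors

* Spatial range: the two-dimensional penalized-complexity (PC) prior with
  survival $P(\rho > r) = 1 - e^{-\lambda/r}$, calibrated by one tail
  statement. Default $P(\rho > 2243\ \mathrm{km}) = 0.5$ — the prior median
  equals half the maximum inter-route distance of the continental survey.
* Marginal SD: exponential PC prior, default $P(\sigma > 1) = 0.5$.
* Noise precision: $\tau_\varepsilon \sim$ Gamma(shape 1, rate $10^{-5}$),
  essentially flat on the log scale.
* Fixed mean levels of the two surfaces: Gaussian with precision $10^{-6}$.

The range prior is deliberately heavy-tailed ($1/r$ survival decay, infinite
mean); when the likelihood is flat in the range direction the posterior
median inherits a long right shelf. This matters for interpreting recovery
experiments (below).

## Inference

The latent vector (two fields plus two fixed effects) is Gaussian given the
five hyperparameters $(\rho_\alpha, \sigma_\alpha, \rho_\beta, \sigma_\beta,
\tau_\varepsilon)$, so it is integrated out analytically; each marginal-
likelihood evaluation is one sparse Cholesky factorization with a reused
symbolic pattern. Two precomputations keep an evaluation at a few
milliseconds: the posterior precision is assembled by pure vector arithmetic
on a fixed sparsity template, and the field log-determinant uses the
identity $\kappa^4 C + 2\kappa^2 G + GC^{-1}G =
C^{1/2}(\kappa^2 I + B)^2 C^{1/2}$ with $B = C^{-1/2} G C^{-1/2}$, whose
eigenvalues are computed once per mesh.

The hyperparameter posterior (log scale) is explored by: Nelder-Mead mode
search (with one restart), a finite-difference Hessian giving a Laplace
approximation, and adaptive importance sampling from a multivariate-t
proposal (df 5, scale inflation 1.4) with up to three re-estimations of the
proposal moments when the effective sample size is below `min_ess`.
Importance draws are systematically resampled to equally weighted
hyperparameter draws; the latent fields are then drawn *exactly* from their
Gaussian conditional at each retained hyperparameter value. Every stochastic
step is driven by one seed through a fixed offset rule, so fits are
bit-reproducible. Failure modes are flagged on the object
(`mode_search_not_converged`, `hessian_not_positive_definite`,
`low_importance_ess`), never silent; Cholesky indefiniteness during
exploration is treated as zero posterior mass, and a jitter ladder
($10^{-10}$ to $10^{-6}$) backs the standalone precision builders.

Numerical conventions: quantiles are type-7; classification of a cell whose
credible interval touches zero exactly is "non-existent" (inclusive
overlap, the conservative reading of "excludes zero"); boxplot outliers use
the 1.5 IQR convention and stay in the counts.

## Form analysis

`build_form_grid()` projects the slope posterior onto a regular grid
(default 40 km, matching the landscape buffer footprint) and labels each
cell positive / negative / non-existent by whether the 95% credible interval
excludes zero; `summarize_by_form()` classifies measure-raster cell centers
by direct projection (not nearest-grid-cell lookup; both the direct and the
grid route are available) and returns five-number summaries per form. No
multiplicity correction is applied across cells, matching the reference
analysis.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes: a seasonal GPP cube whose noiseless series is an exactly known
sinusoid with a west-east gradient multiplier (so the habitat indices have
closed forms), clipped at the physical floor of zero; a clustered land-cover
mosaic with human-dominated classes; uniformly placed routes; and richness
generated from the SVC equation with known Matern surfaces. Defaults are the
study conditions used throughout the tests: a 4,500 x 3,000 km domain, 500
routes, 4 years of monthly composites, intercept surface 56 +/- 10 species
at a 2,000 km range, slope surface 2 +/- 0.5 at 1,500 km, and residual noise
of 2 species — the scale of estimation noise plausible for a multi-year
averaged richness estimate, and small enough that the spatial structure
targeted by the analysis is resolvable, as it evidently was in the
motivating data. Route placement is uniform (road-stratified placement is
not emulated), noise is homoscedastic (the model's own assumption), and
coordinates are planar km — geodesy is out of scope.

What passing tests on these data do *not* show: robustness to detection
heterogeneity, non-Gaussian richness errors, covariate measurement error, or
meshes on strongly anisotropic domains.

## Problem sizes and what the checks mean

The packaged verification suite uses problem sizes chosen to exercise every
code path at desk scale: oracle agreement between the sparse SPDE likelihood
and a dense Matern GP likelihood at n = 60 sites on a fine mesh (within 2%);
parameter recovery over 20 seeded replicates at n = 500 on the 4,500-km
domain (95% interval covers the generating range in at least 80% of
replicates, posterior median within a factor of two in at least 80%);
a degenerate-field limit that reproduces ordinary least squares to 1e-3; and
form-classification checks on strong-signal and null simulations. The
recovery experiment deserves one caveat: with a 0.5-SD slope field over
this domain the range likelihood is intrinsically broad, and the
heavy-tailed PC prior places the posterior median's sampling distribution
close to the factor-of-two boundary; the coverage clause is comfortably met,
the median clause is the tighter of the two.

## Known limitations

* One covariate per model; Gaussian likelihood only; stationary isotropic
  Matern with $\nu = 1$ fixed (the standard SPDE choice).
* The inference engine is a Laplace-plus-importance-resampling
  approximation; very flat hyperparameter posteriors yield wide but honest
  credible intervals and a flagged effective sample size when exploration
  is hard.
* Whether the intercept and slope fields share a range is not identifiable
  from the reference publication; they are modeled separately, and reported
  ranges refer to the slope field.
* Rasters are plain in-memory matrices with a text interchange format;
  continental 1-km grids should be tiled or downsampled by the caller.
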