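# svcspde

Tools for quantifying how productivity–species-richness relationships
(PSRR) change with geographic scale, for macroecologists working with
survey-route richness data (e.g. breeding-bird monitoring) and raster
productivity time series.

The core question: over what distance does the local association between a
productivity measure and species richness stay correlated, and where is
that association positive, negative, or statistically indistinguishable
from zero? The package answers it with a Bayesian spatially varying
coefficient (SVC) model

> S_i = α(s_i) + β(s_i)·PM_i + ε_i,  ε_i ~ N(0, τ_ε⁻¹)

where S_i is mean estimated richness at site s_i, PM_i a standardized
productivity measure, and α(·), β(·) are Matérn Gaussian fields (ν = 1)
represented as finite-element Gaussian Markov random fields through the
SPDE approach, with penalized-complexity priors
P(range > 2,243 km) = 0.5 and P(σ > 1) = 0.5, and τ_ε ~ Gamma(1, 10⁻⁵).
The posterior of the slope field's spatial range is the geographic scale at
which PSRR form changes; mapping where the 95% credible interval of β(s)
excludes zero classifies the form (positive / negative / non-existent).

What's inside:

* **Dynamic habitat indices** — annual sum, minimum, and seasonality
  (coefficient of variation) of monthly GPP, from intra-annual composite
  stacks, with landscape buffer means (39.4-km radius) and standardization.
* **Route retention filters** — human-dominated land cover < 50% of the
  landscape, and whole-buffer containment in the study boundary.
* **SVC engine** — mesh construction (Delaunay refinement over a nonconvex
  hull of the sites, every edge bounded), sparse SPDE precision matrices,
  marginal-likelihood-based inference (Laplace approximation plus adaptive
  importance resampling; exact Gaussian draws of the latent fields),
  posterior range summaries, coefficient-surface prediction, residual
  variogram diagnostics with permutation envelopes.
* **Form analysis** — credible-interval classification on a regular grid
  (40 km by default) and measure-distribution summaries by form.
* **Synthetic-data generator** — seeded end-to-end emulation of the study
  design (seasonal GPP with closed-form indices, clustered land cover,
  routes, richness from known SVC surfaces), so everything is testable
  without downloads.

## Worked example

A complete synthetic study on a 4,500 × 3,000 km domain — simulate inputs,
filter routes, fit the sum-productivity model, summarize the scale, map the
form:

```r
library(svcspde)

cfg <- sim_config(gpp_params = list(base_mean = 0.37, seasonal_amplitude = 0.25,
                                    gradient_low = 0.3, gradient_high = 1.7,
                                    pixel_noise_sd = 0.2),
                  seed = 7)
ds  <- simulate_dataset(cfg, measure = "sum")

routes <- human_cover_filter(ds$routes, ds$landcover,
                             human_classes = c(1, 2, 3))
boundary <- cbind(c(0, 4500, 4500, 0), c(0, 0, 3000, 3000))
routes <- containment_filter(routes, boundary)
sum(routes$retained)
#> [1] 300

fit <- fit_svc(richness ~ pm_std, routes, control = svc_control(seed = 1))
summary(fit)
#> SVC model: 300 sites, 497 mesh vertices
#>
#> Hyperparameters (posterior quantiles):
#>                 q2.5   median       q97.5
#> range_alpha 1142.842 1534.164    2199.761
#> sd_alpha       6.686    8.407      11.223
#> range_beta   511.846 3061.949 1301458.967
#> sd_beta        0.091    0.680       3.320
#> noise_prec     0.188    0.258       0.344
#> noise_sd       1.705    1.967       2.307
#> ...

round(posterior_range_summary(fit, "beta"))
#>    q2.5  median   q97.5
#>     512    3062 1301459

fg <- build_form_grid(fit, resolution_km = 40)
table(fg$form)
#>     negative non-existent     positive
#>            0         8030            0
```

Reading the output: 200 of the 500 simulated routes sit in human-dominated
or edge landscapes and are dropped. The intercept surface is recovered well
(generating values: mean 56, SD 10 at a 2,000-km range; posterior medians
57.6, 8.4, 1,534 km) and the residual SD matches the generating 2 species.
The slope-field range posterior is broad (median ≈ 3,100 km) — with a
spatially smooth covariate the local slope is weakly identified, and the
heavy-tailed range prior leaves a long upper tail. Accordingly no 40-km
cell's 95% interval excludes zero: the form map is honest about that
uncertainty, exactly as large non-existent regions appear in real
continental analyses. Sharper slope signals (see the strong-signal checks
in `tests/testthat/test-acceptance.R`) produce almost entirely positive
maps.

`run_pipeline(pipeline_config(sim = cfg, measures = "sum", seed = 1))`
wraps the same steps (per measure: sum / minimum / seasonality) and writes
routes, range summaries, form grids, boxplot statistics, and a JSON
manifest with the seed and a config checksum for bit-identical reruns.

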