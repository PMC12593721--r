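test_that("the fitted object exposes ordered, reproducible posteriors", {
  sf <- small_fit_cache()
  fit <- sf$fit
  rs <- posterior_range_summary(fit, "beta")
  expect_true(rs["q2.5"] <= rs["median"] && rs["median"] <= rs["q97.5"])
  ra <- posterior_range_summary(fit, "alpha")
  expect_true(all(diff(ra) >= 0))
  # stored seed reproduces summaries bit-exactly
  fit2 <- fit_svc(richness ~ pm_std, sf$ds$routes, mesh = sf$mesh,
                  control = svc_control(seed = 5, n_importance = 150,
                                        n_draws = 150))
  expect_identical(fit$theta_draws, fit2$theta_draws)
  expect_identical(fit$latent_draws, fit2$latent_draws)
  expect_identical(posterior_range_summary(fit, "beta"),
                   posterior_range_summary(fit2, "beta"))
  # methods return sane shapes
  expect_length(fitted(fit), fit$n_obs)
  expect_length(residuals(fit), fit$n_obs)
  expect_named(coef(fit), c("mean_intercept", "mean_slope"))
  s <- summary(fit)
  expect_true(all(s$hyper[, "q2.5"] <= s$hyper[, "q97.5"]))
  sim <- simulate(fit, nsim = 3, seed = 2)
  expect_equal(dim(sim), c(fit$n_obs, 3L))
})

test_that("a degenerate posterior has identical quantiles", {
  sf <- small_fit_cache()
  fitc <- fit_svc(richness ~ pm_std, sf$ds$routes, mesh = sf$mesh,
                  control = svc_control(seed = 3, n_draws = 40),
                  fix_hyper = list(range_alpha = 900, sd_alpha = 8,
                                   range_beta = 800, sd_beta = 0.8,
                                   noise_prec = 0.25))
  rs <- posterior_range_summary(fitc, "beta")
  expect_equal(unname(rs["q2.5"]), unname(rs["median"]))
  expect_equal(unname(rs["median"]), unname(rs["q97.5"]))
})

test_that("the degenerate-field limit reduces to ordinary least squares", {
  sf <- small_fit_cache()
  routes <- sf$ds$routes
  fit0 <- fit_svc(richness ~ pm_std, routes, mesh = sf$mesh,
                  control = svc_control(seed = 9, n_draws = 200),
                  fix_hyper = list(range_alpha = 900, sd_alpha = 1e-4,
                                   range_beta = 900, sd_beta = 1e-4,
                                   noise_prec = 1))
  ols <- coef(lm(richness ~ pm_std, data = routes))
  # exact conditional posterior means (no Monte-Carlo error at fixed
  # hyperparameters): the vanished fields leave Bayesian linear regression
  # under an essentially flat prior
  nv <- fit0$n_vertices
  mean_slope <- fit0$latent_mean[2 * nv + 2] +
    mean(as.vector(fit0$A %*% fit0$latent_mean[nv + seq_len(nv)]))
  mean_int <- fit0$latent_mean[2 * nv + 1] +
    mean(as.vector(fit0$A %*% fit0$latent_mean[seq_len(nv)]))
  expect_lt(abs(mean_slope - ols[2]), 1e-3)
  expect_lt(abs(mean_int - ols[1]), 1e-3)
})

test_that("noiseless constant-slope data concentrates the mean slope at truth", {
  # degenerate generating fields: richness is a fixed linear function of
  # the covariate plus tiny noise, so the mean-slope posterior must
  # concentrate at the constant b = 2
  cfg <- sim_config(domain_extent = c(0, 2500, 0, 2500), n_routes = 500,
                    intercept_field_params = list(mean_level = 50,
                                                  range_km = 1000,
                                                  marginal_sd = 0),
                    slope_field_params = list(mean_level = 2,
                                              range_km = 1000,
                                              marginal_sd = 0),
                    noise_sd = 0.1, seed = 31)
  pm <- svcspde:::with_preserved_seed(17, rnorm(500))
  ds <- simulate_routes_and_richness(cfg, pm_values = pm)
  fit <- fit_svc(richness ~ pm_std, ds$routes,
                 control = svc_control(seed = 1, n_importance = 150,
                                       n_draws = 150))
  # per-draw spatial mean slope; its posterior median concentrates at truth
  fx <- svcspde:::latent_fixed(fit)
  bsite <- as.matrix(fit$A %*% svcspde:::latent_beta(fit)) +
    rep(1, fit$n_obs) %o% fx[2, ]
  expect_lt(abs(median(colMeans(bsite)) - 2), 0.01)
})

test_that("predictions interpolate the latent fields through convex weights", {
  sf <- small_fit_cache()
  fit <- sf$fit
  # at a mesh vertex the prediction equals that vertex's posterior
  vtx <- fit$mesh$point_index[3]
  vloc <- fit$mesh$loc[vtx, , drop = FALSE]
  pred <- predict(fit, vloc)
  fx <- svcspde:::latent_fixed(fit)
  bnode <- svcspde:::latent_beta(fit)[vtx, ] + fx[2, ]
  expect_equal(pred$beta_median, median(bnode), tolerance = 1e-9)
  expect_equal(pred$beta_q2.5, unname(quantile(bnode, 0.025)),
               tolerance = 1e-9)
  # at a triangle centroid every draw lies within the vertex draws' hull
  tt <- fit$mesh$tt[5, ]
  cen <- matrix(colMeans(fit$mesh$loc[tt, ]), 1)
  Ap <- mesh_projector(fit$mesh, cen)
  bd <- as.matrix(Ap %*% svcspde:::latent_beta(fit))
  vtx_draws <- svcspde:::latent_beta(fit)[tt, ]
  expect_true(all(bd >= apply(vtx_draws, 2, min) - 1e-9))
  expect_true(all(bd <= apply(vtx_draws, 2, max) + 1e-9))
  # quantile ordering holds pointwise on a grid
  grid <- cbind(runif(30, 500, 1500), runif(30, 500, 1500))
  pg <- predict_coefficients(fit, grid)
  expect_true(all(pg$beta_q2.5 <= pg$beta_median + 1e-12))
  expect_true(all(pg$beta_median <= pg$beta_q97.5 + 1e-12))
  expect_error(predict(fit, matrix(c(1e6, 1e6), 1)), "outside")
})

test_that("prediction error against the truth surface shrinks with sample size", {
  grid <- as.matrix(expand.grid(x = seq(500, 2000, by = 250),
                                y = seq(500, 2000, by = 250)))
  mae <- sapply(c(100, 400), function(n) {
    cfg <- sim_config(domain_extent = c(0, 2500, 0, 2500), n_routes = n,
                      slope_field_params = list(mean_level = 2,
                                                range_km = 1000,
                                                marginal_sd = 1),
                      noise_sd = 1, seed = 61)
    pm <- svcspde:::with_preserved_seed(62, rnorm(n))
    ds <- simulate_routes_and_richness(cfg, pm_values = pm,
                                       extra_truth_locations = grid)
    fit <- fit_svc(richness ~ pm_std, ds$routes,
                   control = svc_control(seed = 2, n_importance = 120,
                                         n_draws = 120))
    pred <- predict_coefficients(fit, grid)
    mean(abs(pred$beta_median - ds$truth$extra$beta))
  })
  expect_lt(mae[2], mae[1])
})

test_that("marginal log-likelihood matches the dense Matern GP oracle", {
  set.seed(42)
  n <- 40
  pts <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
  mesh <- build_mesh(pts, max_edge_km = 110, hull_buffer_km = 550)
  pm <- rnorm(n)
  al <- simulate_gaussian_field(pts, 550, 1.1, seed = 8)
  be <- simulate_gaussian_field(pts, 450, 0.7, seed = 9)
  y <- al + be * pm + rnorm(n, 0, 1.5)
  ll_spde <- svc_marginal_loglik(y, pm, pts, mesh, 550, 1.1, 450, 0.7,
                                 1 / 1.5^2)
  ll_dense <- dense_gp_loglik(y, pm, pts, 550, 1.1, 450, 0.7, 1 / 1.5^2)
  expect_lt(abs(ll_spde - ll_dense) / abs(ll_dense), 0.02)
})

test_that("residual diagnostics account for every close pair and flag structure", {
  sf <- small_fit_cache()
  dg <- residual_diagnostics(sf$fit, n_bins = 10, seed = 4)
  D <- as.matrix(dist(sf$fit$loc))
  n_close <- sum(upper.tri(D) & D <= dg$max_lag_km)
  expect_equal(sum(dg$variogram$n_pairs), n_close)
  expect_true(all(c("residuals", "fitted", "variogram") %in% names(dg)))
  # permuting residuals over locations stays inside its own envelope most
  # of the time: check the fitted model's variogram has no gross structure
  inside <- with(dg$variogram,
                 semivariance >= env_lo & semivariance <= env_hi)
  expect_gte(mean(inside), 0.7)
})

test_that("a shuffled covariate yields a null slope field almost everywhere", {
  sf <- small_fit_cache()
  routes <- sf$ds$routes
  routes$pm_std <- svcspde:::with_preserved_seed(123,
                                                 sample(routes$pm_std))
  fit <- fit_svc(richness ~ pm_std, routes, mesh = sf$mesh,
                 control = svc_control(seed = 6, n_importance = 150,
                                       n_draws = 150))
  grid <- as.matrix(expand.grid(x = seq(200, 1800, by = 200),
                                y = seq(200, 1800, by = 200)))
  pred <- predict_coefficients(fit, grid)
  covers0 <- pred$beta_q2.5 <= 0 & pred$beta_q97.5 >= 0
  expect_gte(mean(covers0), 0.9)
})
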