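test_that("configuration validation catches inconsistent settings", {
  expect_error(sim_config(n_routes = 2))
  expect_error(sim_config(domain_extent = c(0, 0, 0, 10)))
  expect_error(sim_config(noise_sd = -1))
  expect_s3_class(sim_config(), "sim_config")
})

test_that("the GPP stack follows its stored sinusoid and is reproducible", {
  cfg <- sim_config(domain_extent = c(0, 500, 0, 400),
                    grid_resolution_km = 100, n_routes = 5,
                    gpp_params = list(base_mean = 0.5, seasonal_amplitude = 0,
                                      gradient_low = 1, gradient_high = 1,
                                      pixel_noise_sd = 0), seed = 2)
  st <- simulate_gpp_stack(cfg)
  # constant series: every pixel-month is 0.5
  expect_true(all(st$values == 0.5))
  dhi <- compute_dhi(list(aggregate_to_monthly(st, 2001)))
  expect_equal(unique(as.vector(dhi$sum$values)), 6.0)
  expect_equal(unique(as.vector(dhi$minimum$values)), 0.5)
  expect_equal(unique(as.vector(dhi$seasonality$values)), 0)
  # noiseless sinusoid: min equals base - amplitude clipped at 0, evaluated
  # on the stored month grid
  cfg2 <- sim_config(domain_extent = c(0, 500, 0, 400),
                     grid_resolution_km = 100, n_routes = 5,
                     gpp_params = list(base_mean = 0.3,
                                       seasonal_amplitude = 0.4,
                                       gradient_low = 1, gradient_high = 1,
                                       pixel_noise_sd = 0), seed = 2)
  st2 <- simulate_gpp_stack(cfg2)
  m2 <- aggregate_to_monthly(st2, 2001)
  expect_equal(min(m2[, 1, 1]), min(gpp_true_monthly(cfg2, 1)))
  expect_gte(min(st2$values), 0)
  # same seed: bit-identical stacks
  cfg3 <- sim_config(seed = 77, n_routes = 5,
                     domain_extent = c(0, 500, 0, 500),
                     grid_resolution_km = 100)
  expect_identical(simulate_gpp_stack(cfg3)$values,
                   simulate_gpp_stack(cfg3)$values)
})

test_that("richness follows the SVC equation exactly in degenerate settings", {
  # all field sds zero, no noise: richness = mean intercept + mean slope * pm
  cfg <- sim_config(domain_extent = c(0, 1000, 0, 1000), n_routes = 40,
                    intercept_field_params = list(mean_level = 50,
                                                  range_km = 500,
                                                  marginal_sd = 0),
                    slope_field_params = list(mean_level = 2, range_km = 500,
                                              marginal_sd = 0),
                    noise_sd = 0, seed = 3)
  ds <- simulate_routes_and_richness(cfg, pm_values = rep(1.5, 40))
  expect_equal(ds$routes$richness, rep(53, 40))
  # zero slope and noise: richness equals the intercept surface
  cfg2 <- sim_config(domain_extent = c(0, 1000, 0, 1000), n_routes = 40,
                     intercept_field_params = list(mean_level = 50,
                                                   range_km = 500,
                                                   marginal_sd = 6),
                     slope_field_params = list(mean_level = 0,
                                               range_km = 500,
                                               marginal_sd = 0),
                     noise_sd = 0, seed = 4)
  pm <- rnorm(40)
  ds2 <- simulate_routes_and_richness(cfg2, pm_values = pm)
  expect_equal(ds2$routes$richness, ds2$truth$alpha)
  # full stochastic config is seed-reproducible
  cfg3 <- sim_config(n_routes = 30, domain_extent = c(0, 2000, 0, 2000),
                     seed = 11)
  a <- simulate_routes_and_richness(cfg3, pm_values = seq(-1, 1,
                                                          length.out = 30))
  b <- simulate_routes_and_richness(cfg3, pm_values = seq(-1, 1,
                                                          length.out = 30))
  expect_identical(a$routes$richness, b$routes$richness)
  expect_identical(a$truth$beta, b$truth$beta)
})

test_that("richness residuals obey the law of large numbers", {
  # fields degenerate so the truth signal is exact; n = 5,000 draws
  n <- 5000
  cfg <- sim_config(domain_extent = c(0, 1000, 0, 1000), n_routes = n,
                    intercept_field_params = list(mean_level = 56,
                                                  range_km = 500,
                                                  marginal_sd = 0),
                    slope_field_params = list(mean_level = 2, range_km = 500,
                                              marginal_sd = 0),
                    noise_sd = 2, seed = 5)
  pm <- rep(0, n)
  ds <- simulate_routes_and_richness(cfg, pm_values = pm)
  resid <- ds$routes$richness - ds$truth$alpha
  se_mean <- 2 / sqrt(n)
  expect_lt(abs(mean(resid)), 3 * se_mean)
  se_sd <- 2 / sqrt(2 * (n - 1))
  expect_lt(abs(sd(resid) - 2), 3 * se_sd)
})

test_that("the end-to-end generator wires productivity into richness", {
  cfg <- sim_config(domain_extent = c(0, 900, 0, 700),
                    grid_resolution_km = 30, n_routes = 25,
                    human_cover_range_km = 200, seed = 21)
  ds <- simulate_dataset(cfg, measure = "sum")
  expect_s3_class(ds$routes, "route_table")
  expect_equal(nrow(ds$routes), 25)
  # pm_std is the standardized buffer mean of the sum band
  i <- 7
  bm <- buffer_mean(ds$dhi$sum, c(ds$routes$x_km[i], ds$routes$y_km[i]),
                    39.4)
  expect_equal(ds$routes$pm_raw[i], bm)
  expect_equal(ds$routes$pm_std[i],
               (bm - ds$pm_transform$mean) / ds$pm_transform$sd)
  # richness reproduces the SVC equation from the stored truth
  expect_equal(ds$routes$richness,
               ds$truth$alpha + ds$truth$beta * ds$routes$pm_std +
                 ds$truth$noise)
  # land cover is categorical with the declared codes
  expect_true(all(ds$landcover$values %in% c(1, 2, 3, 10)))
  # plain-text export round-trips the routes
  dir <- tempfile("ds_")
  write_dataset(ds, dir)
  rt <- read_route_csv(file.path(dir, "routes.csv"))
  expect_equal(rt$richness, ds$routes$richness)
  expect_true(file.exists(file.path(dir, "truth.json")))
  unlink(dir, recursive = TRUE)
})
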