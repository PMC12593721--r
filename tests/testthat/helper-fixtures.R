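# shared fixtures, built once per test run

# small synthetic study and fitted model reused by several test files
small_fit_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(domain_extent = c(0, 2000, 0, 2000), n_routes = 120,
                        intercept_field_params = list(mean_level = 56,
                                                      range_km = 900,
                                                      marginal_sd = 8),
                        slope_field_params = list(mean_level = 2,
                                                  range_km = 800,
                                                  marginal_sd = 0.8),
                        noise_sd = 2, seed = 42)
      pm <- svcspde:::with_preserved_seed(99, rnorm(120))
      ds <- simulate_routes_and_richness(cfg, pm_values = pm)
      mesh <- build_mesh(cbind(ds$routes$x_km, ds$routes$y_km),
                         max_edge_km = 260)
      fit <- fit_svc(richness ~ pm_std, ds$routes, mesh = mesh,
                     control = svc_control(seed = 5, n_importance = 150,
                                           n_draws = 150))
      cache <<- list(cfg = cfg, ds = ds, mesh = mesh, fit = fit)
    }
    cache
  }
})

# brute-force buffer mean: loop over every cell center
brute_buffer_mean <- function(raster, point, radius_km) {
  cc <- cell_centers(raster)
  tot <- 0; n <- 0
  for (i in seq_along(cc$y)) for (j in seq_along(cc$x)) {
    if ((cc$x[j] - point[1])^2 + (cc$y[i] - point[2])^2 <= radius_km^2 &&
        !is.na(raster$values[i, j])) {
      tot <- tot + raster$values[i, j]; n <- n + 1
    }
  }
  if (n == 0) NA_real_ else tot / n
}

# dense Matern Gaussian-process log-likelihood of the SVC model: the
# independent oracle for the sparse SPDE-GMRF path
dense_gp_loglik <- function(y, pm, loc, range_alpha, sd_alpha, range_beta,
                            sd_beta, noise_prec) {
  n <- length(y)
  D <- as.matrix(stats::dist(loc))
  Sig <- sd_alpha^2 * matern_correlation(D, range_alpha) +
    outer(pm, pm) * (sd_beta^2 * matern_correlation(D, range_beta)) +
    diag(n) / noise_prec
  ch <- chol(Sig)
  -0.5 * n * log(2 * pi) - sum(log(diag(ch))) -
    0.5 * sum(backsolve(ch, y, transpose = TRUE)^2)
}
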