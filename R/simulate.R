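#' Configuration for the synthetic productivity-richness generator
#'
#' Defines a seeded synthetic study with the statistical structure the
#' analysis assumes: seasonal GPP fields with a west-east spatial gradient
#' in mean, amplitude and minimum; a land-cover mosaic with clustered
#' human-dominated classes; uniformly placed survey routes; and richness
#' generated from the spatially-varying-coefficient equation
#' \eqn{S_i = \alpha(s_i) + \beta(s_i) PM_i + \varepsilon_i} with known
#' Matern intercept/slope surfaces and Gaussian noise.
#'
#' Defaults emulate a continental study: a 4,500 x 3,000 km domain, 500
#' routes, four years of monthly composites, an intercept surface around 56
#' species with 10-species spatial variation at a 2,000 km range, a slope
#' surface of mean 2 species per productivity SD varying by 0.5 at a
#' 1,500 km range, and 2 species of residual noise (the scale of estimation
#' noise expected of a multi-year averaged richness estimate, small enough
#' that the spatial structure the analysis targets remains resolvable).
#'
#' @param domain_extent Numeric (x_min, x_max, y_min, y_max) in km.
#' @param n_routes Number of survey routes (>= 3).
#' @param grid_resolution_km Raster cell size for simulated GPP/land cover.
#' @param n_months Months per year in the productivity series (default 12).
#' @param n_years Years simulated (default 4).
#' @param intercept_field_params List(mean_level, range_km, marginal_sd) for
#'   the spatially varying intercept (species units).
#' @param slope_field_params Same for the spatially varying slope
#'   (species per standardized-productivity unit).
#' @param noise_sd Residual richness SD (species).
#' @param gpp_params List(base_mean, seasonal_amplitude, gradient_low,
#'   gradient_high, pixel_noise_sd): monthly GPP at a pixel with gradient
#'   multiplier g is \code{max(0, g*(base_mean + seasonal_amplitude *
#'   sin(2*pi*month/12)) + noise)}, kg C/m^2/month; g ramps linearly
#'   west to east from gradient_low to gradient_high.
#' @param human_cover_mean Expected fraction of human-dominated land cover.
#' @param human_cover_range_km Clustering range of the land-cover mosaic.
#' @param seed Integer master seed; all sub-streams derive from it.
#' @return Validated list of class \code{sim_config}.
#' @export
sim_config <- function(domain_extent = c(0, 4500, 0, 3000),
                       n_routes = 500,
                       grid_resolution_km = 50,
                       n_months = 12,
                       n_years = 4,
                       intercept_field_params = list(mean_level = 56,
                                                     range_km = 2000,
                                                     marginal_sd = 10),
                       slope_field_params = list(mean_level = 2,
                                                 range_km = 1500,
                                                 marginal_sd = 0.5),
                       noise_sd = 2,
                       gpp_params = list(base_mean = 0.37,
                                         seasonal_amplitude = 0.25,
                                         gradient_low = 0.3,
                                         gradient_high = 1.7,
                                         pixel_noise_sd = 0.03),
                       human_cover_mean = 0.2,
                       human_cover_range_km = 300,
                       seed = 1L) {
  cfg <- list(domain_extent = as.numeric(domain_extent), n_routes = n_routes,
              grid_resolution_km = grid_resolution_km, n_months = n_months,
              n_years = n_years,
              intercept_field_params = intercept_field_params,
              slope_field_params = slope_field_params, noise_sd = noise_sd,
              gpp_params = gpp_params, human_cover_mean = human_cover_mean,
              human_cover_range_km = human_cover_range_km,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(length(domain_extent) == 4L,
              domain_extent[2] > domain_extent[1],
              domain_extent[4] > domain_extent[3],
              n_routes >= 3, grid_resolution_km > 0,
              n_months >= 1, n_years >= 1, n_months * n_years >= 2,
              intercept_field_params$range_km > 0,
              slope_field_params$range_km > 0,
              intercept_field_params$marginal_sd >= 0,
              slope_field_params$marginal_sd >= 0,
              noise_sd >= 0, gpp_params$pixel_noise_sd >= 0,
              human_cover_mean >= 0, human_cover_mean <= 1)
  })
  structure(cfg, class = "sim_config")
}

# deterministic sub-stream seeds from the master seed; the offsets are fixed
# so each stage is independently reproducible from (seed, stage)
sub_seed <- function(seed, stage) {
  (as.integer(seed) + 777007L * as.integer(stage)) %% 2147483647L
}

#' Draw a zero-mean Gaussian field with Matern correlation at given points
#'
#' Dense simulation: builds the Matern covariance at the (deduplicated)
#' points, factorizes with a jitter ladder if needed, and returns one seeded
#' draw. Coincident points receive identical values exactly; a zero
#' \code{marginal_sd} returns zeros.
#'
#' @param points n x 2 coordinate matrix (km).
#' @param range_km Spatial range (km), positive.
#' @param marginal_sd Marginal standard deviation (>= 0).
#' @param nu Matern smoothness (default 1).
#' @param seed Integer seed.
#' @return Numeric vector of field values, one per input point.
#' @export
simulate_gaussian_field <- function(points, range_km, marginal_sd, nu = 1,
                                    seed = 1L) {
  points <- matrix(as.matrix(points), ncol = 2)
  stopifnot(nrow(points) >= 1L, range_km > 0, marginal_sd >= 0)
  if (marginal_sd == 0) return(numeric(nrow(points)))
  dd <- dedupe_points(points, cutoff = 1e-9 * max(range_km, 1))
  u <- points[dd$keep, , drop = FALSE]
  D <- as.matrix(stats::dist(u))
  R <- matern_correlation(D, range_km, nu)
  dim(R) <- dim(D)
  L <- NULL
  jit <- 0
  for (j in c(0, 10^seq(-10, -6))) {
    L <- tryCatch(chol(R + diag(j, nrow(R))), error = function(e) NULL)
    if (!is.null(L)) { jit <- j; break }
  }
  if (is.null(L))
    stop("Matern covariance not positive definite after jitter up to 1e-6")
  z <- with_preserved_seed(seed, stats::rnorm(nrow(u)))
  vals <- marginal_sd * as.vector(crossprod(L, z))
  vals[dd$map]
}

#' Simulate a seasonal GPP raster stack
#'
#' Monthly composites over \code{n_years} years on the configured grid. The
#' noiseless series at a pixel with gradient multiplier g is
#' \code{g * (base_mean + seasonal_amplitude * sin(2*pi*month/12))},
#' clipped at zero after adding pixel noise (GPP has a physical floor of 0).
#'
#' @param config A [sim_config()].
#' @return A [prod_stack()] flagged as monthly, plus attribute
#'   \code{gradient} (the per-column multiplier g).
#' @export
simulate_gpp_stack <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ext <- config$domain_extent
  res <- config$grid_resolution_km
  nc <- max(2L, ceiling((ext[2] - ext[1]) / res))
  nr <- max(2L, ceiling((ext[4] - ext[3]) / res))
  gp <- config$gpp_params
  xc <- ext[1] + (seq_len(nc) - 0.5) * res
  g <- gp$gradient_low + (gp$gradient_high - gp$gradient_low) *
       (xc - ext[1]) / (ext[2] - ext[1])
  nt <- config$n_months * config$n_years
  months <- rep(seq_len(config$n_months), config$n_years)
  vals <- array(NA_real_, c(nt, nr, nc))
  noise <- if (gp$pixel_noise_sd > 0)
    with_preserved_seed(sub_seed(config$seed, 1L),
                        stats::rnorm(nt * nr * nc, 0, gp$pixel_noise_sd))
  else 0
  noise <- array(noise, c(nt, nr, nc))
  for (t in seq_len(nt)) {
    base <- gp$base_mean + gp$seasonal_amplitude *
            sin(2 * pi * months[t] / 12)
    vals[t, , ] <- pmax(0, rep(g * base, each = nr) + noise[t, , ])
  }
  dates <- as.Date(paste(2000 + rep(seq_len(config$n_years),
                                    each = config$n_months),
                         rep(seq_len(config$n_months), config$n_years),
                         1, sep = "-"))
  st <- prod_stack(vals, dates, origin = c(ext[1], ext[3]), res_km = res,
                   composite_days = "monthly")
  attr(st, "gradient") <- g
  st
}

#' Noiseless monthly GPP series implied by a configuration
#'
#' Closed-form counterpart of [simulate_gpp_stack()] for a pixel with
#' gradient multiplier \code{g_value}; used to check the dynamic habitat
#' indices against analytic values.
#'
#' @param config A [sim_config()].
#' @param g_value Gradient multiplier at the pixel.
#' @return Numeric vector of 12 monthly values.
#' @export
gpp_true_monthly <- function(config, g_value) {
  gp <- config$gpp_params
  pmax(0, g_value * (gp$base_mean + gp$seasonal_amplitude *
                     sin(2 * pi * seq_len(12) / 12)))
}

#' Simulate a clustered categorical land-cover raster
#'
#' Class codes: 1 cropland, 2 urban, 3 cropland/natural mosaic (the
#' human-dominated set), 10 natural. Human cover is spatially clustered via
#' a Matern field thresholded to match \code{human_cover_mean} on average.
#'
#' @param config A [sim_config()].
#' @return Categorical \code{grid_raster} of class codes.
#' @export
simulate_landcover <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ext <- config$domain_extent
  res <- config$grid_resolution_km
  nc <- max(2L, ceiling((ext[2] - ext[1]) / res))
  nr <- max(2L, ceiling((ext[4] - ext[3]) / res))
  xc <- ext[1] + (seq_len(nc) - 0.5) * res
  yc <- ext[3] + (seq_len(nr) - 0.5) * res
  pts <- cbind(rep(xc, each = nr), rep(yc, nc))
  # simulate on a thinned grid then bilinear-free nearest lookup to stay cheap
  u <- simulate_gaussian_field(pts, config$human_cover_range_km, 1,
                               seed = sub_seed(config$seed, 2L))
  p <- stats::plogis(stats::qlogis(max(1e-6, min(1 - 1e-6,
                                                 config$human_cover_mean))) +
                     1.6 * u)
  draw <- with_preserved_seed(sub_seed(config$seed, 5L),
                              stats::runif(length(p)))
  human <- draw < p
  cls <- with_preserved_seed(sub_seed(config$seed, 6L),
                             sample(c(1, 2, 3), length(p), replace = TRUE,
                                    prob = c(0.6, 0.1, 0.3)))
  codes <- ifelse(human, cls, 10)
  grid_raster(matrix(codes, nrow = nr, ncol = nc),
              origin = c(ext[1], ext[3]), res_km = res)
}

#' Seeded uniform route start points over the domain
#'
#' Locations are drawn uniformly over the domain inset by \code{inset_km}
#' from each edge, so landscape buffers stay inside simulated rasters.
#'
#' @param config A [sim_config()].
#' @param inset_km Edge inset (default 0).
#' @return n_routes x 2 matrix of (x_km, y_km).
#' @export
simulate_route_locations <- function(config, inset_km = 0) {
  ext <- config$domain_extent
  stopifnot(ext[2] - ext[1] > 2 * inset_km, ext[4] - ext[3] > 2 * inset_km)
  with_preserved_seed(sub_seed(config$seed, 3L), {
    cbind(stats::runif(config$n_routes, ext[1] + inset_km, ext[2] - inset_km),
          stats::runif(config$n_routes, ext[3] + inset_km, ext[4] - inset_km))
  })
}

#' Generate routes and richness from the SVC model equation
#'
#' Draws route locations, evaluates the known intercept and slope surfaces
#' there (one joint Matern draw per surface), and generates richness as
#' \code{alpha + beta * pm + noise}. The generating surfaces and
#' hyperparameters are stored as ground truth.
#'
#' @param config A [sim_config()].
#' @param pm_values Standardized productivity covariate, one finite value
#'   per route.
#' @param extra_truth_locations Optional m x 2 matrix; the truth surfaces
#'   are drawn jointly at these locations too (e.g. a prediction grid) and
#'   returned in \code{truth$extra}.
#' @param inset_km Passed to [simulate_route_locations()].
#' @return List of class \code{synthetic_dataset}: \code{routes} (a
#'   [route_table()] with \code{pm_std}) and \code{truth} (alpha/beta at
#'   routes, noise draws, generating hyperparameters, extra-location
#'   surfaces).
#' @export
simulate_routes_and_richness <- function(config, pm_values,
                                         extra_truth_locations = NULL,
                                         inset_km = 0) {
  stopifnot(inherits(config, "sim_config"),
            is.numeric(pm_values), all(is.finite(pm_values)),
            length(pm_values) == config$n_routes)
  locs <- simulate_route_locations(config, inset_km)
  pts <- locs
  if (!is.null(extra_truth_locations)) {
    extra_truth_locations <- matrix(as.matrix(extra_truth_locations),
                                    ncol = 2)
    pts <- rbind(pts, extra_truth_locations)
  }
  ip <- config$intercept_field_params
  sp <- config$slope_field_params
  alpha <- ip$mean_level + simulate_gaussian_field(
    pts, ip$range_km, ip$marginal_sd, seed = sub_seed(config$seed, 10L))
  beta <- sp$mean_level + simulate_gaussian_field(
    pts, sp$range_km, sp$marginal_sd, seed = sub_seed(config$seed, 11L))
  n <- config$n_routes
  eps <- if (config$noise_sd > 0)
    with_preserved_seed(sub_seed(config$seed, 12L),
                        stats::rnorm(n, 0, config$noise_sd))
  else numeric(n)
  richness <- alpha[seq_len(n)] + beta[seq_len(n)] * pm_values + eps
  routes <- route_table(data.frame(
    route_id = seq_len(n), x_km = locs[, 1], y_km = locs[, 2],
    richness = richness, pm_std = pm_values))
  truth <- list(alpha = alpha[seq_len(n)], beta = beta[seq_len(n)],
                noise = eps,
                hyperparameters = list(
                  range_alpha = ip$range_km, sd_alpha = ip$marginal_sd,
                  mean_alpha = ip$mean_level,
                  range_beta = sp$range_km, sd_beta = sp$marginal_sd,
                  mean_beta = sp$mean_level, noise_sd = config$noise_sd),
                extra = if (!is.null(extra_truth_locations))
                  list(locations = extra_truth_locations,
                       alpha = alpha[-seq_len(n)], beta = beta[-seq_len(n)]))
  structure(list(routes = routes, truth = truth, config = config),
            class = "synthetic_dataset")
}

#' Simulate a complete synthetic study
#'
#' End-to-end generator: GPP stack, land cover, route placement, dynamic
#' habitat indices, landscape buffer means, standardization, and richness
#' from the SVC equation. The productivity covariate entering the richness
#' equation is the standardized buffer mean of the chosen index, exactly as
#' the analysis computes it.
#'
#' @param config A [sim_config()].
#' @param measure Which index drives richness: "sum", "minimum" or
#'   "seasonality".
#' @param radius_km Landscape buffer radius (default 39.4 km).
#' @param extra_truth_locations Passed through to
#'   [simulate_routes_and_richness()].
#' @return A \code{synthetic_dataset} augmented with \code{gpp_stack},
#'   \code{landcover}, \code{dhi}; route table gains \code{pm_raw}.
#' @export
simulate_dataset <- function(config, measure = c("sum", "minimum",
                                                 "seasonality"),
                             radius_km = 39.4,
                             extra_truth_locations = NULL) {
  measure <- match.arg(measure)
  stack <- simulate_gpp_stack(config)
  landcover <- simulate_landcover(config)
  years <- unique(as.integer(format(stack$composite_start_dates, "%Y")))
  monthly <- lapply(years, function(y) aggregate_to_monthly(stack, y))
  dhi <- compute_dhi(monthly, origin = stack$origin, res_km = stack$res_km)
  locs <- simulate_route_locations(config, inset_km = radius_km)
  pm_raw <- vapply(seq_len(nrow(locs)), function(i)
    buffer_mean(dhi[[measure]], locs[i, ], radius_km), numeric(1))
  std <- standardize(pm_raw)
  ds <- simulate_routes_and_richness(config, std$z,
                                     extra_truth_locations =
                                       extra_truth_locations,
                                     inset_km = radius_km)
  ds$routes$pm_raw <- pm_raw
  ds$gpp_stack <- stack
  ds$landcover <- landcover
  ds$dhi <- dhi
  ds$measure <- measure
  ds$pm_transform <- std[c("mean", "sd")]
  ds
}

#' Write a synthetic dataset to plain-text files
#'
#' Routes as CSV, rasters as ESRI ASCII grids, truth and configuration as a
#' JSON sidecar.
#'
#' @param dataset A \code{synthetic_dataset} from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_route_csv(dataset$routes, file.path(dir, "routes.csv"))
  if (!is.null(dataset$landcover))
    write_ascii_grid(dataset$landcover, file.path(dir, "landcover.asc"))
  if (!is.null(dataset$dhi))
    for (b in names(dataset$dhi))
      write_ascii_grid(dataset$dhi[[b]], file.path(dir, paste0("dhi_", b,
                                                               ".asc")))
  truth <- dataset$truth
  truth$config <- unclass(dataset$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
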