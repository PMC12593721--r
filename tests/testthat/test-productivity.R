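make_stack <- function(vals, dates, ...) {
  prod_stack(vals, dates, ...)
}

test_that("monthly aggregation scales composite means by days_in_month/8", {
  # four 8-day composites of 0.1 starting in a 30-day June
  dates <- as.Date(c("2001-06-02", "2001-06-10", "2001-06-18", "2001-06-26"))
  vals <- array(0.1, c(4, 2, 2))
  st <- make_stack(vals, dates)
  expect_error(aggregate_to_monthly(st, 2001), "month 1")
  # complete the year with one composite per remaining month
  other <- as.Date(paste(2001, setdiff(1:12, 6), 15, sep = "-"))
  st2 <- make_stack(array(0.2, c(15, 2, 2)), c(dates, other))
  st2$values[1:4, , ] <- 0.1
  m <- aggregate_to_monthly(st2, 2001)
  expect_equal(m[6, , ], matrix(0.1 * 30 / 8, 2, 2))
  expect_equal(m[1, , ], matrix(0.2 * 31 / 8, 2, 2))
})

test_that("monthly aggregation propagates nodata and passes through monthly stacks", {
  dates <- as.Date(paste(2001, 1:12, 1, sep = "-"))
  vals <- array(0.5, c(12, 2, 2))
  vals[, 1, 1] <- NA
  st <- prod_stack(vals, dates, composite_days = "monthly")
  m <- aggregate_to_monthly(st, 2001)
  expect_true(all(is.na(m[, 1, 1])))
  expect_equal(m[3, 2, 2], 0.5)  # identity for already-monthly input
})

test_that("DHI matches direct arithmetic, including the 1..12 worked case", {
  mk_year <- function(series) {
    a <- array(NA_real_, c(12, 1, 1)); a[, 1, 1] <- series; a
  }
  # constant series
  d1 <- compute_dhi(list(mk_year(rep(0.5, 12))))
  expect_equal(d1$sum$values[1, 1], 6.0)
  expect_equal(d1$minimum$values[1, 1], 0.5)
  expect_equal(d1$seasonality$values[1, 1], 0)
  # increasing series 1..12: sum 78, min 1, CV = sd(1:12)/6.5
  d2 <- compute_dhi(list(mk_year(1:12)))
  expect_equal(d2$sum$values[1, 1], 78)
  expect_equal(d2$minimum$values[1, 1], 1)
  expect_equal(d2$seasonality$values[1, 1], sd(1:12) / 6.5, tolerance = 1e-9)
  expect_equal(d2$seasonality$values[1, 1], 0.5547002, tolerance = 1e-4)
  # all-zero pixel: CV defined as 0
  d3 <- compute_dhi(list(mk_year(rep(0, 12))))
  expect_equal(d3$seasonality$values[1, 1], 0)
  # averaging across years is a plain mean
  d4 <- compute_dhi(list(mk_year(rep(1, 12)), mk_year(rep(3, 12))))
  expect_equal(d4$sum$values[1, 1], (12 + 36) / 2)
  expect_error(compute_dhi(list(array(0, c(11, 1, 1)))), "12 monthly")
})

test_that("DHI of a noiseless sinusoidal stack matches its closed form", {
  cfg <- sim_config(domain_extent = c(0, 400, 0, 300),
                    grid_resolution_km = 100, n_routes = 3,
                    gpp_params = list(base_mean = 0.5,
                                      seasonal_amplitude = 0.3,
                                      gradient_low = 0.4, gradient_high = 1.6,
                                      pixel_noise_sd = 0), seed = 1)
  st <- simulate_gpp_stack(cfg)
  years <- unique(as.integer(format(st$composite_start_dates, "%Y")))
  dhi <- compute_dhi(lapply(years, function(y) aggregate_to_monthly(st, y)))
  g <- attr(st, "gradient")
  for (j in seq_along(g)) {
    series <- gpp_true_monthly(cfg, g[j])
    expect_equal(dhi$sum$values[1, j], sum(series), tolerance = 1e-9)
    expect_equal(dhi$minimum$values[1, j], min(series), tolerance = 1e-9)
    expect_equal(dhi$seasonality$values[1, j], sd(series) / mean(series),
                 tolerance = 1e-9)
  }
  # invariants: sum >= 12 * minimum; seasonality >= 0
  expect_true(all(dhi$sum$values >= 12 * dhi$minimum$values - 1e-12))
  expect_true(all(dhi$seasonality$values >= 0))
})

test_that("pixel aggregation averages blocks and honours nodata", {
  r <- grid_raster(matrix(c(1, 3, 2, 4), 2, 2), res_km = 1)
  expect_identical(aggregate_pixels(r, 1), r)
  expect_equal(aggregate_pixels(r, 2)$values[1, 1], 2.5)
  r2 <- grid_raster(matrix(c(1, 3, NA, NA), 2, 2), res_km = 1)
  expect_equal(aggregate_pixels(r2, 2)$values[1, 1], 2.0)
  r3 <- grid_raster(matrix(NA_real_, 2, 2), res_km = 1)
  expect_true(is.na(aggregate_pixels(r3, 2)$values[1, 1]))
  # categorical majority rule
  r4 <- grid_raster(matrix(c(1, 1, 1, 10), 2, 2), res_km = 1)
  expect_equal(aggregate_pixels(r4, 2, categorical = TRUE)$values[1, 1], 1)
  # edge blocks averaged over available cells
  r5 <- grid_raster(matrix(1:9, 3, 3), res_km = 1)
  a5 <- aggregate_pixels(r5, 2)
  expect_equal(dim(a5$values), c(2L, 2L))
  expect_equal(a5$values[2, 2], 9)  # the lone corner cell
})

test_that("buffer means agree with brute-force enumeration", {
  const <- grid_raster(matrix(7, 10, 10), res_km = 1)
  expect_equal(buffer_mean(const, c(5, 5), 3), 7)
  # tiny radius at a cell center picks that cell
  ramp <- grid_raster(matrix(rep(1:10, each = 10), 10, 10), res_km = 1)
  expect_equal(buffer_mean(ramp, c(3.5, 5.5), 0.4), 4)
  # centered buffer on a linear ramp returns the center value (symmetry)
  expect_equal(buffer_mean(ramp, c(5, 5), 3), brute_buffer_mean(ramp, c(5, 5), 3))
  set.seed(8)
  rnd <- grid_raster(matrix(runif(100), 10, 10), res_km = 1)
  rnd$values[sample(100, 20)] <- NA
  for (pt in list(c(2.3, 7.1), c(5, 5), c(9, 1.5)))
    expect_equal(buffer_mean(rnd, pt, 2.7), brute_buffer_mean(rnd, pt, 2.7))
  expect_error(buffer_mean(rnd, c(50, 50), 2), "outside")
  allna <- grid_raster(matrix(NA_real_, 5, 5), res_km = 1)
  expect_error(buffer_mean(allna, c(2.5, 2.5), 1), "no valid cells")
})

test_that("coarse-then-buffer approximates fine-raster buffer for smooth fields", {
  xs <- (1:40 - 0.5); fine <- grid_raster(outer(rep(1, 40), xs), res_km = 1)
  coarse <- aggregate_pixels(fine, 2)
  expect_equal(buffer_mean(coarse, c(20, 20), 8),
               buffer_mean(fine, c(20, 20), 8), tolerance = 1)
})

test_that("standardization uses the sample sd and reports its transform", {
  s <- standardize(c(1, 2, 3))
  expect_equal(s$z, c(-1, 0, 1))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  x <- rnorm(50, 10, 3)
  z1 <- standardize(x)
  expect_equal(mean(z1$z), 0, tolerance = 1e-12)
  expect_equal(sd(z1$z), 1, tolerance = 1e-12)
  z2 <- standardize(z1$z)  # idempotent on standardized input
  expect_equal(z2$z, z1$z, tolerance = 1e-10)
  expect_error(standardize(rep(2, 5)), "constant")
})

test_that("ASCII grid IO round-trips values, origin and nodata", {
  set.seed(3)
  m <- matrix(runif(24), 4, 6)
  m[2, 3] <- NA
  r <- grid_raster(m, origin = c(100, -50), res_km = 2.5)
  f <- tempfile(fileext = ".asc")
  write_ascii_grid(r, f)
  r2 <- read_ascii_grid(f)
  expect_equal(r2$values, r$values)
  expect_equal(r2$origin, r$origin)
  expect_equal(r2$res_km, r$res_km)
  unlink(f)
})
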