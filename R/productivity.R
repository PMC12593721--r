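#' Intra-annual productivity raster stack
#'
#' Time-indexed cube of gross primary productivity (GPP) composites on a
#' regular metric grid. \code{values} is a 3-D array (time x row x col) in
#' kg C/m^2 per compositing period; \code{composite_start_dates} gives the
#' start date of each composite. \code{composite_days} records the length of
#' the compositing period (8 for standard 8-day composites; the special value
#' \code{"monthly"} flags a stack that is already monthly).
#'
#' @param values 3-D numeric array, time first.
#' @param composite_start_dates \code{Date} vector, one per time slice.
#' @param origin,res_km,crs Grid metadata as in [grid_raster()].
#' @param composite_days 8 (default) or \code{"monthly"}.
#' @return An object of class \code{prod_stack}.
#' @export
prod_stack <- function(values, composite_start_dates, origin = c(0, 0),
                       res_km = 1, crs = "planar-km", composite_days = 8) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            inherits(composite_start_dates, "Date"),
            dim(values)[1] == length(composite_start_dates))
  bad <- values < 0 & !is.na(values)
  if (any(bad)) stop("GPP values must be non-negative or NA")
  structure(list(values = values,
                 composite_start_dates = composite_start_dates,
                 origin = as.numeric(origin), res_km = as.numeric(res_km),
                 crs = crs, composite_days = composite_days),
            class = "prod_stack")
}

#' @export
print.prod_stack <- function(x, ...) {
  d <- dim(x$values)
  cat("prod_stack: ", d[1], " composites (",
      format(min(x$composite_start_dates)), " to ",
      format(max(x$composite_start_dates)), "), grid ", d[2], " x ", d[3],
      " at ", x$res_km, " km\n", sep = "")
  invisible(x)
}

#' Aggregate a composite stack to monthly totals for one year
#'
#' Each composite is assigned to the calendar month containing its start
#' date. The monthly value per pixel is the mean of that month's composites
#' scaled by \code{days_in_month / composite_days}, turning an average
#' per-composite flux into a monthly total. A stack flagged as already
#' monthly passes through unchanged. Nodata propagates: a pixel is \code{NA}
#' for a month when all of that month's composites are \code{NA}.
#'
#' @param stack A [prod_stack()].
#' @param year Calendar year to aggregate.
#' @return 3-D array (12 x row x col) of monthly GPP totals, kg C/m^2/month.
#' @export
aggregate_to_monthly <- function(stack, year) {
  stopifnot(inherits(stack, "prod_stack"))
  dates <- stack$composite_start_dates
  yrs <- as.integer(format(dates, "%Y"))
  if (!any(yrs == year)) stop("stack has no composites in year ", year)
  sel <- which(yrs == year)
  mons <- as.integer(format(dates[sel], "%m"))
  d <- dim(stack$values)
  out <- array(NA_real_, c(12L, d[2], d[3]))
  if (identical(stack$composite_days, "monthly")) {
    if (!setequal(unique(mons), 1:12))
      stop("monthly stack for year ", year, " is missing months: ",
           paste(setdiff(1:12, unique(mons)), collapse = ", "))
    for (m in 1:12) out[m, , ] <- stack$values[sel[match(m, mons)], , ]
    return(out)
  }
  dim_days <- days_in_month(year)
  for (m in 1:12) {
    idx <- sel[mons == m]
    if (!length(idx))
      stop("no composites with start date in month ", m, " of year ", year)
    slab <- stack$values[idx, , , drop = FALSE]
    n_ok <- apply(!is.na(slab), c(2, 3), sum)
    s <- apply(slab, c(2, 3), sum, na.rm = TRUE)
    mu <- ifelse(n_ok > 0, s / n_ok, NA_real_)
    out[m, , ] <- mu * (dim_days[m] / stack$composite_days)
  }
  out
}

days_in_month <- function(year) {
  feb <- if ((year %% 4 == 0 && year %% 100 != 0) || year %% 400 == 0) 29 else 28
  c(31, feb, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
}

#' Dynamic habitat indices from monthly productivity
#'
#' For each year the three dynamic habitat indices are computed per pixel
#' from the 12 monthly GPP totals: \code{sum} (annual total, the available
#' energy), \code{minimum} (the intra-annual bottleneck) and
#' \code{seasonality} (coefficient of variation, sample sd over mean,
#' resource instability). Yearly values are then averaged across years. A
#' pixel whose monthly mean is 0 (a fully unproductive pixel) gets
#' seasonality 0 rather than NaN, so deserts map to the low end of the
#' seasonality scale.
#'
#' @param monthly_by_year List of 3-D arrays (12 x row x col), one per year,
#'   as produced by [aggregate_to_monthly()].
#' @param origin,res_km,crs Grid metadata for the output rasters.
#' @return A list of class \code{dhi_raster} with \code{grid_raster} bands
#'   \code{sum} (kg C/m^2/year), \code{minimum} (kg C/m^2/month) and
#'   \code{seasonality} (dimensionless).
#' @export
compute_dhi <- function(monthly_by_year, origin = c(0, 0), res_km = 1,
                        crs = "planar-km") {
  stopifnot(is.list(monthly_by_year), length(monthly_by_year) >= 1L)
  acc <- NULL
  for (yr in monthly_by_year) {
    stopifnot(is.array(yr), length(dim(yr)) == 3L)
    if (dim(yr)[1] != 12L)
      stop("each year must have 12 monthly layers, got ", dim(yr)[1])
    s <- apply(yr, c(2, 3), sum)
    mn <- apply(yr, c(2, 3), min)
    mu <- s / 12
    sdev <- apply(yr, c(2, 3), stats::sd)
    cv <- ifelse(mu > 0, sdev / mu, ifelse(is.na(mu), NA_real_, 0))
    if (is.null(acc)) {
      acc <- list(sum = s, min = mn, cv = cv, n = 1L)
    } else {
      acc$sum <- acc$sum + s; acc$min <- acc$min + mn; acc$cv <- acc$cv + cv
      acc$n <- acc$n + 1L
    }
  }
  mk <- function(m) grid_raster(m / acc$n, origin = origin, res_km = res_km,
                                crs = crs)
  structure(list(sum = mk(acc$sum), minimum = mk(acc$min),
                 seasonality = mk(acc$cv)),
            class = "dhi_raster")
}

#' @export
print.dhi_raster <- function(x, ...) {
  cat("dhi_raster with bands sum, minimum, seasonality\n")
  for (b in names(x)) { cat("$", b, "\n", sep = ""); print(x[[b]]) }
  invisible(x)
}

#' Standardize a covariate to zero mean and unit sample standard deviation
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return List with \code{z} (the z-scores), \code{mean} and \code{sd}
#'   (sample sd, n-1 denominator) for projecting new values onto the same
#'   scale.
#' @export
standardize <- function(values) {
  stopifnot(is.numeric(values), all(is.finite(values)), length(values) >= 2L)
  s <- stats::sd(values)
  if (s == 0) stop("cannot standardize a constant vector")
  m <- mean(values)
  list(z = (values - m) / s, mean = m, sd = s)
}
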