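#' Minimal single-band raster on a regular metric grid
#'
#' A light container used throughout the package: a numeric matrix of cell
#' values plus grid metadata. Row 1 is the southernmost row (y increases with
#' row index); \code{origin} is the lower-left corner of the grid in km and
#' cell centers sit at \code{origin + (index - 0.5) * res_km}. Missing data is
#' \code{NA}.
#'
#' @param values Numeric matrix (rows = south-to-north, cols = west-to-east).
#' @param origin Length-2 numeric, lower-left corner (x_km, y_km).
#' @param res_km Cell size in km (positive scalar; cells are square).
#' @param crs Free-text tag recording the planar CRS the coordinates live in.
#' @return An object of class \code{grid_raster}.
#' @export
grid_raster <- function(values, origin = c(0, 0), res_km = 1,
                        crs = "planar-km") {
  stopifnot(is.matrix(values), is.numeric(values) || is.logical(values),
            length(origin) == 2L, is.finite(origin),
            length(res_km) == 1L, res_km > 0)
  structure(list(values = values, origin = as.numeric(origin),
                 res_km = as.numeric(res_km), crs = crs),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  d <- dim(x$values)
  cat("grid_raster: ", d[1], " x ", d[2], " cells, ", x$res_km,
      " km resolution\n", sep = "")
  cat("  extent (km): x [", x$origin[1], ", ", x$origin[1] + d[2] * x$res_km,
      "], y [", x$origin[2], ", ", x$origin[2] + d[1] * x$res_km, "]\n",
      sep = "")
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat("  values: min ", signif(min(v), 4), ", median ",
        signif(stats::median(v), 4), ", max ", signif(max(v), 4), "; ",
        sum(is.na(x$values)), " nodata cells\n", sep = "")
  invisible(x)
}

#' Cell-center coordinates of a grid_raster
#'
#' @param raster A \code{grid_raster}.
#' @return List with vectors \code{x} (per column) and \code{y} (per row).
#' @export
cell_centers <- function(raster) {
  d <- dim(raster$values)
  list(x = raster$origin[1] + (seq_len(d[2]) - 0.5) * raster$res_km,
       y = raster$origin[2] + (seq_len(d[1]) - 0.5) * raster$res_km)
}

#' Read / write rasters as ESRI ASCII grid
#'
#' Plain-text raster exchange format: a 6-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values,
#' northernmost row first. Coordinates are interpreted as km.
#'
#' @param path File path.
#' @return \code{read_ascii_grid} returns a \code{grid_raster};
#'   \code{write_ascii_grid} returns \code{path} invisibly.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header incomplete: missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  # file stores north-first; flip to our south-first convention
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  grid_raster(m, origin = c(hdr$xllcorner, hdr$yllcorner),
              res_km = hdr$cellsize)
}

#' @rdname read_ascii_grid
#' @param raster A \code{grid_raster} to write.
#' @param nodata Value used to encode \code{NA} on disk.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "grid_raster"))
  m <- raster$values
  m[is.na(m)] <- nodata
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", raster$origin[1]),
           paste("yllcorner", raster$origin[2]),
           paste("cellsize", raster$res_km),
           paste("NODATA_value", nodata))
  body <- apply(m, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Block-aggregate a raster to coarser resolution
#'
#' Each coarse cell is the mean of the underlying \code{factor x factor} block
#' of fine cells, ignoring nodata; an all-nodata block stays nodata. When the
#' raster dimensions are not divisible by \code{factor}, edge blocks are
#' averaged over the cells available. With \code{categorical = TRUE} the
#' majority class in the block is taken instead (ties broken by the smallest
#' class code).
#'
#' @param raster A \code{grid_raster}.
#' @param factor Integer aggregation factor (>= 1).
#' @param categorical Majority-class aggregation for categorical rasters.
#' @return A coarser \code{grid_raster} with the same origin.
#' @export
aggregate_pixels <- function(raster, factor, categorical = FALSE) {
  stopifnot(inherits(raster, "grid_raster"),
            length(factor) == 1L, factor >= 1, factor == round(factor))
  factor <- as.integer(factor)
  if (factor == 1L) return(raster)
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  out_r <- ceiling(nr / factor); out_c <- ceiling(nc / factor)
  ri <- (seq_len(nr) - 1L) %/% factor + 1L
  ci <- (seq_len(nc) - 1L) %/% factor + 1L
  grp <- (rep(ci, each = nr) - 1L) * out_r + rep(ri, times = nc)
  vals <- as.vector(v)
  out <- rep(NA_real_, out_r * out_c)
  ok <- !is.na(vals)
  if (any(ok)) {
    if (categorical) {
      for (g in unique(grp[ok])) {
        x <- vals[ok & grp == g]
        tab <- table(x)
        out[g] <- as.numeric(names(tab)[which.max(tab)])
      }
    } else {
      s <- tapply(vals[ok], grp[ok], sum)
      n <- tapply(vals[ok], grp[ok], length)
      out[as.integer(names(s))] <- s / n
    }
  }
  grid_raster(matrix(out, nrow = out_r, ncol = out_c),
              origin = raster$origin, res_km = raster$res_km * factor,
              crs = raster$crs)
}

#' Mean of raster values within a circular buffer
#'
#' Averages the cells whose centers lie within Euclidean distance
#' \code{radius_km} of \code{point}, excluding nodata. Membership is decided
#' by cell-center distance, the usual zonal-statistics convention.
#'
#' @param raster A \code{grid_raster}.
#' @param point Length-2 numeric (x_km, y_km); must be inside the raster
#'   extent.
#' @param radius_km Positive buffer radius in km.
#' @return Scalar mean; errors if the buffer contains no valid cell.
#' @export
buffer_mean <- function(raster, point, radius_km) {
  v <- buffer_values(raster, point, radius_km)
  if (!length(v))
    stop("buffer of radius ", radius_km, " km at (", point[1], ", ", point[2],
         ") contains no valid cells")
  mean(v)
}

# valid (non-NA) cell values whose centers fall inside the buffer
buffer_values <- function(raster, point, radius_km) {
  stopifnot(inherits(raster, "grid_raster"), length(point) == 2L,
            length(radius_km) == 1L, radius_km > 0)
  d <- dim(raster$values)
  ext_x <- raster$origin[1] + c(0, d[2] * raster$res_km)
  ext_y <- raster$origin[2] + c(0, d[1] * raster$res_km)
  if (point[1] < ext_x[1] || point[1] > ext_x[2] ||
      point[2] < ext_y[1] || point[2] > ext_y[2])
    stop("point (", point[1], ", ", point[2], ") lies outside raster extent")
  cc <- cell_centers(raster)
  # restrict to the bounding box of the disk before the distance test
  cs <- which(abs(cc$x - point[1]) <= radius_km)
  rs <- which(abs(cc$y - point[2]) <= radius_km)
  if (!length(cs) || !length(rs)) return(numeric(0))
  dx2 <- (cc$x[cs] - point[1])^2
  dy2 <- (cc$y[rs] - point[2])^2
  inside <- outer(dy2, dx2, "+") <= radius_km^2
  v <- raster$values[rs, cs, drop = FALSE][inside]
  v[!is.na(v)]
}
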