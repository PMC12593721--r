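#' Construct a route table
#'
#' Survey sites with planar coordinates (km) and a richness response. Columns
#' beyond \code{route_id}, \code{x_km}, \code{y_km}, \code{richness} (e.g.
#' productivity covariates) are carried along untouched. Filters annotate the
#' table with \code{retained} / \code{drop_reason} rather than deleting rows,
#' so filter order and reasons stay auditable.
#'
#' @param df Data frame with at least route_id, x_km, y_km, richness.
#' @return The data frame with class \code{route_table} prepended.
#' @export
route_table <- function(df) {
  need <- c("route_id", "x_km", "y_km", "richness")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("route table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$route_id)) stop("route_id must be unique")
  if (is.null(df$retained)) df$retained <- TRUE
  if (is.null(df$drop_reason)) df$drop_reason <- NA_character_
  class(df) <- unique(c("route_table", class(df)))
  df
}

#' Drop routes in human-dominated landscapes
#'
#' A route is retained only when strictly less than \code{threshold} of the
#' valid land-cover cells within \code{radius_km} of its start point belong
#' to the human-dominated classes (croplands, urban and built-up lands,
#' cropland/natural-vegetation mosaics in the source land-cover product).
#' The boundary is exclusive: a landscape at exactly the threshold is
#' dropped. Cell membership uses the same cell-center rule as
#' [buffer_mean()]. A buffer with no valid land-cover cells drops the route
#' with its own reason code.
#'
#' @param routes A [route_table()].
#' @param landcover Categorical \code{grid_raster} of class codes.
#' @param human_classes Numeric class codes counted as human-dominated.
#' @param radius_km Landscape radius in km (default 39.4, the route length).
#' @param threshold Maximum tolerated human fraction (default 0.5).
#' @return The route table with \code{retained}/\code{drop_reason} updated
#'   and a \code{human_frac} column appended.
#' @export
human_cover_filter <- function(routes, landcover, human_classes,
                               radius_km = 39.4, threshold = 0.5) {
  stopifnot(inherits(routes, "route_table"), inherits(landcover, "grid_raster"))
  frac <- rep(NA_real_, nrow(routes))
  for (i in seq_len(nrow(routes))) {
    if (!isTRUE(routes$retained[i])) next
    v <- buffer_values(landcover, c(routes$x_km[i], routes$y_km[i]), radius_km)
    if (!length(v)) {
      routes$retained[i] <- FALSE
      routes$drop_reason[i] <- "no_valid_landcover"
      next
    }
    frac[i] <- mean(v %in% human_classes)
    if (frac[i] >= threshold) {
      routes$retained[i] <- FALSE
      routes$drop_reason[i] <- "human_cover"
    }
  }
  routes$human_frac <- frac
  routes
}

#' Drop routes whose landscape buffer leaves the study area
#'
#' A route is retained only when the full disk of radius \code{radius_km}
#' around its start point lies inside the boundary polygon: the point must be
#' interior and its distance to the boundary must be at least the radius
#' (equality retained).
#'
#' @param routes A [route_table()].
#' @param boundary Polygon as an n x 2 matrix of vertices (closed implicitly)
#'   or a list of such rings for multi-part boundaries.
#' @param radius_km Buffer radius in km.
#' @return The route table with \code{retained}/\code{drop_reason} updated.
#' @export
containment_filter <- function(routes, boundary, radius_km = 39.4) {
  stopifnot(inherits(routes, "route_table"))
  rings <- validate_rings(boundary)
  for (i in seq_len(nrow(routes))) {
    if (!isTRUE(routes$retained[i])) next
    p <- c(routes$x_km[i], routes$y_km[i])
    inside <- point_in_rings(p, rings)
    if (!inside || dist_to_rings(p, rings) < radius_km) {
      routes$retained[i] <- FALSE
      routes$drop_reason[i] <- "buffer_outside_boundary"
    }
  }
  routes
}

validate_rings <- function(boundary) {
  rings <- if (is.list(boundary) && !is.data.frame(boundary)) boundary
           else list(boundary)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2L || nrow(r) < 3L || any(!is.finite(r)))
      stop("invalid boundary ring: need >= 3 finite (x, y) vertices")
    # drop an explicit closing vertex
    if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    if (nrow(r) < 3L) stop("invalid boundary ring: degenerate after closing")
    r
  })
  rings
}

# even-odd rule across all rings (holes supported implicitly)
point_in_rings <- function(p, rings) {
  crossings <- 0L
  for (r in rings) {
    n <- nrow(r)
    j <- n
    for (i in seq_len(n)) {
      yi <- r[i, 2]; yj <- r[j, 2]
      if ((yi > p[2]) != (yj > p[2])) {
        xint <- r[j, 1] + (p[2] - yj) / (yi - yj) * (r[i, 1] - r[j, 1])
        if (p[1] < xint) crossings <- crossings + 1L
      }
      j <- i
    }
  }
  crossings %% 2L == 1L
}

dist_to_rings <- function(p, rings) {
  dmin <- Inf
  for (r in rings) {
    n <- nrow(r)
    a <- r
    b <- r[c(2:n, 1), , drop = FALSE]
    abx <- b[, 1] - a[, 1]; aby <- b[, 2] - a[, 2]
    apx <- p[1] - a[, 1]; apy <- p[2] - a[, 2]
    len2 <- abx^2 + aby^2
    t <- ifelse(len2 > 0, pmin(1, pmax(0, (apx * abx + apy * aby) / len2)), 0)
    dx <- apx - t * abx; dy <- apy - t * aby
    dmin <- min(dmin, sqrt(min(dx^2 + dy^2)))
  }
  dmin
}

#' Write a route table (with filter annotations) to CSV
#'
#' @param routes A [route_table()].
#' @param path Output CSV path.
#' @export
write_route_csv <- function(routes, path) {
  utils::write.csv(as.data.frame(routes), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a route table from CSV
#'
#' @param path CSV with columns route_id, x_km, y_km, richness (extra
#'   columns preserved).
#' @export
read_route_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(df$drop_reason)) df$drop_reason[df$drop_reason == ""] <- NA
  route_table(df)
}
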