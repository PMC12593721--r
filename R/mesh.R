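#' Build a triangulated mesh over a nonconvex hull of data points
#'
#' Constructs the finite-element mesh for the SPDE representation of a
#' Matern field: a Delaunay triangulation whose vertices include every data
#' point, covering the nonconvex hull of the points dilated by
#' \code{hull_buffer_km} (so fields are estimated away from the mesh edge),
#' refined until no triangle edge exceeds \code{max_edge_km}.
#'
#' The domain is the union of disks of radius \code{hull_buffer_km} around
#' the data points; a candidate triangle is kept when its centroid lies in
#' the domain. Filler vertices come from a jittered hexagonal lattice, and
#' midpoints of over-long edges are inserted iteratively until the edge
#' bound holds.
#'
#' @param points n x 2 matrix of (x_km, y_km) locations (>= 3, not all
#'   collinear).
#' @param max_edge_km Maximum allowed triangle edge length (km).
#' @param hull_buffer_km Dilation of the point cloud defining the mesh
#'   domain; defaults to \code{max_edge_km}.
#' @param cutoff_km Data points closer than this are merged to one vertex
#'   (defaults to \code{max_edge_km / 100}).
#' @return An object of class \code{svc_mesh}: \code{loc} (vertex
#'   coordinates), \code{tt} (triangle vertex indices), \code{point_index}
#'   (vertex index of each input point), \code{interior_boundary} and
#'   \code{extension_boundary} (closed polygon loops), and the build
#'   parameters.
#' @export
build_mesh <- function(points, max_edge_km, hull_buffer_km = max_edge_km,
                       cutoff_km = max_edge_km / 100) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, nrow(points) >= 3L, all(is.finite(points)),
            max_edge_km > 0, hull_buffer_km > 0)
  span <- svd(sweep(points, 2, colMeans(points)))$d
  if (span[2] < 1e-9 * max(span[1], 1))
    stop("degenerate point set: all points are (nearly) collinear")

  # merge near-coincident data points to a single vertex
  keep <- dedupe_points(points, cutoff_km)
  verts <- points[keep$keep, , drop = FALSE]
  n_data <- nrow(verts)

  # hexagonal filler lattice over the dilated domain
  # lattice spacing well under the edge bound: removing lattice nodes that
  # crowd a data vertex leaves holes the Delaunay spans with edges up to
  # roughly spacing + 2 * crowding radius, which must stay <= max_edge
  s <- max_edge_km * 0.6
  bbox <- rbind(apply(points, 2, min) - hull_buffer_km - s,
                apply(points, 2, max) + hull_buffer_km + s)
  lat <- hex_lattice(bbox, s)
  lat <- with_preserved_seed(20231L, {
    lat + matrix(stats::runif(length(lat), -0.02 * s, 0.02 * s), ncol = 2)
  })
  # keep lattice up to a two-cell margin beyond the domain: kept triangles
  # (centroid inside the domain) then sit in uniformly covered territory and
  # never border the vertex-free exterior, which would otherwise contribute
  # arbitrarily long sliver edges along the domain boundary
  lat <- lat[min_dist_to(lat, verts) <= hull_buffer_km + 2 * s, , drop = FALSE]
  if (nrow(lat)) # drop lattice nodes crowding a data vertex
    lat <- lat[min_dist_to(lat, verts) > 0.35 * s, , drop = FALSE]
  verts <- rbind(verts, lat)

  in_domain <- function(p) min_dist_to(p, points) <= hull_buffer_km
  for (iter in 1:25) {
    tri <- delaunay_triangles(verts)
    cent <- (verts[tri[, 1], ] + verts[tri[, 2], ] + verts[tri[, 3], ]) / 3
    tri <- tri[in_domain(cent), , drop = FALSE]
    if (!nrow(tri)) stop("mesh construction produced no interior triangles")
    ed <- triangle_edges(tri)
    len <- sqrt(rowSums((verts[ed[, 1], , drop = FALSE] -
                         verts[ed[, 2], , drop = FALSE])^2))
    long <- len > max_edge_km
    if (!any(long)) break
    mids <- (verts[ed[long, 1], , drop = FALSE] +
             verts[ed[long, 2], , drop = FALSE]) / 2
    # displace each midpoint slightly toward the nearest data point: this
    # breaks the exact collinearity that defeats floating-point incircle
    # tests, and for edges hugging the domain boundary it puts the new
    # vertex on the interior side, where it forces the edge to flip; the
    # displacement grows with the iteration so a flip-resistant sliver edge
    # receives a fresh splitting point each pass instead of a duplicate
    disp <- 0.02 * max_edge_km * min(iter, 6)
    mids <- mids + disp * toward_nearest(mids, points)
    mids <- mids[min_dist_to(mids, verts) > cutoff_km, , drop = FALSE]
    if (nrow(mids) > 1)
      mids <- mids[dedupe_points(mids, cutoff_km)$keep, , drop = FALSE]
    verts <- rbind(verts, mids)
  }
  if (any(long)) stop("mesh refinement did not converge in 25 iterations")

  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
  loc <- verts[used, , drop = FALSE]
  tt <- matrix(remap[tri], ncol = 3)
  point_index <- remap[keep$map]
  if (any(point_index == 0))
    stop("internal error: a data vertex fell outside the meshed domain")

  structure(list(
    loc = loc, tt = tt, n_data_vertices = n_data,
    point_index = point_index,
    interior_boundary = concave_hull_loops(points[keep$keep, , drop = FALSE],
                                           alpha = max_edge_km),
    extension_boundary = boundary_loops(loc, tt),
    max_edge_km = max_edge_km, hull_buffer_km = hull_buffer_km
  ), class = "svc_mesh")
}

#' @export
print.svc_mesh <- function(x, ...) {
  cat("svc_mesh: ", nrow(x$loc), " vertices, ", nrow(x$tt), " triangles\n",
      "  max edge ", signif(max(mesh_edge_lengths(x)), 4), " km (bound ",
      x$max_edge_km, " km), hull buffer ", x$hull_buffer_km, " km\n", sep = "")
  invisible(x)
}

#' @export
plot.svc_mesh <- function(x, ...) {
  plot(x$loc, type = "n", xlab = "x (km)", ylab = "y (km)", asp = 1, ...)
  ed <- triangle_edges(x$tt)
  graphics::segments(x$loc[ed[, 1], 1], x$loc[ed[, 1], 2],
                     x$loc[ed[, 2], 1], x$loc[ed[, 2], 2], col = "grey70")
  graphics::points(x$loc[x$point_index, , drop = FALSE], pch = 16, cex = 0.5)
  invisible(x)
}

#' Edge lengths of a mesh
#' @param mesh An \code{svc_mesh}.
#' @return Numeric vector of unique edge lengths in km.
#' @export
mesh_edge_lengths <- function(mesh) {
  ed <- triangle_edges(mesh$tt)
  sqrt(rowSums((mesh$loc[ed[, 1], , drop = FALSE] -
                mesh$loc[ed[, 2], , drop = FALSE])^2))
}

# --- internals -------------------------------------------------------------

dedupe_points <- function(points, cutoff) {
  n <- nrow(points)
  keep <- integer(0)
  map <- integer(n)
  for (i in seq_len(n)) {
    if (length(keep)) {
      d2 <- (points[keep, 1] - points[i, 1])^2 +
            (points[keep, 2] - points[i, 2])^2
      j <- which(d2 <= cutoff^2)
      if (length(j)) { map[i] <- j[1]; next }
    }
    keep <- c(keep, i)
    map[i] <- length(keep)
  }
  list(keep = keep, map = map)
}

hex_lattice <- function(bbox, s) {
  xs <- seq(bbox[1, 1], bbox[2, 1], by = s)
  ys <- seq(bbox[1, 2], bbox[2, 2], by = s * sqrt(3) / 2)
  pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
    off <- if (i %% 2 == 0) s / 2 else 0
    cbind(xs + off, ys[i])
  }))
  pts
}

# unit vectors from each row of a toward its nearest point in b (zero for
# coincident points, given a slight non-radial twist to avoid collinearity)
toward_nearest <- function(a, b) {
  a <- matrix(a, ncol = 2)
  out <- matrix(0, nrow(a), 2)
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2
    j <- which.min(d2)
    if (d2[j] > 0) {
      v <- c(b[j, 1] - a[i, 1], b[j, 2] - a[i, 2]) / sqrt(d2[j])
      out[i, ] <- 0.95 * v + 0.31 * c(-v[2], v[1])
    } else out[i, ] <- c(0.95, 0.31)
  }
  out
}

# min distance from each row of a to the point set b (chunked outer)
min_dist_to <- function(a, b) {
  a <- matrix(a, ncol = 2)
  out <- numeric(nrow(a))
  step <- max(1L, floor(2e6 / nrow(b)))
  for (i0 in seq(1L, nrow(a), by = step)) {
    i1 <- min(i0 + step - 1L, nrow(a))
    d2 <- outer(a[i0:i1, 1], b[, 1], "-")^2 + outer(a[i0:i1, 2], b[, 2], "-")^2
    out[i0:i1] <- sqrt(apply(d2, 1, min))
  }
  out
}

delaunay_triangles <- function(verts) {
  tr <- interp::tri.mesh(verts[, 1], verts[, 2], duplicate = "error")
  tm <- unname(as.matrix(interp::triangles(tr)[, 1:3, drop = FALSE]))
  if (nrow(tm) == 0) stop("Delaunay triangulation failed")
  tm
}

triangle_edges <- function(tt) {
  ed <- rbind(tt[, c(1, 2)], tt[, c(2, 3)], tt[, c(3, 1)])
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  ed[!duplicated(ed), , drop = FALSE]
}

# edges used by exactly one triangle, chained into closed loops
boundary_loops <- function(loc, tt) {
  ed <- rbind(tt[, c(1, 2)], tt[, c(2, 3)], tt[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  bnd <- ed[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  loops <- list()
  adj <- split(rep(seq_len(nrow(bnd)), 2L), c(bnd[, 1], bnd[, 2]))
  used <- rep(FALSE, nrow(bnd))
  for (e0 in seq_len(nrow(bnd))) {
    if (used[e0]) next
    loop <- bnd[e0, 1]
    cur <- bnd[e0, 2]; used[e0] <- TRUE
    repeat {
      loop <- c(loop, cur)
      nxt <- adj[[as.character(cur)]]
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) break
      e <- nxt[1]; used[e] <- TRUE
      cur <- if (bnd[e, 1] == cur) bnd[e, 2] else bnd[e, 1]
    }
    loops[[length(loops) + 1L]] <- loc[loop, , drop = FALSE]
  }
  loops
}

# alpha-shape style concave hull: Delaunay triangles with circumradius <= alpha
concave_hull_loops <- function(points, alpha) {
  if (nrow(points) < 3L) return(list())
  tri <- delaunay_triangles(points)
  r <- circumradius(points, tri)
  tri <- tri[r <= alpha, , drop = FALSE]
  if (!nrow(tri)) tri <- delaunay_triangles(points) # fall back to convex hull
  boundary_loops(points, tri)
}

circumradius <- function(loc, tt) {
  a <- loc[tt[, 1], , drop = FALSE]
  b <- loc[tt[, 2], , drop = FALSE]
  c <- loc[tt[, 3], , drop = FALSE]
  la <- sqrt(rowSums((b - c)^2))
  lb <- sqrt(rowSums((a - c)^2))
  lc <- sqrt(rowSums((a - b)^2))
  area <- 0.5 * abs((b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
                    (c[, 1] - a[, 1]) * (b[, 2] - a[, 2]))
  ifelse(area > 0, la * lb * lc / (4 * area), Inf)
}

# evaluate expr with the global RNG state saved/restored, seeded locally
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Barycentric projector matrix from mesh vertices to locations
#'
#' Builds the sparse matrix A mapping mesh-vertex field values to values at
#' arbitrary locations by linear interpolation within the containing
#' triangle. Rows are convex weights (non-negative, summing to 1); a
#' location coinciding with a vertex gets a unit row.
#'
#' @param mesh An \code{svc_mesh}.
#' @param loc m x 2 matrix of query locations.
#' @param strict Error if a location is outside the mesh (default). With
#'   \code{strict = FALSE} such rows are zero and flagged.
#' @return With \code{strict = TRUE} a \code{dgCMatrix}; otherwise a list
#'   \code{(A, ok)}.
#' @export
mesh_projector <- function(mesh, loc, strict = TRUE) {
  loc <- matrix(as.matrix(loc), ncol = 2)
  m <- nrow(loc)
  tt <- mesh$tt; V <- mesh$loc
  # bucket triangles by bounding box for fast point location
  cell <- mesh$max_edge_km
  ox <- min(V[, 1]); oy <- min(V[, 2])
  nbx <- max(1L, ceiling((max(V[, 1]) - ox) / cell))
  bucket_of <- function(x, y) {
    bx <- pmin(pmax(floor((x - ox) / cell), 0), nbx - 1)
    by <- pmax(floor((y - oy) / cell), 0)
    by * nbx + bx + 1
  }
  tri_buckets <- lapply(seq_len(nrow(tt)), function(k) {
    xs <- V[tt[k, ], 1]; ys <- V[tt[k, ], 2]
    bx <- floor((c(min(xs), max(xs)) - ox) / cell)
    by <- floor((c(min(ys), max(ys)) - oy) / cell)
    as.vector(outer(pmax(by[1], 0):by[2] * nbx,
                    pmin(pmax(bx[1], 0), nbx - 1):pmin(bx[2], nbx - 1) + 1,
                    "+"))
  })
  idx <- split(rep(seq_len(nrow(tt)), lengths(tri_buckets)),
               unlist(tri_buckets))
  tol <- 1e-9
  ii <- jj <- xx <- vector("list", m)
  ok <- rep(FALSE, m)
  for (q in seq_len(m)) {
    cand <- idx[[as.character(bucket_of(loc[q, 1], loc[q, 2]))]]
    if (is.null(cand)) cand <- seq_len(nrow(tt))
    for (k in cand) {
      w <- barycentric(V[tt[k, ], , drop = FALSE], loc[q, ])
      if (!is.null(w) && all(w >= -tol)) {
        w <- pmax(w, 0); w <- w / sum(w)
        ii[[q]] <- rep(q, 3); jj[[q]] <- tt[k, ]; xx[[q]] <- w
        ok[q] <- TRUE
        break
      }
    }
  }
  if (strict && !all(ok))
    stop("locations outside the mesh: rows ",
         paste(utils::head(which(!ok), 10), collapse = ", "),
         if (sum(!ok) > 10) " ..." else "")
  A <- Matrix::sparseMatrix(i = as.integer(unlist(ii)),
                            j = as.integer(unlist(jj)),
                            x = as.numeric(unlist(xx)),
                            dims = c(m, nrow(V)))
  if (strict) A else list(A = A, ok = ok)
}

barycentric <- function(tri, p) {
  d <- (tri[2, 2] - tri[3, 2]) * (tri[1, 1] - tri[3, 1]) +
       (tri[3, 1] - tri[2, 1]) * (tri[1, 2] - tri[3, 2])
  if (abs(d) < 1e-12) return(NULL)
  w1 <- ((tri[2, 2] - tri[3, 2]) * (p[1] - tri[3, 1]) +
         (tri[3, 1] - tri[2, 1]) * (p[2] - tri[3, 2])) / d
  w2 <- ((tri[3, 2] - tri[1, 2]) * (p[1] - tri[3, 1]) +
         (tri[1, 1] - tri[3, 1]) * (p[2] - tri[3, 2])) / d
  c(w1, w2, 1 - w1 - w2)
}
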