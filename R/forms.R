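#' Classify relationship form from a 95% credible interval
#'
#' A local productivity-richness relationship is \code{positive} when the
#' interval lies strictly above zero, \code{negative} when strictly below,
#' and \code{non-existent} otherwise. Overlap is inclusive: an interval
#' touching zero at either endpoint is non-existent (the conservative
#' reading of "excluded zero").
#'
#' @param q2.5,q97.5 Lower and upper 95% credible bounds (vectorized).
#' @return Factor with levels negative, non-existent, positive.
#' @export
classify_form <- function(q2.5, q97.5) {
  if (any(q2.5 > q97.5, na.rm = TRUE))
    stop("unordered quantiles: q2.5 > q97.5")
  out <- ifelse(q2.5 > 0, "positive",
                ifelse(q97.5 < 0, "negative", "non-existent"))
  factor(out, levels = c("negative", "non-existent", "positive"))
}

#' Map relationship form on a regular grid
#'
#' Projects the slope-surface posterior onto the centers of a regular grid
#' (40 km by default, approximating the landscape-buffer footprint),
#' classifies each cell with [classify_form()], and flags statistically
#' important cells (interval excluding zero). Cells outside the mesh, or
#' outside an optional study polygon, are masked.
#'
#' @param fit An \code{svc_fit}.
#' @param resolution_km Grid resolution (default 40).
#' @param extent Numeric (x_min, x_max, y_min, y_max); defaults to the
#'   bounding box of the data sites.
#' @param boundary Optional polygon (ring matrix or list of rings); cells
#'   with centers outside it are masked.
#' @return Data frame of class \code{form_grid}: cell centers, beta
#'   median/q2.5/q97.5, \code{important}, \code{form}; attributes
#'   \code{resolution_km} and \code{origin}.
#' @export
build_form_grid <- function(fit, resolution_km = 40, extent = NULL,
                            boundary = NULL) {
  if (is.null(extent))
    extent <- c(min(fit$loc[, 1]), max(fit$loc[, 1]),
                min(fit$loc[, 2]), max(fit$loc[, 2]))
  xs <- seq(extent[1] + resolution_km / 2, extent[2], by = resolution_km)
  ys <- seq(extent[3] + resolution_km / 2, extent[4], by = resolution_km)
  cells <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  keep <- rep(TRUE, nrow(cells))
  if (!is.null(boundary)) {
    rings <- validate_rings(boundary)
    keep <- vapply(seq_len(nrow(cells)), function(i)
      point_in_rings(cells[i, ], rings), logical(1))
  }
  pr <- mesh_projector(fit$mesh, cells, strict = FALSE)
  keep <- keep & pr$ok
  cells <- cells[keep, , drop = FALSE]
  pred <- predict.svc_fit(fit, cells)
  form <- classify_form(pred$beta_q2.5, pred$beta_q97.5)
  out <- data.frame(x_km = cells[, 1], y_km = cells[, 2],
                    beta_median = pred$beta_median,
                    beta_q2.5 = pred$beta_q2.5,
                    beta_q97.5 = pred$beta_q97.5,
                    important = form != "non-existent",
                    form = form)
  attr(out, "resolution_km") <- resolution_km
  attr(out, "origin") <- extent[c(1, 3)]
  class(out) <- c("form_grid", class(out))
  out
}

#' @export
plot.form_grid <- function(x, ...) {
  cols <- c(negative = "#b2182b", `non-existent` = "grey85",
            positive = "#2166ac")
  plot(x$x_km, x$y_km, col = cols[as.character(x$form)], pch = 15,
       cex = 0.6, asp = 1, xlab = "x (km)", ylab = "y (km)",
       main = "Relationship form", ...)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 15,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Distribution of a productivity measure by relationship form
#'
#' Classifies each valid cell of a measure raster (via the slope posterior
#' at the cell center) and summarizes the measure per form with five-number
#' statistics, flagging 1.5*IQR outliers (flagged, still counted). This is
#' the boxplot-by-form summary relating prevailing productivity conditions
#' to relationship form.
#'
#' @param measure_raster A \code{grid_raster} of the productivity measure.
#' @param fit An \code{svc_fit} whose mesh covers the raster cells used.
#' @return Data frame of class \code{form_summary}: one row per form with
#'   n, min, q25, median, q75, max, n_outliers; attribute \code{cells}
#'   holds the per-cell classification.
#' @export
summarize_by_form <- function(measure_raster, fit) {
  stopifnot(inherits(measure_raster, "grid_raster"))
  cc <- cell_centers(measure_raster)
  cells <- cbind(rep(cc$x, each = length(cc$y)), rep(cc$y, length(cc$x)))
  vals <- as.vector(measure_raster$values)
  ok <- !is.na(vals)
  pr <- mesh_projector(fit$mesh, cells[ok, , drop = FALSE], strict = FALSE)
  cells_ok <- which(ok)[pr$ok]
  pred <- predict.svc_fit(fit, cells[cells_ok, , drop = FALSE])
  form <- classify_form(pred$beta_q2.5, pred$beta_q97.5)
  v <- vals[cells_ok]
  rows <- lapply(levels(form), function(f) {
    vf <- v[form == f]
    if (!length(vf))
      return(data.frame(form = f, n = 0L, min = NA, q25 = NA, median = NA,
                        q75 = NA, max = NA, n_outliers = 0L))
    q <- stats::quantile(vf, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    iqr <- q[4] - q[2]
    out_n <- sum(vf < q[2] - 1.5 * iqr | vf > q[4] + 1.5 * iqr)
    data.frame(form = f, n = length(vf), min = q[1], q25 = q[2],
               median = q[3], q75 = q[4], max = q[5], n_outliers = out_n)
  })
  out <- do.call(rbind, rows)
  attr(out, "cells") <- data.frame(x_km = cells[cells_ok, 1],
                                   y_km = cells[cells_ok, 2],
                                   value = v, form = form)
  class(out) <- c("form_summary", class(out))
  out
}

#' @export
plot.form_summary <- function(x, ...) {
  cells <- attr(x, "cells")
  graphics::boxplot(value ~ form, data = cells, outline = FALSE,
                    xlab = "relationship form", ylab = "measure value", ...)
  invisible(x)
}
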