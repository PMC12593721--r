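#' @export
print.svc_fit <- function(x, ...) {
  cat("Spatially varying coefficient model fit\n")
  cat("  ", deparse(x$formula), " on ", x$n_obs, " sites, mesh of ",
      x$n_vertices, " vertices\n", sep = "")
  rs <- posterior_range_summary(x, "beta")
  cat("  slope-field spatial range (km): median ", round(rs["median"]),
      " [", round(rs["q2.5"]), ", ", round(rs["q97.5"]), "]\n", sep = "")
  if (!x$converged)
    cat("  WARNING: fit flagged: ", paste(x$flags, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Posterior summaries of an SVC fit
#'
#' @param object An \code{svc_fit}.
#' @param ... Unused.
#' @return A list of class \code{summary.svc_fit} with hyperparameter and
#'   fixed-effect quantiles and convergence diagnostics.
#' @export
summary.svc_fit <- function(object, ...) {
  qs <- function(v) stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
  th <- hyper_draws(object)
  hp <- t(apply(th, 2, qs))
  hp <- rbind(hp, noise_sd = qs(1 / sqrt(th[, "noise_prec"])))
  fx <- t(apply(latent_fixed(object), 1, qs))
  rownames(fx) <- c("mean_intercept", "mean_slope")
  colnames(hp) <- colnames(fx) <- c("q2.5", "median", "q97.5")
  structure(list(call = object$call, n_obs = object$n_obs,
                 n_vertices = object$n_vertices, hyper = hp, fixed = fx,
                 ess = object$ess, converged = object$converged,
                 flags = object$flags),
            class = "summary.svc_fit")
}

#' @export
print.summary.svc_fit <- function(x, ...) {
  cat("SVC model: ", x$n_obs, " sites, ", x$n_vertices,
      " mesh vertices\n\nHyperparameters (posterior quantiles):\n", sep = "")
  print(round(x$hyper, 3))
  cat("\nFixed effects:\n")
  print(round(x$fixed, 3))
  cat("\nImportance-sampling ESS: ", round(x$ess, 1),
      if (x$converged) "  (converged)" else
        paste0("  FLAGS: ", paste(x$flags, collapse = ", ")), "\n", sep = "")
  invisible(x)
}

#' @export
coef.svc_fit <- function(object, ...) {
  fx <- latent_fixed(object)
  c(mean_intercept = stats::median(fx[1, ]),
    mean_slope = stats::median(fx[2, ]))
}

#' Posterior medians and residuals at the data sites
#'
#' \code{fitted} returns the posterior median of the linear predictor;
#' \code{residuals} the observed response minus it.
#'
#' @param object An \code{svc_fit}.
#' @param ... Unused.
#' @export
fitted.svc_fit <- function(object, ...) {
  apply(fitted_draws(object), 1, stats::median)
}

#' @rdname fitted.svc_fit
#' @export
residuals.svc_fit <- function(object, ...) {
  object$y - fitted.svc_fit(object)
}

#' Posterior predictions of coefficient surfaces or the response
#'
#' For \code{what = "coefficients"} (the default), returns per-location
#' posterior median and 95% credible bounds of the intercept and slope
#' surfaces (fixed mean level plus spatial field, interpolated through the
#' mesh projector). For \code{what = "response"}, a covariate value per
#' location must be supplied in \code{pm} and the linear predictor is
#' summarized instead.
#'
#' @param object An \code{svc_fit}.
#' @param locations m x 2 matrix of (x_km, y_km); defaults to the data
#'   sites. Must lie inside the mesh.
#' @param what "coefficients" or "response".
#' @param pm Covariate values for response prediction.
#' @param ... Unused.
#' @return Data frame with columns x_km, y_km and, per requested surface,
#'   median/q2.5/q97.5.
#' @export
predict.svc_fit <- function(object, locations = NULL,
                            what = c("coefficients", "response"), pm = NULL,
                            ...) {
  what <- match.arg(what)
  if (is.null(locations)) locations <- object$loc
  locations <- matrix(as.matrix(locations), ncol = 2)
  Ap <- mesh_projector(object$mesh, locations)
  fx <- latent_fixed(object)
  ad <- as.matrix(Ap %*% latent_alpha(object)) +
    rep(1, nrow(locations)) %o% fx[1, ]
  bd <- as.matrix(Ap %*% latent_beta(object)) +
    rep(1, nrow(locations)) %o% fx[2, ]
  qs <- function(m) t(apply(m, 1, stats::quantile, c(0.5, 0.025, 0.975),
                            names = FALSE))
  out <- data.frame(x_km = locations[, 1], y_km = locations[, 2])
  if (what == "coefficients") {
    qa <- qs(ad); qb <- qs(bd)
    out$alpha_median <- qa[, 1]; out$alpha_q2.5 <- qa[, 2]
    out$alpha_q97.5 <- qa[, 3]
    out$beta_median <- qb[, 1]; out$beta_q2.5 <- qb[, 2]
    out$beta_q97.5 <- qb[, 3]
  } else {
    stopifnot(!is.null(pm), length(pm) == nrow(locations))
    qr <- qs(ad + pm * bd)
    out$response_median <- qr[, 1]; out$response_q2.5 <- qr[, 2]
    out$response_q97.5 <- qr[, 3]
  }
  out
}

#' Per-location coefficient posterior summaries
#'
#' Convenience wrapper around [predict.svc_fit()] returning the intercept
#' and slope surfaces at arbitrary locations.
#'
#' @param fit An \code{svc_fit}.
#' @param locations m x 2 coordinate matrix (km) inside the mesh.
#' @return Data frame from \code{predict(fit, locations)}.
#' @export
predict_coefficients <- function(fit, locations) {
  predict.svc_fit(fit, locations)
}

#' Posterior quantiles of a spatial range
#'
#' @param fit An \code{svc_fit}.
#' @param field "alpha" (intercept field) or "beta" (slope field; the
#'   geographic scale at which the covariate effect changes).
#' @param probs Quantile probabilities.
#' @return Named numeric vector (by default q2.5, median, q97.5) in km.
#' @export
posterior_range_summary <- function(fit, field = c("beta", "alpha"),
                                    probs = c(0.025, 0.5, 0.975)) {
  field <- match.arg(field)
  v <- hyper_draws(fit)[, paste0("range_", field)]
  out <- stats::quantile(v, probs, names = FALSE)
  names(out) <- ifelse(probs == 0.5, "median",
                       paste0("q", formatC(100 * probs, format = "fg")))
  out
}

#' Posterior predictive simulation at the data sites
#'
#' Draws replicate response vectors \eqn{y^{rep}} from the fitted model:
#' linear-predictor draws plus Gaussian noise at the drawn precision.
#'
#' @param object An \code{svc_fit}.
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Data frame (n_obs x nsim), as [stats::simulate()] conventions.
#' @export
simulate.svc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  ndr <- nrow(object$theta_draws)
  pick <- with_preserved_seed(if (is.null(seed)) 1L else seed, {
    ks <- sample.int(ndr, nsim, replace = TRUE)
    eps <- matrix(stats::rnorm(object$n_obs * nsim), object$n_obs)
    list(ks = ks, eps = eps)
  })
  fd <- fitted_draws(object)
  tau <- hyper_draws(object)[, "noise_prec"]
  out <- sapply(seq_len(nsim), function(j) {
    k <- pick$ks[j]
    fd[, k] + pick$eps[, j] / sqrt(tau[k])
  })
  as.data.frame(out)
}

#' Residual diagnostics: fitted-value plot inputs and an empirical variogram
#'
#' Computes posterior-median residuals, an empirical semivariogram on
#' distance bins, and a Monte-Carlo envelope obtained by permuting the
#' residuals over the site locations (which destroys any spatial structure
#' while keeping the marginal distribution). A well-specified model should
#' have its variogram inside the envelope: no residual spatial
#' autocorrelation.
#'
#' @param fit An \code{svc_fit}.
#' @param n_bins Number of distance bins.
#' @param max_lag_km Largest lag considered; default half the maximum
#'   inter-site distance.
#' @param n_perm Permutations for the envelope.
#' @param seed Integer seed for the permutations.
#' @return List of class \code{svc_diagnostics}: \code{residuals},
#'   \code{fitted}, and \code{variogram} (data frame with bin centers,
#'   semivariance, pair counts, and envelope bounds).
#' @export
residual_diagnostics <- function(fit, n_bins = 12, max_lag_km = NULL,
                                 n_perm = 199, seed = 1L) {
  r <- residuals.svc_fit(fit)
  f <- fitted.svc_fit(fit)
  D <- as.matrix(stats::dist(fit$loc))
  if (is.null(max_lag_km)) max_lag_km <- max(D) / 2
  pair <- which(upper.tri(D) & D <= max_lag_km, arr.ind = TRUE)
  d <- D[pair]
  breaks <- seq(0, max_lag_km, length.out = n_bins + 1)
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  gamma_of <- function(res) {
    sq <- 0.5 * (res[pair[, 1]] - res[pair[, 2]])^2
    tapply(sq, bin, mean)
  }
  g <- gamma_of(r)
  counts <- tabulate(bin, nbins = n_bins)
  perms <- with_preserved_seed(seed, {
    replicate(n_perm, gamma_of(r[sample.int(length(r))]))
  })
  lo <- apply(perms, 1, stats::quantile, 0.025, na.rm = TRUE)
  hi <- apply(perms, 1, stats::quantile, 0.975, na.rm = TRUE)
  vg <- data.frame(lag_km = (breaks[-1] + breaks[-length(breaks)]) / 2,
                   semivariance = as.numeric(g), n_pairs = counts,
                   env_lo = lo, env_hi = hi)
  structure(list(residuals = r, fitted = f, variogram = vg,
                 max_lag_km = max_lag_km),
            class = "svc_diagnostics")
}

#' @export
plot.svc_fit <- function(x, ...) {
  dg <- residual_diagnostics(x)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(dg$fitted, dg$residuals, xlab = "fitted", ylab = "residual",
       main = "Residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  vg <- dg$variogram
  plot(vg$lag_km, vg$semivariance, type = "b", xlab = "lag (km)",
       ylab = "semivariance", main = "Residual variogram",
       ylim = range(c(vg$semivariance, vg$env_lo, vg$env_hi), na.rm = TRUE))
  graphics::lines(vg$lag_km, vg$env_lo, lty = 3)
  graphics::lines(vg$lag_km, vg$env_hi, lty = 3)
  invisible(x)
}
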