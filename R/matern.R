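#' Matern correlation function
#'
#' Correlation of a Matern Gaussian field at a given separation distance,
#' parameterized by the spatial range \code{range_km} under the convention
#' \eqn{\kappa = \sqrt{8\nu} / \rho}, for which the correlation at distance
#' equal to the range is approximately 0.13 (for \eqn{\nu = 1}). This is the
#' convention under which a penalized-complexity prior statement such as
#' "probability 0.5 that the range exceeds 2,243 km" is interpretable.
#'
#' @param distance_km Non-negative distance(s) in km.
#' @param range_km Spatial range \eqn{\rho} in km (positive scalar).
#' @param nu Matern smoothness \eqn{\nu} (positive scalar, default 1, the
#'   standard choice for the SPDE representation with \eqn{\alpha = 2} in 2-D).
#' @return Correlation values in \eqn{[0, 1]}, same length as
#'   \code{distance_km}; exactly 1 at distance 0.
#' @examples
#' matern_correlation(0, 100)            # 1
#' matern_correlation(100, 100)          # ~0.139
#' matern_correlation(100, 100, nu = 0.5) # exp(-2)
#' @export
matern_correlation <- function(distance_km, range_km, nu = 1) {
  stopifnot(is.numeric(distance_km), all(distance_km >= 0),
            length(range_km) == 1L, range_km > 0,
            length(nu) == 1L, nu > 0)
  kappa <- sqrt(8 * nu) / range_km
  h <- kappa * distance_km
  out <- numeric(length(h))
  pos <- h > 0
  # 2^(1-nu)/Gamma(nu) * h^nu * K_nu(h); besselK underflows for large h -> 0
  hk <- h[pos]
  v <- 2^(1 - nu) / gamma(nu) * hk^nu * besselK(hk, nu)
  v[!is.finite(v)] <- 0
  out[pos] <- pmin(1, pmax(0, v))
  out[!pos] <- 1
  dim(out) <- dim(distance_km)
  out
}

#' Penalized-complexity prior for the spatial range of a 2-D Matern field
#'
#' The PC prior for the range \eqn{\rho} of a Matern field in two dimensions
#' has survival function \eqn{P(\rho > r) = 1 - \exp(-\lambda / r)} with
#' \eqn{\lambda} calibrated from a tail statement
#' \eqn{P(\rho > \rho_0) = \alpha}: \eqn{\lambda = -\rho_0 \log(1 - \alpha)}.
#' With \eqn{\alpha = 0.5} the prior median equals \eqn{\rho_0} exactly.
#'
#' @param rho0 Threshold range in km (positive).
#' @param alpha_prob Exceedance probability \eqn{P(\rho > \rho_0)}, in (0, 1).
#' @return An object of class \code{pc_prior_range} with functions
#'   \code{log_density(rho)}, \code{cdf(rho)} and \code{quantile(p)}, plus the
#'   calibrated \code{lambda}.
#' @examples
#' pr <- pc_prior_range(2243, 0.5)
#' pr$quantile(0.5)  # 2243
#' @export
pc_prior_range <- function(rho0, alpha_prob) {
  stopifnot(length(rho0) == 1L, rho0 > 0,
            length(alpha_prob) == 1L, alpha_prob > 0, alpha_prob < 1)
  lambda <- -rho0 * log1p(-alpha_prob)
  structure(list(
    lambda = lambda, rho0 = rho0, alpha_prob = alpha_prob,
    log_density = function(rho) {
      ifelse(rho > 0, log(lambda) - 2 * log(rho) - lambda / rho, -Inf)
    },
    cdf = function(rho) ifelse(rho > 0, exp(-lambda / rho), 0),
    quantile = function(p) {
      stopifnot(all(p > 0 & p < 1))
      -lambda / log(p)
    }
  ), class = "pc_prior_range")
}

#' Penalized-complexity prior for the marginal standard deviation
#'
#' Exponential PC prior on the marginal standard deviation \eqn{\sigma} of a
#' Gaussian field: \eqn{P(\sigma > s) = \exp(-\lambda s)} with
#' \eqn{\lambda = -\log(\alpha) / \sigma_0} so that
#' \eqn{P(\sigma > \sigma_0) = \alpha}. With \eqn{\sigma_0 = 1},
#' \eqn{\alpha = 0.5}, the median is exactly 1 and \eqn{\lambda = \log 2}.
#'
#' @param sigma0 Threshold standard deviation (positive).
#' @param alpha_prob Exceedance probability \eqn{P(\sigma > \sigma_0)}.
#' @return An object of class \code{pc_prior_sd} with \code{log_density},
#'   \code{cdf}, \code{quantile} and the rate \code{lambda}.
#' @examples
#' ps <- pc_prior_sd(1, 0.5)
#' ps$quantile(0.5)  # 1
#' @export
pc_prior_sd <- function(sigma0, alpha_prob) {
  stopifnot(length(sigma0) == 1L, sigma0 > 0,
            length(alpha_prob) == 1L, alpha_prob > 0, alpha_prob < 1)
  lambda <- -log(alpha_prob) / sigma0
  structure(list(
    lambda = lambda, sigma0 = sigma0, alpha_prob = alpha_prob,
    log_density = function(sigma) {
      ifelse(sigma >= 0, log(lambda) - lambda * sigma, -Inf)
    },
    cdf = function(sigma) ifelse(sigma >= 0, 1 - exp(-lambda * sigma), 0),
    quantile = function(p) {
      stopifnot(all(p > 0 & p < 1))
      -log1p(-p) / lambda
    }
  ), class = "pc_prior_sd")
}
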