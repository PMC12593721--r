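#' Prior configuration for the SVC model
#'
#' Penalized-complexity priors on the Matern hyperparameters of both latent
#' fields and a Gamma prior on the observation noise precision. Defaults are
#' the continental-analysis settings: P(range > 2,243 km) = 0.5 (half the
#' maximum inter-route distance in the motivating study), P(sd > 1) = 0.5,
#' and noise precision ~ Gamma(shape = 1, rate = 1e-5) (an essentially flat
#' log-gamma prior on the log precision).
#'
#' @param range_rho0,range_prob PC range prior: P(range > rho0) = prob.
#' @param sd_sigma0,sd_prob PC sd prior: P(sd > sigma0) = prob.
#' @param noise_shape,noise_rate Gamma prior on the noise precision.
#' @param fixed_prec Gaussian prior precision on the two fixed effects
#'   (overall intercept and mean slope); small = vague.
#' @return List of class \code{svc_priors}.
#' @export
svc_priors <- function(range_rho0 = 2243, range_prob = 0.5,
                       sd_sigma0 = 1, sd_prob = 0.5,
                       noise_shape = 1, noise_rate = 1e-5,
                       fixed_prec = 1e-6) {
  structure(list(range = pc_prior_range(range_rho0, range_prob),
                 sd = pc_prior_sd(sd_sigma0, sd_prob),
                 noise_shape = noise_shape, noise_rate = noise_rate,
                 fixed_prec = fixed_prec),
            class = "svc_priors")
}

#' Inference controls for [fit_svc()]
#'
#' @param seed Integer seed driving proposal draws, resampling and latent
#'   sampling (mandatory for reproducibility).
#' @param n_importance Hyperparameter proposals evaluated for importance
#'   resampling.
#' @param n_draws Posterior draws retained (hyperparameters + latents).
#' @param max_opt_iter Nelder-Mead iteration cap for the mode search.
#' @param proposal_df,proposal_scale Multivariate-t proposal: degrees of
#'   freedom and scale inflation of the Laplace covariance.
#' @param min_ess Importance-sampling effective sample size below which the
#'   fit is flagged as not converged.
#' @return List of class \code{svc_control}.
#' @export
svc_control <- function(seed, n_importance = 300, n_draws = 250,
                        max_opt_iter = 500, proposal_df = 5,
                        proposal_scale = 1.4, min_ess = 30) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(seed = as.integer(seed), n_importance = n_importance,
                 n_draws = n_draws, max_opt_iter = max_opt_iter,
                 proposal_df = proposal_df, proposal_scale = proposal_scale,
                 min_ess = min_ess),
            class = "svc_control")
}

# ---- engine internals -----------------------------------------------------

# names and order of the hyperparameter vector (log scale)
THETA_NAMES <- c("log_range_alpha", "log_sd_alpha", "log_range_beta",
                 "log_sd_beta", "log_noise_prec")

# precompute everything the marginal likelihood needs: aligned sparse
# x-slot vectors so each evaluation assembles the posterior precision by
# pure vector arithmetic, and the generalized eigenvalues of the stiffness
# pencil so the field log-determinant is closed form
build_engine <- function(y, pm, A, mesh, priors) {
  n <- length(y)
  nv <- nrow(mesh$loc)
  fem <- fem_matrices(mesh)
  DA <- Matrix::Diagonal(x = pm) %*% A
  M <- cbind(A, DA, Matrix::Matrix(cbind(1, pm), sparse = TRUE))
  M <- as(M, "CsparseMatrix")
  MtM <- Matrix::forceSymmetric(Matrix::crossprod(M))
  Mty <- as.vector(Matrix::crossprod(M, y))

  # field-block template on the union sparsity pattern
  Uf <- as(Matrix::forceSymmetric(Matrix::Diagonal(x = fem$c0) + fem$g1 +
                                  fem$g2), "CsparseMatrix")
  trip <- function(S) {
    S <- as(Matrix::forceSymmetric(S), "CsparseMatrix")
    s <- Matrix::summary(S)
    s[s$i <= s$j, , drop = FALSE]
  }
  posmat <- Uf
  posmat@x <- as.numeric(seq_along(Uf@x))
  align_f <- function(S) {
    tr <- trip(S)
    v <- numeric(length(Uf@x))
    v[round(posmat[cbind(tr$i, tr$j)])] <- tr$x
    v
  }
  xC <- align_f(Matrix::Diagonal(x = fem$c0))
  xG <- align_f(fem$g1)
  xG2 <- align_f(fem$g2)

  # full posterior-precision template: two field blocks + fixed effects +
  # the data term
  U <- Matrix::forceSymmetric(
    Matrix::bdiag(Uf, Uf, Matrix::Diagonal(2)) + MtM)
  U <- as(U, "CsparseMatrix")
  posU <- U
  posU@x <- as.numeric(seq_along(U@x))
  tf <- trip(Uf)
  pos_f1 <- round(posU[cbind(tf$i, tf$j)])
  pos_f2 <- round(posU[cbind(tf$i + nv, tf$j + nv)])
  pos_fix <- round(posU[cbind(2L * nv + 1:2, 2L * nv + 1:2)])
  tm <- trip(MtM)
  xMtM <- numeric(length(U@x))
  xMtM[round(posU[cbind(tm$i, tm$j)])] <- tm$x

  # generalized eigenvalues: logdet(k^4 C + 2 k^2 G + G C^-1 G)
  #   = sum(log c0) + 2 sum log(k^2 + eig(C^-1/2 G C^-1/2))
  B <- Matrix::Diagonal(x = 1 / sqrt(fem$c0)) %*% fem$g1 %*%
    Matrix::Diagonal(x = 1 / sqrt(fem$c0))
  ev <- eigen(as.matrix(Matrix::forceSymmetric(B)), symmetric = TRUE,
              only.values = TRUE)$values
  ev <- pmax(ev, 0)

  chP <- Matrix::Cholesky(U + Matrix::Diagonal(nrow(U)), LDL = FALSE)
  list(y = y, pm = pm, n = n, nv = nv, fem = fem, mesh = mesh, A = A, M = M,
       MtM = MtM, Mty = Mty, yty = sum(y^2), chP = chP, priors = priors,
       U = U, xC = xC, xG = xG, xG2 = xG2, xMtM = xMtM,
       pos_f1 = pos_f1, pos_f2 = pos_f2, pos_fix = pos_fix,
       ev = ev, sum_log_c0 = sum(log(fem$c0)))
}

chm_logdet <- function(ch) 2 * Matrix::determinant(ch, sqrt = TRUE)$modulus

# x-slot of the field precision on the engine template, plus its logdet
field_parts <- function(eng, range_km, sd) {
  kappa2 <- 8 / range_km^2
  tau2 <- 1 / (4 * pi * kappa2 * sd^2)
  list(x = tau2 * (kappa2^2 * eng$xC + 2 * kappa2 * eng$xG + eng$xG2),
       logdet = eng$nv * log(tau2) + eng$sum_log_c0 +
         2 * sum(log(kappa2 + eng$ev)))
}

# log p(y | theta) with latents and fixed effects integrated out; optionally
# also returns the conditional mean/Cholesky of the latent posterior
marginal_loglik_engine <- function(eng, theta, keep_factor = FALSE) {
  ra <- exp(theta[1]); sa <- exp(theta[2])
  rb <- exp(theta[3]); sb <- exp(theta[4])
  tau_e <- exp(theta[5])
  if (!all(is.finite(c(ra, sa, rb, sb, tau_e)))) return(list(ll = -Inf))
  fa <- field_parts(eng, ra, sa)
  fb <- field_parts(eng, rb, sb)
  ld_prior <- fa$logdet + fb$logdet + 2 * log(eng$priors$fixed_prec)
  xU <- tau_e * eng$xMtM
  xU[eng$pos_f1] <- xU[eng$pos_f1] + fa$x
  xU[eng$pos_f2] <- xU[eng$pos_f2] + fb$x
  xU[eng$pos_fix] <- xU[eng$pos_fix] + eng$priors$fixed_prec
  Qpost <- eng$U
  Qpost@x <- xU
  # CHOLMOD signals an indefinite matrix as a warning from update(); treat
  # warnings as factorization failures, not as usable factors
  ch <- tryCatch(Matrix::update(eng$chP, Qpost),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  b <- tau_e * eng$Mty
  mu <- as.vector(Matrix::solve(ch, b, system = "A"))
  ll <- 0.5 * ld_prior - 0.5 * chm_logdet(ch) +
    0.5 * eng$n * log(tau_e) - 0.5 * eng$n * log(2 * pi) -
    0.5 * tau_e * eng$yty + 0.5 * sum(b * mu)
  out <- list(ll = as.numeric(ll))
  if (keep_factor) { out$mu <- mu; out$chol <- ch }
  out
}

log_posterior_engine <- function(eng, theta) {
  ll <- marginal_loglik_engine(eng, theta)$ll
  if (!is.finite(ll)) return(-Inf)
  pr <- eng$priors
  ra <- exp(theta[1]); sa <- exp(theta[2])
  rb <- exp(theta[3]); sb <- exp(theta[4]); tau_e <- exp(theta[5])
  lp <- pr$range$log_density(ra) + theta[1] +
        pr$sd$log_density(sa) + theta[2] +
        pr$range$log_density(rb) + theta[3] +
        pr$sd$log_density(sb) + theta[4] +
        stats::dgamma(tau_e, pr$noise_shape, rate = pr$noise_rate,
                      log = TRUE) + theta[5]
  ll + lp
}

# central-difference Hessian (falls back when numDeriv is unavailable)
fd_hessian <- function(f, x, h = 1e-3) {
  if (requireNamespace("numDeriv", quietly = TRUE))
    return(numDeriv::hessian(f, x))
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < d) for (j in (i + 1):d) {
      ej <- replace(numeric(d), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

systematic_resample <- function(w, n, seed) {
  w <- w / sum(w)
  u <- with_preserved_seed(seed, stats::runif(1)) / n
  cum <- cumsum(w)
  findInterval(u + (seq_len(n) - 1) / n, cum) + 1L
}

# ---- main fitting function ------------------------------------------------

#' Fit a Bayesian spatially varying coefficient model
#'
#' Fits the model \eqn{S_i = \alpha(s_i) + \beta(s_i) PM_i + \varepsilon_i}
#' where the intercept surface \eqn{\alpha} and slope surface \eqn{\beta}
#' are independent Matern Gaussian fields (smoothness 1) represented as
#' finite-element GMRFs on a triangulated mesh, each decomposed into a fixed
#' mean level plus a zero-mean spatial field with its own penalized-
#' complexity priors on range and marginal SD, and
#' \eqn{\varepsilon_i \sim N(0, \tau_\varepsilon^{-1})} with a Gamma prior
#' on \eqn{\tau_\varepsilon}.
#'
#' Inference integrates the Gaussian latents out analytically, locates the
#' hyperparameter posterior mode (Nelder-Mead on the log scale), forms a
#' Laplace approximation there, and corrects it by importance resampling
#' from a multivariate-t proposal; latent fields are then drawn exactly
#' from their Gaussian conditional at each retained hyperparameter draw.
#' Non-convergence (failed mode search or degenerate importance weights) is
#' flagged on the returned object, never silent.
#'
#' @param formula Two-sided formula \code{response ~ covariate} naming one
#'   (already standardized) covariate column.
#' @param data Data frame (e.g. a [route_table()]) containing the formula
#'   variables and coordinates. Rows with \code{retained == FALSE} are
#'   dropped.
#' @param coords Names of the coordinate columns (km), default
#'   \code{c("x_km", "y_km")}.
#' @param mesh An [build_mesh()] result; by default one is built on the
#'   data with \code{max_edge_km} one tenth of the maximum inter-point
#'   distance (the rule used in the motivating analysis).
#' @param priors An [svc_priors()] object.
#' @param control An [svc_control()] object; \code{control$seed} is the
#'   seed for all stochastic steps.
#' @param fix_hyper Optional named list fixing hyperparameters (any of
#'   \code{range_alpha, sd_alpha, range_beta, sd_beta, noise_prec}); when
#'   all five are given the mode search is skipped and inference is
#'   conditional on them (used e.g. for degenerate-limit checks).
#' @return An object of class \code{svc_fit} holding the hyperparameter
#'   draws, latent-field draws, the exact conditional posterior mean of the
#'   latent vector averaged over hyperparameter draws
#'   (\code{latent_mean}), the mesh and projector, and convergence flags;
#'   see [summary.svc_fit()], [predict.svc_fit()],
#'   [posterior_range_summary()].
#' @examples
#' \donttest{
#' cfg <- sim_config(domain_extent = c(0, 2000, 0, 2000), n_routes = 80,
#'                   seed = 7)
#' ds <- simulate_routes_and_richness(cfg, pm_values = rnorm(80))
#' fit <- fit_svc(richness ~ pm_std, ds$routes,
#'                control = svc_control(seed = 1, n_importance = 50,
#'                                      n_draws = 50))
#' summary(fit)
#' }
#' @export
fit_svc <- function(formula, data, coords = c("x_km", "y_km"), mesh = NULL,
                    priors = svc_priors(), control, fix_hyper = NULL) {
  stopifnot(inherits(formula, "formula"), inherits(control, "svc_control"))
  data <- as.data.frame(data)
  if (!is.null(data$retained)) data <- data[data$retained %in% TRUE, ]
  vars <- all.vars(formula)
  if (length(vars) != 2L)
    stop("formula must be response ~ covariate with exactly one covariate")
  y <- data[[vars[1]]]
  pm <- data[[vars[2]]]
  stopifnot(is.numeric(y), is.numeric(pm), all(is.finite(y)),
            all(is.finite(pm)))
  n <- length(y)
  if (n < 30) stop("need at least 30 retained routes, got ", n)
  loc <- as.matrix(data[, coords])
  if (is.null(mesh)) {
    max_edge <- 0.1 * max(stats::dist(loc))
    mesh <- build_mesh(loc, max_edge_km = max_edge)
  }
  A <- mesh_projector(mesh, loc)
  eng <- build_engine(y, pm, A, mesh, priors)
  lp <- function(theta) log_posterior_engine(eng, theta)

  flags <- character(0)
  if (!is.null(fix_hyper)) {
    need <- c("range_alpha", "sd_alpha", "range_beta", "sd_beta",
              "noise_prec")
    miss <- setdiff(need, names(fix_hyper))
    if (length(miss)) stop("fix_hyper missing: ", paste(miss, collapse = ", "))
    mode <- log(unlist(fix_hyper[need]))
    names(mode) <- THETA_NAMES
    theta_draws <- matrix(rep(mode, control$n_draws), ncol = 5, byrow = TRUE)
    ess <- control$n_draws
    opt_conv <- 0L
  } else {
    theta0 <- c(log(priors$range$rho0 / 2), log(priors$sd$sigma0),
                log(priors$range$rho0 / 2), log(priors$sd$sigma0),
                log(2 / stats::var(y)))
    opt <- stats::optim(theta0, lp, method = "Nelder-Mead",
                        control = list(fnscale = -1,
                                       maxit = control$max_opt_iter,
                                       reltol = 1e-8))
    # restart once from the incumbent: Nelder-Mead on flat ridges benefits
    # from a fresh simplex
    opt <- stats::optim(opt$par, lp, method = "Nelder-Mead",
                        control = list(fnscale = -1,
                                       maxit = control$max_opt_iter,
                                       reltol = 1e-8))
    mode <- opt$par
    names(mode) <- THETA_NAMES
    opt_conv <- opt$convergence
    if (opt_conv != 0) flags <- c(flags, "mode_search_not_converged")
    H <- fd_hessian(lp, mode)
    Sigma <- tryCatch(solve(-(H + t(H)) / 2), error = function(e) NULL)
    ok_sigma <- !is.null(Sigma) && all(is.finite(Sigma)) &&
      all(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values > 0)
    if (!ok_sigma) {
      flags <- c(flags, "hessian_not_positive_definite")
      Sigma <- diag(0.25, 5)
    }
    # adaptive importance sampling: when the Laplace proposal misses the
    # posterior shape (flat or skewed hyperparameter surfaces), re-estimate
    # the proposal moments from the weighted draws and redraw
    prop_mean <- mode
    Sigma_p <- control$proposal_scale^2 * (Sigma + t(Sigma)) / 2
    best <- NULL
    for (round in 1:4) {
      prop <- with_preserved_seed(sub_seed(control$seed, 80L + round), {
        mvtnorm::rmvt(control$n_importance, sigma = Sigma_p,
                      df = control$proposal_df, delta = prop_mean)
      })
      lq <- mvtnorm::dmvt(prop, delta = prop_mean, sigma = Sigma_p,
                          df = control$proposal_df, log = TRUE)
      lpost <- apply(prop, 1L, lp)
      lw <- lpost - lq
      lw[!is.finite(lw)] <- -Inf
      if (!any(is.finite(lw))) next
      w <- exp(lw - max(lw))
      ess <- sum(w)^2 / sum(w^2)
      if (is.null(best) || ess > best$ess)
        best <- list(prop = prop, w = w, ess = ess)
      if (best$ess >= control$min_ess) break
      wn <- best$w / sum(best$w)
      prop_mean <- colSums(best$prop * wn)
      cen <- sweep(best$prop, 2, prop_mean)
      Sw <- crossprod(cen * sqrt(wn)) / (1 - sum(wn^2))
      Sigma_p <- control$proposal_scale^2 *
        ((Sw + t(Sw)) / 2 + diag(1e-4, length(mode)))
    }
    if (is.null(best))
      stop("all importance weights are zero; hyperparameter posterior ",
           "could not be explored from the mode at (",
           paste(signif(exp(mode), 4), collapse = ", "), ")")
    ess <- best$ess
    if (ess < control$min_ess) flags <- c(flags, "low_importance_ess")
    idx <- systematic_resample(best$w, control$n_draws,
                               seed = sub_seed(control$seed, 91L))
    theta_draws <- best$prop[idx, , drop = FALSE]
    colnames(theta_draws) <- THETA_NAMES
  }

  # exact Gaussian draws of (alpha nodes, beta nodes, fixed effects) per
  # unique hyperparameter draw
  nv <- eng$nv
  p <- 2L * nv + 2L
  latent <- matrix(NA_real_, p, nrow(theta_draws))
  latent_mean <- numeric(p)
  key <- apply(theta_draws, 1, paste, collapse = ",")
  zs <- with_preserved_seed(sub_seed(control$seed, 92L),
                            matrix(stats::rnorm(p * nrow(theta_draws)), p))
  for (k in unique(key)) {
    rows <- which(key == k)
    cond <- marginal_loglik_engine(eng, theta_draws[rows[1], ],
                                   keep_factor = TRUE)
    latent_mean <- latent_mean + cond$mu * length(rows)
    if (!is.finite(cond$ll))
      stop("latent conditional failed at hyperparameters (",
           paste(signif(exp(theta_draws[rows[1], ]), 4), collapse = ", "), ")")
    for (r in rows) {
      pert <- Matrix::solve(cond$chol,
                            Matrix::solve(cond$chol, zs[, r], system = "Lt"),
                            system = "Pt")
      latent[, r] <- cond$mu + as.vector(pert)
    }
  }

  structure(list(
    call = match.call(), formula = formula, coords = coords,
    y = y, pm = pm, loc = loc, mesh = mesh, A = A, priors = priors,
    control = control, mode = mode,
    theta_draws = theta_draws, latent_draws = latent,
    latent_mean = latent_mean / nrow(theta_draws),
    n_vertices = nv, n_obs = n,
    converged = length(flags) == 0L, flags = flags, ess = ess,
    opt_convergence = opt_conv
  ), class = "svc_fit")
}

# hyperparameter draws on the natural scale
hyper_draws <- function(fit) {
  th <- exp(fit$theta_draws)
  colnames(th) <- c("range_alpha", "sd_alpha", "range_beta", "sd_beta",
                    "noise_prec")
  th
}

# latent block accessors
latent_alpha <- function(fit) fit$latent_draws[seq_len(fit$n_vertices), ,
                                               drop = FALSE]
latent_beta <- function(fit)
  fit$latent_draws[fit$n_vertices + seq_len(fit$n_vertices), , drop = FALSE]
latent_fixed <- function(fit)
  fit$latent_draws[2L * fit$n_vertices + 1:2, , drop = FALSE]

# draws of the linear predictor at the data locations
fitted_draws <- function(fit) {
  fx <- latent_fixed(fit)
  as.matrix(fit$A %*% latent_alpha(fit)) +
    fit$pm * as.matrix(fit$A %*% latent_beta(fit)) +
    rep(1, fit$n_obs) %o% fx[1, ] + fit$pm %o% fx[2, ]
}

#' Marginal log-likelihood of the SVC model under fixed hyperparameters
#'
#' Computes \eqn{\log p(y \mid \theta)} with the latent Gaussian fields
#' integrated out, through the sparse SPDE-GMRF representation. With
#' \code{include_fixed = FALSE} the model has no fixed effects (pure
#' zero-mean fields), which is the form directly comparable to a dense
#' Matern Gaussian-process likelihood
#' \eqn{y \sim N(0, \sigma_\alpha^2 R_\alpha + D \sigma_\beta^2 R_\beta D
#' + \tau_\varepsilon^{-1} I)} evaluated with the closed-form correlation.
#'
#' @param y Response vector.
#' @param pm Covariate vector (same length).
#' @param loc n x 2 coordinates (km).
#' @param mesh An \code{svc_mesh} covering the locations.
#' @param range_alpha,sd_alpha,range_beta,sd_beta,noise_prec Hyperparameter
#'   values.
#' @param include_fixed Include vague-prior fixed effects (as in
#'   [fit_svc()]); default \code{FALSE}.
#' @param fixed_prec Fixed-effect prior precision when included.
#' @return Scalar log-likelihood.
#' @export
svc_marginal_loglik <- function(y, pm, loc, mesh, range_alpha, sd_alpha,
                                range_beta, sd_beta, noise_prec,
                                include_fixed = FALSE, fixed_prec = 1e-6) {
  A <- mesh_projector(mesh, loc)
  if (include_fixed) {
    eng <- build_engine(y, pm, A, mesh, svc_priors(fixed_prec = fixed_prec))
    return(marginal_loglik_engine(
      eng, log(c(range_alpha, sd_alpha, range_beta, sd_beta, noise_prec)))$ll)
  }
  fem <- fem_matrices(mesh)
  Qa <- spde_precision(mesh, range_alpha, sd_alpha, fem = fem)
  Qb <- spde_precision(mesh, range_beta, sd_beta, fem = fem)
  DA <- Matrix::Diagonal(x = pm) %*% A
  M <- as(cbind(A, DA), "CsparseMatrix")
  Qprior <- Matrix::forceSymmetric(Matrix::bdiag(Qa, Qb))
  Qpost <- Matrix::forceSymmetric(Qprior + noise_prec * Matrix::crossprod(M))
  chpr <- chol_with_jitter(Qprior)$chol
  chpo <- chol_with_jitter(Qpost)$chol
  b <- noise_prec * as.vector(Matrix::crossprod(M, y))
  mu <- as.vector(Matrix::solve(chpo, b, system = "A"))
  n <- length(y)
  as.numeric(chm_logdet(chpr) / 2 - chm_logdet(chpo) / 2 +
             0.5 * n * log(noise_prec) - 0.5 * n * log(2 * pi) -
             0.5 * noise_prec * sum(y^2) + 0.5 * sum(b * mu))
}
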