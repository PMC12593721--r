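#' Finite-element matrices for the SPDE representation
#'
#' Piecewise-linear finite-element matrices on a triangulated mesh: the
#' lumped mass matrix C (diagonal, row sums of the consistent mass matrix)
#' and the stiffness matrix G. These are the building blocks of the sparse
#' Gaussian Markov random field precision that approximates a Matern field
#' (smoothness nu = 1, SPDE order alpha = 2 in two dimensions).
#'
#' @param mesh An \code{svc_mesh}.
#' @return List with \code{c0} (diagonal of C as a vector), \code{g1} (G,
#'   sparse), and \code{g2} (\eqn{G C^{-1} G}, sparse).
#' @export
fem_matrices <- function(mesh) {
  V <- mesh$loc; tt <- mesh$tt
  nv <- nrow(V); nt <- nrow(tt)
  p1 <- V[tt[, 1], , drop = FALSE]
  p2 <- V[tt[, 2], , drop = FALSE]
  p3 <- V[tt[, 3], , drop = FALSE]
  e1 <- p3 - p2; e2 <- p1 - p3; e3 <- p2 - p1
  area <- 0.5 * (e3[, 1] * (-e2[, 2]) - e3[, 2] * (-e2[, 1]))
  if (any(!is.finite(area)) || any(abs(area) < 1e-12)) {
    bad <- which(!is.finite(area) | abs(area) < 1e-12)[1]
    stop("degenerate triangle in mesh (index ", bad, ")")
  }
  area <- abs(area)
  # stiffness: G_ij = sum_T (grad phi_i . grad phi_j) |T|,
  # grad phi_k = rot90(opposite edge) / (2 |T|)
  ii <- jj <- xx <- vector("list", 9)
  E <- list(e1, e2, e3)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    ii[[k]] <- tt[, a]; jj[[k]] <- tt[, b]
    xx[[k]] <- rowSums(E[[a]] * E[[b]]) / (4 * area)
  }
  G <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nv, nv))
  G <- Matrix::forceSymmetric((G + Matrix::t(G)) / 2)
  c0 <- as.vector(Matrix::sparseMatrix(i = as.vector(tt),
                                       j = rep(1L, 3 * nt),
                                       x = rep(area / 3, 3),
                                       dims = c(nv, 1)))
  Cinv <- Matrix::Diagonal(x = 1 / c0)
  g2 <- Matrix::forceSymmetric(G %*% Cinv %*% G)
  list(c0 = c0, g1 = G, g2 = g2)
}

#' Sparse SPDE precision matrix of a Matern field on a mesh
#'
#' Assembles \eqn{Q = \tau^2 (\kappa^4 C + 2 \kappa^2 G + G C^{-1} G)} with
#' \eqn{\kappa = \sqrt{8} / \rho} (smoothness nu = 1) and \eqn{\tau} chosen
#' so the stationary interior marginal variance equals
#' \code{marginal_sd^2} (\eqn{\tau^2 = 1 / (4\pi \kappa^2 \sigma^2)}).
#' The result is a symmetric positive-definite sparse matrix over mesh
#' vertices; vertices near the mesh boundary have somewhat inflated variance
#' (the usual Neumann boundary effect), which is why meshes extend beyond
#' the data hull.
#'
#' @param mesh An \code{svc_mesh}.
#' @param range_km Spatial range in km (correlation ~0.13 at this distance).
#' @param marginal_sd Marginal standard deviation of the field.
#' @param fem Optional precomputed [fem_matrices()] (avoids reassembly).
#' @return Sparse symmetric precision matrix (\code{dsCMatrix}).
#' @export
spde_precision <- function(mesh, range_km, marginal_sd, fem = NULL) {
  stopifnot(range_km > 0, marginal_sd > 0)
  if (is.null(fem)) fem <- fem_matrices(mesh)
  kappa2 <- 8 / range_km^2
  tau2 <- 1 / (4 * pi * kappa2 * marginal_sd^2)
  Q <- tau2 * (kappa2^2 * Matrix::Diagonal(x = fem$c0) + 2 * kappa2 * fem$g1 +
               fem$g2)
  if (any(!is.finite(Q@x)))
    stop("non-finite entries in SPDE precision (range ", range_km, ", sd ",
         marginal_sd, ")")
  Matrix::forceSymmetric(Q)
}

# Cholesky with a jitter ladder; returns list(chol, jitter_used)
chol_with_jitter <- function(Q, ladder = 10^seq(-10, -6, by = 1)) {
  ch <- tryCatch(Matrix::Cholesky(Q, LDL = FALSE), error = function(e) NULL)
  if (!is.null(ch)) return(list(chol = ch, jitter = 0))
  for (j in ladder) {
    Qj <- Q + Matrix::Diagonal(nrow(Q), j)
    ch <- tryCatch(Matrix::Cholesky(Qj, LDL = FALSE), error = function(e) NULL)
    if (!is.null(ch)) return(list(chol = ch, jitter = j))
  }
  stop("matrix not positive definite after jitter up to ",
       max(ladder))
}
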