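## Recovery of absorbed animals' solutions from retained-animal
## solutions and the stored blocks of the partitioned inverse.

.solveKnn <- function(blocks, rhs, method = c("cholesky", "pcg"),
                      tol = 1e-10, maxIter = NULL) {
  method <- match.arg(method)
  rhs <- as.matrix(rhs)
  if (method == "cholesky") {
    ch <- tryCatch(
      Matrix::Cholesky(Matrix::forceSymmetric(
        as(blocks@Knn, "CsparseMatrix")), LDL = FALSE, perm = TRUE),
      error = function(e)
        stop("K_nn is singular; cannot back-solve: ", conditionMessage(e)))
    as.matrix(Matrix::solve(ch, rhs))
  } else {
    A <- Matrix::forceSymmetric(as(blocks@Knn, "CsparseMatrix"))
    if (is.null(maxIter)) maxIter <- 10L * nrow(A)
    apply(rhs, 2, function(b)
      .pcgCore(A, b, tol = tol, maxIter = maxIter)$x)
  }
}

#' Back-solve absorbed solutions
#'
#' Solves `K_nn u_n = -K_np u_p` for the absorbed animals.  The same
#' identity serves the genetic-group family (where the retained vector
#' carries `u_p + Q_p g` and the group solutions, and the result is
#' `u_n + Q_n g`) and single-step models (where the blocks come from
#' `A^-1` alone).
#'
#' @param blocks an [InverseBlocks-class] (or [AbsorbedKernel-class],
#'   whose stored blocks are used).
#' @param uP numeric vector (or matrix of columns) of retained
#'   solutions in `idxP` order.
#' @param method `"cholesky"` (default) or `"pcg"` with Jacobi
#'   preconditioning for very large `K_nn`.
#' @param tol,maxIter PCG controls.
#' @return numeric vector (or matrix) of absorbed solutions in `idxN`
#'   order.
#' @export
backsolvePlain <- function(blocks, uP, method = c("cholesky", "pcg"),
                           tol = 1e-10, maxIter = NULL) {
  if (is(blocks, "AbsorbedKernel")) blocks <- blocks@blocks
  stopifnot(is(blocks, "InverseBlocks"))
  uP <- as.matrix(uP)
  if (nrow(uP) != length(blocks@idxP))
    stop("uP length does not match the retained index set")
  if (!length(blocks@idxN))
    return(if (ncol(uP) == 1L) numeric(0) else
             matrix(0, 0, ncol(uP)))
  rhs <- -as.matrix(blocks@Knp %*% uP)
  out <- .solveKnn(blocks, rhs, method = method, tol = tol,
                   maxIter = maxIter)
  if (ncol(uP) == 1L) as.numeric(out) else out
}

#' Kronecker back-solve for multi-trait and maternal models
#'
#' Solves `(K_nn x G0^-1) u_n = -(K_np x G0^-1) u_p` for stacked
#' solutions (trait-major, or direct-then-maternal).  Because the trait
#' covariance factor cancels, this equals a per-trait (per-effect)
#' plain back-solve; the cheap cancelled path is the default and the
#' explicit Kronecker system is available for cross-checking.
#'
#' @param blocks an [InverseBlocks-class] or [AbsorbedKernel-class].
#' @param G0inv dense symmetric inverse trait (or direct/maternal)
#'   covariance.
#' @param uP stacked retained solutions, length
#'   `length(idxP) * nrow(G0inv)`.
#' @param useKronecker solve the explicit Kronecker system instead of
#'   the cancelled per-trait path.
#' @return stacked absorbed solutions, same stacking order as `uP`.
#' @export
backsolveKron <- function(blocks, G0inv, uP, useKronecker = FALSE) {
  if (is(blocks, "AbsorbedKernel")) blocks <- blocks@blocks
  t <- nrow(G0inv)
  p <- length(blocks@idxP)
  if (length(uP) != p * t)
    stop("uP length must be length(idxP) * nrow(G0inv)")
  if (!length(blocks@idxN)) return(numeric(0))
  if (!useKronecker) {
    U <- matrix(uP, ncol = t)
    return(as.numeric(backsolvePlain(blocks, U)))
  }
  A <- kronecker(G0inv, as.matrix(blocks@Knn))
  B <- kronecker(G0inv, as.matrix(blocks@Knp))
  as.numeric(solve(A, -B %*% uP))
}

#' Marker-based back-solve for GBLUP
#'
#' First back-solves marker effects from the phenotyped animals'
#' breeding values, `a = Z_p' G_pp^-1 u_p / k` with
#' `Z = M - (2p - 1)` and `k = 2 sum(p (1 - p))`, then accumulates them
#' for the non-phenotyped animals, `u_n = Z_n a`.  The identity with
#' the relationship-based back-solve is exact only for an unblended,
#' full-rank G; a positive blend weight is reported as a warning.
#'
#' @param g the [GenotypeMatrix-class] of all modeled animals.
#' @param p allele frequencies used to build G.
#' @param Gpp dense genomic relationship matrix of the phenotyped
#'   animals (unblended for exactness).
#' @param uP breeding values of the phenotyped animals.
#' @param pheRows row indices of the phenotyped animals within `g`.
#' @param blendWeight the blend used when building `Gpp` (for the
#'   warning only).
#' @return list with `markerEffects` and `uN` (rows of `g` not in
#'   `pheRows`, ascending).
#' @export
backsolveMarkers <- function(g, p, Gpp, uP, pheRows, blendWeight = 0) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (blendWeight > 0)
    warning("blended G (w = ", blendWeight, "): marker-based back-solve ",
            "no longer reproduces the relationship-based solutions exactly")
  k <- 2 * sum(p * (1 - p))
  Z <- sweep(g@M, 2, 2 * p - 1)
  Zp <- Z[pheRows, , drop = FALSE]
  Zn <- Z[-pheRows, , drop = FALSE]
  w <- tryCatch(solve(Gpp, uP),
                error = function(e)
                  stop("G_pp is singular; cannot back-solve marker ",
                       "effects: ", conditionMessage(e)))
  a <- as.numeric(crossprod(Zp, w)) / k
  list(markerEffects = a, uN = as.numeric(Zn %*% a))
}
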