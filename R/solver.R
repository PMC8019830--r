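## Solving MME systems (sparse Cholesky, PCG, generalized minimum-norm)
## and comparing full against reduced(+back-solved) solutions.

.relResidual <- function(lhs, x, rhs) {
  denom <- max(abs(rhs))
  if (denom == 0) denom <- 1
  max(abs(as.numeric(lhs %*% x) - rhs)) / denom
}

#' Solve mixed-model equations directly
#'
#' Sparse Cholesky with fill-reducing ordering, falling back to a
#' sparse LU factorization.  Singular systems (typically genetic-group
#' equations without an anchor) error unless `generalized = TRUE`, in
#' which case a dense SVD minimum-norm least-squares solution is
#' returned; comparisons should then be made on estimable contrasts
#' such as `u + Q g`.
#'
#' @param sys an [MMESystem-class].
#' @param generalized allow a minimum-norm solve of singular systems.
#' @return a [Solutions-class]; `info$residual` holds the relative
#'   infinity-norm residual.
#' @export
solveDirect <- function(sys, generalized = FALSE) {
  stopifnot(is(sys, "MMESystem"))
  lhs <- Matrix::forceSymmetric(as(sys@lhs, "CsparseMatrix"))
  ## CHOLMOD chatters on indefinite input; failures are handled here
  x <- suppressWarnings(tryCatch({
    ch <- Matrix::Cholesky(lhs, LDL = FALSE, perm = TRUE)
    as.numeric(Matrix::solve(ch, sys@rhs))
  }, error = function(e) NULL))
  method <- "sparse Cholesky"
  if (is.null(x)) {
    x <- suppressWarnings(tryCatch(as.numeric(Matrix::solve(lhs, sys@rhs)),
                                   error = function(e) NULL))
    method <- "sparse LU"
  }
  if (is.null(x)) {
    if (!generalized) {
      suspect <- unique(sys@labels$effect[Matrix::diag(lhs) == 0])
      stop("MME left-hand side is singular",
           if (length(suspect)) paste0(" (suspect effect blocks: ",
                                       paste(suspect, collapse = ", "), ")"),
           "; re-run with generalized = TRUE for a minimum-norm solution")
    }
    sv <- svd(as.matrix(lhs))
    keep <- sv$d > max(sv$d) * 1e-12 * length(sv$d)
    x <- as.numeric(sv$v[, keep, drop = FALSE] %*%
                      (crossprod(sv$u[, keep, drop = FALSE], sys@rhs) /
                         sv$d[keep]))
    method <- "SVD minimum-norm"
  }
  new("Solutions", labels = sys@labels, values = x,
      info = list(method = method,
                  residual = .relResidual(sys@lhs, x, sys@rhs)))
}

## Jacobi-preconditioned conjugate gradients on a symmetric positive
## (semi)definite sparse system.
.pcgCore <- function(A, b, tol = 1e-10, maxIter = 10L * length(b),
                     x0 = NULL) {
  n <- length(b)
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  d <- Matrix::diag(A)
  d[d <= 0] <- 1
  r <- b - as.numeric(A %*% x)
  z <- r / d
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) bnorm <- 1
  converged <- sqrt(sum(r * r)) / bnorm <= tol
  it <- 0L
  while (!converged && it < maxIter) {
    it <- it + 1L
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    converged <- sqrt(sum(r * r)) / bnorm <= tol
    z <- r / d
    rzNew <- sum(r * z)
    p <- z + (rzNew / rz) * p
    rz <- rzNew
  }
  list(x = unname(as.numeric(x)), iterations = it, converged = converged,
       relres = sqrt(sum(r * r)) / bnorm)
}

#' Solve mixed-model equations by preconditioned conjugate gradients
#'
#' Jacobi (diagonal) preconditioner; intended for systems too large to
#' factor.  Non-convergence is reported in `info` and the partial
#' solution retained.
#'
#' @param sys an [MMESystem-class] with symmetric positive
#'   (semi)definite left-hand side.
#' @param tol relative residual convergence tolerance.
#' @param maxIter iteration cap (default `10 * order`).
#' @param x0 optional start vector (default zeros).
#' @return a [Solutions-class] with `iterations` and `converged` in
#'   `info`.
#' @export
solvePCG <- function(sys, tol = 1e-10, maxIter = NULL, x0 = NULL) {
  stopifnot(is(sys, "MMESystem"))
  if (is.null(maxIter)) maxIter <- 10L * length(sys@rhs)
  res <- .pcgCore(Matrix::forceSymmetric(as(sys@lhs, "CsparseMatrix")),
                  sys@rhs, tol = tol, maxIter = maxIter, x0 = x0)
  if (!res$converged)
    warning("PCG did not converge in ", maxIter,
            " iterations (relative residual ",
            format(res$relres, digits = 3), ")")
  new("Solutions", labels = sys@labels, values = res$x,
      info = list(method = "PCG (Jacobi)", iterations = res$iterations,
                  converged = res$converged,
                  residual = .relResidual(sys@lhs, res$x, sys@rhs)))
}

.labelKey <- function(labels) {
  paste(labels$effect, labels$level, labels$trait, sep = "\r")
}

#' Compare full-model and reduced(+back-solved) solutions
#'
#' Joins the two solution sets by their `(effect, level, trait)` labels
#' and reports per-label absolute differences.  Labels expected from
#' the full model but absent from the reduced set are enumerated and
#' fail the check; they are never silently dropped.
#'
#' @param full [Solutions-class] from the full model.
#' @param reduced [Solutions-class] from the reduced model, merged with
#'   back-solved values.
#' @param tol pass tolerance on the maximum absolute difference.
#' @return an [EquivalenceReport-class].
#' @export
checkEquivalence <- function(full, reduced, tol = 1e-8) {
  kf <- .labelKey(full@labels)
  kr <- .labelKey(reduced@labels)
  hit <- match(kf, kr)
  shared <- which(!is.na(hit))
  if (!length(shared))
    stop("no shared labels between the two solution sets")
  tab <- cbind(full@labels[shared, , drop = FALSE],
               full = full@values[shared],
               reduced = reduced@values[hit[shared]])
  tab$diff <- tab$full - tab$reduced
  rownames(tab) <- NULL
  missing <- full@labels[is.na(hit), , drop = FALSE]
  maxAbs <- max(abs(tab$diff))
  new("EquivalenceReport", table = tab, maxAbs = maxAbs, tol = tol,
      pass = maxAbs <= tol && nrow(missing) == 0L,
      nCompared = length(shared), missingLabels = missing)
}
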