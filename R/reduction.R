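## Schur-complement absorption of the excluded animals' equations.

#' Absorb the excluded block of a partitioned inverse
#'
#' Computes `phi = K_pp - K_pn (K_nn)^-1 K_np` by sparse Cholesky
#' factorization of `K_nn` (with fill-reducing ordering) applied to the
#' columns of `K_np` in blocks; `(K_nn)^-1` is never formed densely.
#' When K is a pedigree inverse partitioned at the phenotyped animals,
#' phi equals the inverse of the phenotyped block of the relationship
#' matrix itself, which is why the reduced equations reproduce the full
#' model's solutions.
#'
#' @param blocks an [InverseBlocks-class] from [partitionInverse()].
#' @param retainedLabels optional character labels for phi's rows.
#' @param blockCols number of right-hand-side columns factored per
#'   solve; bounds the dense working memory.
#' @return an [AbsorbedKernel-class] with a dense symmetric `phi`.
#' @export
schurComplement <- function(blocks, retainedLabels = character(0),
                            blockCols = 512L) {
  stopifnot(is(blocks, "InverseBlocks"))
  phi <- as.matrix(blocks@Kpp)
  if (length(blocks@idxN)) {
    ch <- tryCatch(
      Matrix::Cholesky(Matrix::forceSymmetric(
        as(blocks@Knn, "CsparseMatrix")), LDL = FALSE, perm = TRUE),
      error = function(e)
        stop("K_nn could not be factored (singular or indefinite): ",
             conditionMessage(e)))
    np <- ncol(blocks@Knp)
    for (start in seq(1L, np, by = blockCols)) {
      cols <- start:min(start + blockCols - 1L, np)
      Y <- Matrix::solve(ch, blocks@Knp[, cols, drop = FALSE])
      phi[, cols] <- phi[, cols] -
        as.matrix(Matrix::crossprod(blocks@Knp, Y))
    }
    phi <- (phi + t(phi)) / 2
  }
  new("AbsorbedKernel", phi = phi, blocks = blocks,
      retainedLabels = as.character(retainedLabels))
}
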