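## Genomic relationships: the G matrix from centered marker codes, and
## the single-step augmented inverse H^-1.

#' Construct a GenotypeMatrix
#'
#' @param M numeric matrix, animals by markers; coding `"centered"`
#'   means codes -1/0/+1, `"dosage"` means allele counts 0/1/2 which are
#'   re-centered to -1/0/+1.
#' @param markerIds character marker names (default `m1..mK`).
#' @param animalIds integer internal pedigree ids of the rows.
#' @param coding genotype coding of `M`.
#' @param strict reject missing genotype codes instead of mean-imputing
#'   them per marker.
#' @return a [GenotypeMatrix-class] with allele frequencies computed
#'   over all its animals.
#' @export
genotypeMatrix <- function(M, markerIds = NULL, animalIds = NULL,
                           coding = c("centered", "dosage"),
                           strict = FALSE) {
  coding <- match.arg(coding)
  M <- as.matrix(M)
  storage.mode(M) <- "double"
  if (coding == "dosage") M <- M - 1
  if (anyNA(M)) {
    if (strict) stop("missing genotype codes present (strict mode)")
    for (j in which(colSums(is.na(M)) > 0)) {
      mj <- mean(M[, j], na.rm = TRUE)
      if (is.nan(mj)) mj <- 0
      M[is.na(M[, j]), j] <- mj
    }
  }
  if (any(M < -1 - 1e-9) || any(M > 1 + 1e-9))
    stop("genotype codes outside the additive -1/0/+1 range")
  if (is.null(markerIds)) markerIds <- paste0("m", seq_len(ncol(M)))
  if (is.null(animalIds)) animalIds <- seq_len(nrow(M))
  g <- new("GenotypeMatrix", M = M, markerIds = as.character(markerIds),
           animalIds = as.integer(animalIds), p = numeric(0))
  g@p <- as.numeric(alleleFrequencies(g))
  g
}

#' Allele frequencies from additive genotype codes
#'
#' Under -1/0/+1 coding the frequency of the counted allele is
#' `p_j = (mean(M[,j]) + 1) / 2`.  Estimation should generally use all
#' genotyped animals, not only the phenotyped subset.
#'
#' @param g a [GenotypeMatrix-class].
#' @param subset optional row indices to restrict the estimate to.
#' @return numeric vector of frequencies with a logical `monomorphic`
#'   attribute flagging markers at p = 0 or 1.
#' @export
alleleFrequencies <- function(g, subset = NULL) {
  stopifnot(is(g, "GenotypeMatrix"))
  M <- g@M
  if (!is.null(subset)) {
    if (!length(subset)) stop("empty subset for allele frequencies")
    M <- M[subset, , drop = FALSE]
  }
  if (!nrow(M)) stop("empty subset for allele frequencies")
  p <- (colMeans(M) + 1) / 2
  attr(p, "monomorphic") <- p <= 0 | p >= 1
  p
}

#' Genomic relationship matrix with diagonal blending
#'
#' `G = Z Z' / (2 * sum(p (1 - p))) + w I` where `Z = M - (2p - 1)` is
#' the matrix of centered marker codes.  The default blend weight
#' `w = 0.1` keeps G positive definite; set `w = 0` for the unblended
#' matrix (required for exact marker-based back-solving).
#'
#' @param g a [GenotypeMatrix-class].
#' @param p allele frequencies (default: the frequencies stored in `g`,
#'   i.e. estimated from all its animals).
#' @param blendWeight non-negative weight of the identity added to G.
#' @param subset optional row indices restricting G to a subset of
#'   animals (frequencies are *not* re-estimated on the subset).
#' @return dense symmetric matrix with animal internal ids as dimnames.
#' @export
buildG <- function(g, p = NULL, blendWeight = 0.1, subset = NULL) {
  stopifnot(is(g, "GenotypeMatrix"), blendWeight >= 0)
  if (is.null(p)) p <- g@p
  if (length(p) != ncol(g@M))
    stop("p must hold one frequency per marker")
  k <- 2 * sum(p * (1 - p))
  if (k <= 0)
    stop("all markers monomorphic: zero denominator for G")
  rows <- if (is.null(subset)) seq_len(nrow(g@M)) else subset
  Z <- sweep(g@M[rows, , drop = FALSE], 2, 2 * p - 1)
  G <- tcrossprod(Z) / k + blendWeight * diag(length(rows))
  dimnames(G) <- list(g@animalIds[rows], g@animalIds[rows])
  G
}

#' Single-step augmented inverse relationship matrix
#'
#' `H^-1` equals `A^-1` with the genotyped block incremented by
#' `G^-1 - A22^-1`; every other entry is unchanged.  The increment may
#' be supplied directly or computed with [genomicIncrement()].
#'
#' @param Ainv sparse symmetric pedigree inverse.
#' @param genoIdx integer internal ids of the genotyped animals.
#' @param increment dense symmetric matrix of order `length(genoIdx)`,
#'   typically `solve(G) - solve(A22)`.
#' @return sparse symmetric H^-1.
#' @export
buildHInverse <- function(Ainv, genoIdx, increment) {
  genoIdx <- as.integer(genoIdx)
  increment <- as.matrix(increment)
  if (nrow(increment) != length(genoIdx) ||
      ncol(increment) != length(genoIdx))
    stop("increment must be square of order length(genoIdx)")
  if (max(abs(increment - t(increment))) > 1e-10)
    stop("increment must be symmetric")
  H <- as(Ainv, "generalMatrix")
  H[genoIdx, genoIdx] <- H[genoIdx, genoIdx] + increment
  Matrix::forceSymmetric(Matrix::drop0(H))
}

#' The G^-1 - A22^-1 increment for single-step models
#'
#' Desk-scale helper: inverts G and the genotyped block of the tabular
#' relationship matrix densely.
#'
#' @param G dense genomic relationship matrix of the genotyped animals.
#' @param ped a sorted [Pedigree-class].
#' @param genoIdx internal ids of the genotyped animals.
#' @return dense symmetric increment matrix.
#' @export
genomicIncrement <- function(G, ped, genoIdx) {
  A <- tabularA(ped)
  A22 <- A[genoIdx, genoIdx, drop = FALSE]
  inc <- solve(G) - solve(A22)
  (inc + t(inc)) / 2
}
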