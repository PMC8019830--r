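## Design matrices relating phenotype records to fixed effects, animals,
## permanent-environment terms and dams.

.fixedDesign <- function(df, factors) {
  if (!length(factors)) {
    X <- matrix(1, nrow(df), 1, dimnames = list(NULL, "mean"))
    return(Matrix::Matrix(X, sparse = TRUE))
  }
  miss <- setdiff(factors, names(df))
  if (length(miss))
    stop("fixed-effect columns absent from the phenotype table: ",
         paste(miss, collapse = ", "))
  df2 <- df[factors]
  for (f in factors)
    if (!is.numeric(df2[[f]])) df2[[f]] <- factor(df2[[f]])
  ## first factor one-hot without intercept; later factors drop-first
  fml <- stats::as.formula(paste("~ 0 +", paste(factors, collapse = " + ")))
  X <- stats::model.matrix(fml, data = df2)
  Matrix::Matrix(X, sparse = TRUE)
}

.checkFixedRank <- function(XtX, xLabels) {
  q <- qr(as.matrix(XtX))
  if (q$rank < ncol(XtX)) {
    bad <- xLabels[setdiff(seq_len(ncol(XtX)), q$pivot[seq_len(q$rank)])]
    stop("fixed-effect design is rank deficient; confounded columns: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Build design matrices for a model family
#'
#' Records are sorted by the animal's internal id (so that, with one
#' record per phenotyped animal, the phenotyped block of Z is an
#' identity).  A record is kept when at least one trait is non-missing;
#' animals contributing no record are the candidates for absorption.
#'
#' @param phen phenotype data.frame with an `animal` column (original
#'   ids), the fixed-effect columns named in `spec`, and the trait
#'   columns (`NA` = missing).
#' @param ped a sorted [Pedigree-class] covering every phenotyped animal.
#' @param spec a [ModelSpec-class].
#' @return a list of class `ramDesign` with elements `X`, `Z` (records
#'   by all animals), `y` (single trait) or `yMat`/`obs` (multitrait),
#'   family-specific `W` (repeatability PE / maternal PE over dams) and
#'   `S` (records by dams), `recAnimal`, `idxP`, `damSet`, `xLabels`.
#' @export
buildDesignMatrices <- function(phen, ped, spec) {
  .requireSorted(ped)
  stopifnot(is(spec, "ModelSpec"))
  fam <- spec@family
  traits <- spec@traits
  if (!"animal" %in% names(phen))
    stop("phenotype table needs an 'animal' column")
  miss <- setdiff(traits, names(phen))
  if (length(miss))
    stop("trait columns absent from the phenotype table: ",
         paste(miss, collapse = ", "))
  ids <- match(as.character(phen$animal), ped@id)
  if (anyNA(ids))
    stop("phenotype records for animals absent from the pedigree: ",
         paste(unique(phen$animal[is.na(ids)]), collapse = ", "))
  obsAll <- !is.na(as.matrix(phen[traits]))
  keep <- rowSums(obsAll) > 0
  phen <- phen[keep, , drop = FALSE]
  ids <- ids[keep]
  ord <- order(ids)
  phen <- phen[ord, , drop = FALSE]
  recAnimal <- ids[ord]
  nRec <- length(recAnimal)
  if (!nRec) stop("no phenotype records left after missing-value removal")
  N <- nAnimals(ped)
  idxP <- sort(unique(recAnimal))
  X <- .fixedDesign(phen, spec@fixedFactors)
  .checkFixedRank(Matrix::crossprod(X), colnames(X))
  Z <- Matrix::sparseMatrix(i = seq_len(nRec), j = recAnimal, x = 1,
                            dims = c(nRec, N))
  out <- list(X = X, Z = Z, recAnimal = recAnimal, idxP = idxP, N = N,
              nRec = nRec, xLabels = colnames(X), traits = traits,
              phen = phen)
  if (fam == "multitrait") {
    yMat <- as.matrix(phen[traits])
    out$obs <- !is.na(yMat)
    yMat[is.na(yMat)] <- 0
    out$yMat <- yMat
  } else {
    out$y <- as.numeric(phen[[traits[1]]])
    if (anyNA(out$y))
      stop("single-trait families require a complete trait column ",
           "after record filtering")
  }
  if (fam == "repeatability") {
    out$W <- Z[, idxP, drop = FALSE]       # PE over phenotyped animals
  }
  if (fam %in% c("maternal_uncorrelated", "maternal_correlated")) {
    damRec <- ped@dam[recAnimal]
    hasDam <- damRec > 0L
    out$S <- Matrix::sparseMatrix(i = which(hasDam), j = damRec[hasDam],
                                  x = 1, dims = c(nRec, N))
    out$damSet <- sort(unique(damRec[hasDam]))
    if (spec@includeMPE) {
      if (!length(out$damSet))
        stop("maternal PE effect requires records with known dams")
      out$W <- Matrix::sparseMatrix(i = which(hasDam),
                                    j = match(damRec[hasDam], out$damSet),
                                    x = 1,
                                    dims = c(nRec, length(out$damSet)))
    }
  }
  class(out) <- "ramDesign"
  out
}
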