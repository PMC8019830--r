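## End-to-end evaluation: kinship construction, assembly, solving,
## absorption, back-solving and full-vs-reduced validation.

.pedigreeFamilies <- c("basic", "multitrait", "repeatability",
                       "maternal_uncorrelated", "maternal_correlated")

#' Run a full or reduced genetic evaluation
#'
#' Builds the inverse kinship demanded by the model family, assembles
#' and solves either the full mixed-model equations or the reduced
#' (absorbed) equations of the retained animals.  In reduced mode with
#' `backsolve = TRUE` the absorbed animals' solutions are recovered and
#' merged, so the returned solutions carry the full label schema and
#' are directly comparable with a full-model run.
#'
#' Retained sets per family: phenotyped animals (basic, multitrait,
#' repeatability, gblup, and the direct effect of uncorrelated-maternal
#' models); phenotyped animals plus dams of phenotyped animals
#' (correlated-maternal); phenotyped animals plus the group equations
#' (groups); phenotyped-or-genotyped animals (ssgblup).  Animals of
#' interest can be added via `extras` to skip their back-solving.
#'
#' @param spec a [ModelSpec-class].
#' @param ped sorted [Pedigree-class]; for `gblup` this is the
#'   genotyped animal universe (see [pedigreeFromIds()]).
#' @param phen phenotype data.frame (see [buildDesignMatrices()]).
#' @param vc a [VarianceComponents-class] (default
#'   [defaultVarComp()] for the family).
#' @param geno [GenotypeMatrix-class] (gblup: all modeled animals;
#'   ssgblup: the genotyped subset, rows ascending by internal id).
#' @param increment ssgblup `G^-1 - A22^-1` increment; computed from
#'   `geno` via [genomicIncrement()] when omitted.
#' @param groupMap a [GroupMap-class] (groups family; computed from the
#'   pedigree's group labels when omitted).
#' @param mode `"full"` or `"reduced"`.
#' @param backsolve recover absorbed animals' solutions (reduced mode).
#' @param extras original ids of extra animals to retain.
#' @param solverMethod `"direct"` or `"pcg"`.
#' @param blendWeight diagonal blend for G (genomic families).
#' @param anchorGroup anchor the last genetic group's solution at 0
#'   (keeps the group-extended system nonsingular).
#' @param generalized allow minimum-norm solving of singular systems.
#' @return list of class `ramEvaluation`: `solutions`
#'   ([Solutions-class]), `system` ([MMESystem-class]), `kernel` (the
#'   [AbsorbedKernel-class] or `NULL`), `details` (orders, non-zero
#'   counts, retained set).
#' @export
runEvaluation <- function(spec, ped, phen, vc = defaultVarComp(spec@family),
                          geno = NULL, increment = NULL, groupMap = NULL,
                          mode = c("full", "reduced"), backsolve = TRUE,
                          extras = character(0),
                          solverMethod = c("direct", "pcg"),
                          blendWeight = 0.1, anchorGroup = TRUE,
                          generalized = FALSE) {
  mode <- match.arg(mode)
  solverMethod <- match.arg(solverMethod)
  fam <- spec@family
  design <- buildDesignMatrices(phen, ped, spec)
  N <- design$N
  groupIds <- NULL
  G <- NULL
  genoIdx <- NULL
  gm <- NULL

  if (fam %in% .pedigreeFamilies) {
    Kinv <- buildAInverse(ped)
  } else if (fam == "groups") {
    Ainv <- buildAInverse(ped)
    gm <- groupMap %||% computeQ(ped)
    Lam <- extendInverseWithGroups(Ainv, gm@Q)
    groupIds <- gm@groupIds
    if (anchorGroup && length(groupIds) > 1L) {
      keep <- seq_len(nrow(Lam))[-(N + length(groupIds))]
      Lam <- Lam[keep, keep]
      groupIds <- groupIds[-length(groupIds)]
    }
    Kinv <- Lam
  } else if (fam == "gblup") {
    if (is.null(geno)) stop("gblup requires genotypes for all modeled animals")
    rows <- match(seq_len(N), geno@animalIds)
    if (anyNA(rows))
      stop("gblup requires genotypes for every animal in the pedigree")
    G <- buildG(geno, blendWeight = blendWeight, subset = rows)
    Kinv <- Matrix::Matrix(solve(G), sparse = TRUE)
  } else if (fam == "ssgblup") {
    Ainv <- buildAInverse(ped)
    genoIdx <- geno@animalIds
    if (is.unsorted(genoIdx))
      stop("ssgblup genotype rows must be ascending by internal id")
    if (is.null(increment)) {
      if (is.null(geno))
        stop("ssgblup needs either an increment matrix or genotypes")
      increment <- genomicIncrement(
        buildG(geno, blendWeight = blendWeight), ped, genoIdx)
    }
    Kinv <- buildHInverse(Ainv, genoIdx, increment)
  } else stop("unknown family: ", fam)

  if (mode == "full") {
    sys <- assembleFullMME(spec, vc, design, Kinv, ped, groupIds)
    sol <- if (solverMethod == "direct") solveDirect(sys, generalized)
           else solvePCG(sys)
    return(structure(list(solutions = sol, system = sys, kernel = NULL,
                          details = list(mode = mode, family = fam,
                                         order = length(sys@rhs),
                                         nnzKinship = Matrix::nnzero(Kinv))),
                     class = "ramEvaluation"))
  }

  ## ---- reduced mode ----
  extrasIdx <- integer(0)
  if (length(extras)) {
    extrasIdx <- match(as.character(extras), ped@id)
    if (anyNA(extrasIdx))
      stop("extras not found in the pedigree: ",
           paste(extras[is.na(extrasIdx)], collapse = ", "))
  }
  retained <- switch(fam,
    maternal_correlated = union(design$idxP, design$damSet),
    ssgblup = union(design$idxP, genoIdx),
    design$idxP)
  retained <- sort(unique(c(retained, extrasIdx)))

  if (fam == "gblup") {
    kernel <- solve(G[retained, retained, drop = FALSE])
    blocks <- partitionInverse(Kinv, retained)
  } else if (fam == "groups") {
    blocks <- partitionInverse(Kinv, c(retained, N + seq_along(groupIds)))
    kernel <- schurComplement(blocks,
                              retainedLabels = c(ped@id[retained], groupIds))
  } else {
    blocks <- partitionInverse(Kinv, retained)
    kernel <- schurComplement(blocks, retainedLabels = ped@id[retained])
  }
  sysR <- assembleReducedMME(spec, vc, design, kernel, retained, ped,
                             Ainv = if (fam == "maternal_uncorrelated") Kinv,
                             groupIds = groupIds)
  solR <- if (solverMethod == "direct") solveDirect(sysR, generalized)
          else solvePCG(sysR)

  phi <- if (is(kernel, "AbsorbedKernel")) kernel@phi else kernel
  details <- list(mode = mode, family = fam, order = length(sysR@rhs),
                  nnzKinship = Matrix::nnzero(Kinv),
                  nnzPhi = sum(phi != 0), nRetained = length(retained),
                  nAbsorbed = N - length(retained), retained = retained)

  if (backsolve && length(retained) < N) {
    solR <- .mergeBacksolved(spec, vc, ped, design, solR, blocks,
                             retained, groupIds)
  }
  structure(list(solutions = solR, system = sysR, kernel = kernel,
                 details = details),
            class = "ramEvaluation")
}

## Back-solve the absorbed animals and merge everything into the full
## label schema.
.mergeBacksolved <- function(spec, vc, ped, design, solR, blocks,
                             retained, groupIds) {
  fam <- spec@family
  N <- design$N
  id <- ped@id
  tr1 <- spec@traits[1]
  lr <- solR@labels
  vr <- solR@values
  fullLabels <- .systemLabels(spec, ped, design, uIds = seq_len(N),
                              groupIds = groupIds, matIds = seq_len(N))
  values <- rep(NA_real_, nrow(fullLabels))
  hit <- match(.labelKey(fullLabels), .labelKey(lr))
  values[!is.na(hit)] <- vr[hit[!is.na(hit)]]

  nIds <- blocks@idxN   # animal rows only; group equations sit in idxP
  bl <- list()                                # back-solved labels/values
  if (fam == "multitrait") {
    G0inv <- solve(vc@G0)
    uP <- vr[lr$effect == "u"]
    uN <- matrix(backsolveKron(blocks, G0inv, uP), ncol = ncol(vc@G0))
    for (t in seq_along(spec@traits))
      bl[[length(bl) + 1L]] <-
        cbind(.labelsDF("u", id[nIds], spec@traits[t]), value = uN[, t])
  } else if (fam == "maternal_correlated") {
    G2inv <- solve(.maternalG2(vc, TRUE))
    stacked <- c(vr[lr$effect == "u"], vr[lr$effect == "mat"])
    res <- backsolveKron(blocks, G2inv, stacked)
    nn <- length(nIds)
    bl[[1]] <- cbind(.labelsDF("u", id[nIds], tr1), value = res[seq_len(nn)])
    bl[[2]] <- cbind(.labelsDF("mat", id[nIds], tr1),
                     value = res[nn + seq_len(nn)])
  } else if (fam == "groups") {
    uP <- vr[lr$effect %in% c("u", "group")]
    uN <- backsolvePlain(blocks, uP)
    bl[[1]] <- cbind(.labelsDF("u", id[nIds], tr1), value = uN)
  } else {
    uP <- vr[lr$effect == "u"]
    uN <- backsolvePlain(blocks, uP)
    bl[[1]] <- cbind(.labelsDF("u", id[nIds], tr1), value = uN)
  }
  back <- do.call(rbind, bl)
  hit2 <- match(.labelKey(fullLabels), .labelKey(back))
  values[!is.na(hit2)] <- back$value[hit2[!is.na(hit2)]]
  if (anyNA(values))
    stop("internal error: unmerged labels after back-solving")
  new("Solutions", labels = fullLabels, values = values,
      info = c(solR@info, list(backsolved = TRUE)))
}

#' Validate full-vs-reduced equivalence for a model family
#'
#' Runs the full model and the reduced model with back-solving on the
#' same inputs and compares all shared labels.
#'
#' @inheritParams runEvaluation
#' @param tol equivalence tolerance on the maximum absolute difference.
#' @param ... passed on to [runEvaluation()].
#' @return list of class `ramValidation` with elements `report`
#'   ([EquivalenceReport-class]), `full` and `reduced` (the two
#'   `ramEvaluation` results).
#' @export
validateReduction <- function(spec, ped, phen,
                              vc = defaultVarComp(spec@family),
                              tol = 1e-8, ...) {
  full <- runEvaluation(spec, ped, phen, vc, mode = "full", ...)
  red <- runEvaluation(spec, ped, phen, vc, mode = "reduced",
                       backsolve = TRUE, ...)
  report <- checkEquivalence(full$solutions, red$solutions, tol = tol)
  structure(list(report = report, full = full, reduced = red),
            class = "ramValidation")
}

#' @export
print.ramValidation <- function(x, ...) {
  show(x$report)
  d <- x$reduced$details
  cat(sprintf("  full order %d -> reduced order %d (%d animals absorbed)\n",
              x$full$details$order, d$order, d$nAbsorbed))
  if (!is.null(d$nnzPhi))
    cat(sprintf("  non-zeros: kinship inverse %d, absorbed kernel %d\n",
                d$nnzKinship, d$nnzPhi))
  invisible(x)
}

#' @export
print.ramEvaluation <- function(x, ...) {
  cat(sprintf("%s-model evaluation (%s), system order %d\n",
              x$details$mode, x$details$family, x$details$order))
  show(x$solutions)
  invisible(x)
}
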