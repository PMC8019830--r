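## S4 classes for pedigrees, relationship-matrix partitions, model
## specification and mixed-model equation systems.

#' Pedigree of renumbered animal records
#'
#' Animals are stored in row order; after [sortAndRenumber()] the row
#' position is the internal id, parents precede offspring, and the
#' `inbreeding` slot holds the pedigree inbreeding coefficients.
#'
#' @slot id character, original animal identifiers (one per row).
#' @slot sire,dam integer internal ids of the parents; `0` means unknown.
#' @slot generation integer generation number (0 = founders) or empty.
#' @slot sex character `"M"`/`"F"` per animal, or empty when unknown.
#' @slot groupLabel character unknown-parent group label per animal
#'   (the group to which that animal's unknown parents belong), or empty.
#' @slot inbreeding numeric inbreeding coefficients F in `[0, 1)`;
#'   `NA` until the pedigree has been sorted.
#' @slot sorted logical; `TRUE` once parents precede offspring.
#' @export
setClass("Pedigree",
  representation(id = "character", sire = "integer", dam = "integer",
                 generation = "integer", sex = "character",
                 groupLabel = "character", inbreeding = "numeric",
                 sorted = "logical"),
  prototype(generation = integer(0), sex = character(0),
            groupLabel = character(0), inbreeding = numeric(0),
            sorted = FALSE))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  msg <- character(0)
  if (length(object@sire) != n || length(object@dam) != n)
    msg <- c(msg, "sire and dam must have one entry per animal")
  if (anyDuplicated(object@id))
    msg <- c(msg, "duplicate animal ids")
  bad <- object@sire < 0L | object@sire > n | object@dam < 0L | object@dam > n
  if (any(bad))
    msg <- c(msg, "parent indices must be 0 (unknown) or valid internal ids")
  for (s in c("generation", "sex", "groupLabel", "inbreeding"))
    if (!length(slot(object, s)) %in% c(0L, n))
      msg <- c(msg, sprintf("slot '%s' must be empty or length N", s))
  if (isTRUE(object@sorted) && n > 0) {
    i <- seq_len(n)
    if (any(object@sire >= i) || any(object@dam >= i))
      msg <- c(msg, "sorted pedigree requires parents to precede offspring")
  }
  if (length(msg)) msg else TRUE
})

#' Partition of a sparse symmetric inverse into n/p blocks
#'
#' Index sets are carried instead of physically permuting the matrix:
#' `idxN` (excluded/absorbed rows) and `idxP` (retained rows) partition
#' the row set of the source matrix `K`, and the three stored blocks
#' reassemble `K` exactly.
#'
#' @slot idxN,idxP integer index sets, ascending, disjoint, covering K.
#' @slot Knn,Knp,Kpp the (n,n), (n,p) and (p,p) blocks of K
#'   (`K[p,n]` is `t(Knp)` and is never stored).
#' @export
setClass("InverseBlocks",
  representation(idxN = "integer", idxP = "integer",
                 Knn = "Matrix", Knp = "Matrix", Kpp = "Matrix"))

setValidity("InverseBlocks", function(object) {
  msg <- character(0)
  if (length(intersect(object@idxN, object@idxP)))
    msg <- c(msg, "idxN and idxP must be disjoint")
  if (nrow(object@Knn) != length(object@idxN) ||
      ncol(object@Knp) != length(object@idxP) ||
      nrow(object@Kpp) != length(object@idxP))
    msg <- c(msg, "block dimensions inconsistent with index sets")
  if (length(msg)) msg else TRUE
})

#' Marker genotypes in {-1, 0, +1} additive coding
#'
#' @slot M numeric matrix, animals by markers, codes -1/0/+1 (mean
#'   imputation of missing values can leave non-integer codes).
#' @slot markerIds character marker names.
#' @slot animalIds integer internal pedigree ids of the rows.
#' @slot p numeric allele frequencies per marker.
#' @export
setClass("GenotypeMatrix",
  representation(M = "matrix", markerIds = "character",
                 animalIds = "integer", p = "numeric"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character(0)
  if (ncol(object@M) != length(object@markerIds))
    msg <- c(msg, "one marker id per column required")
  if (nrow(object@M) != length(object@animalIds))
    msg <- c(msg, "one animal id per row required")
  if (length(object@p) && length(object@p) != ncol(object@M))
    msg <- c(msg, "p must be empty or one frequency per marker")
  if (anyNA(object@M))
    msg <- c(msg, "missing genotype codes must be imputed or rejected at load")
  if (length(msg)) msg else TRUE
})

#' Genetic-group fractions per animal
#'
#' @slot groupIds character ordered group names.
#' @slot Q numeric matrix, animals by groups, entries in `[0, 1]`; rows
#'   sum to 1 when every ancestral lineage ends in a grouped unknown
#'   parent and to less otherwise.
#' @export
setClass("GroupMap",
  representation(groupIds = "character", Q = "matrix"))

setValidity("GroupMap", function(object) {
  msg <- character(0)
  if (ncol(object@Q) != length(object@groupIds))
    msg <- c(msg, "one column of Q per group required")
  if (length(object@Q) && (min(object@Q) < -1e-12 || max(object@Q) > 1 + 1e-12))
    msg <- c(msg, "Q entries must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Variance components for the supported model families
#'
#' Scalar components are stored once; the variance ratios used in the
#' equations (lambda = sigmaE2/sigmaU2, alpha = sigmaE2/sigmaP2, and the
#' sigmaE2 * G^-1 maternal coefficients) are always derived, never
#' stored.  Unused slots stay empty.
#'
#' @slot sigmaU2 additive genetic variance.
#' @slot sigmaE2 residual variance.
#' @slot sigmaP2 permanent-environment variance (repeatability models).
#' @slot sigmaM2 maternal genetic variance.
#' @slot sigmaUM direct-maternal genetic covariance.
#' @slot sigmaMPE2 maternal permanent-environment variance.
#' @slot G0 t x t genetic covariance matrix between traits.
#' @slot R0 t x t residual covariance matrix between traits.
#' @export
setClass("VarianceComponents",
  representation(sigmaU2 = "numeric", sigmaE2 = "numeric",
                 sigmaP2 = "numeric", sigmaM2 = "numeric",
                 sigmaUM = "numeric", sigmaMPE2 = "numeric",
                 G0 = "matrix", R0 = "matrix"),
  prototype(sigmaU2 = numeric(0), sigmaE2 = numeric(0),
            sigmaP2 = numeric(0), sigmaM2 = numeric(0),
            sigmaUM = numeric(0), sigmaMPE2 = numeric(0),
            G0 = matrix(numeric(0), 0, 0), R0 = matrix(numeric(0), 0, 0)))

#' Model family and effect layout
#'
#' @slot family one of `"basic"`, `"multitrait"`, `"repeatability"`,
#'   `"maternal_uncorrelated"`, `"maternal_correlated"`, `"groups"`,
#'   `"gblup"`, `"ssgblup"`.
#' @slot fixedFactors character names of fixed factor/covariate columns
#'   in the phenotype table (empty means a single overall mean).
#' @slot traits character trait column names (one, or several for
#'   `multitrait`).
#' @slot includeMPE logical, add a maternal permanent-environment effect
#'   (maternal families only).
#' @slot kinshipSource `"pedigree"`, `"genomic"` or `"hybrid"`.
#' @export
setClass("ModelSpec",
  representation(family = "character", fixedFactors = "character",
                 traits = "character", includeMPE = "logical",
                 kinshipSource = "character"))

.ramFamilies <- c("basic", "multitrait", "repeatability",
                  "maternal_uncorrelated", "maternal_correlated",
                  "groups", "gblup", "ssgblup")

setValidity("ModelSpec", function(object) {
  msg <- character(0)
  if (!object@family %in% .ramFamilies)
    msg <- c(msg, paste("unknown family; must be one of:",
                        paste(.ramFamilies, collapse = ", ")))
  if (object@family == "multitrait" && length(object@traits) < 2)
    msg <- c(msg, "multitrait family needs at least two trait columns")
  if (object@family != "multitrait" && length(object@traits) != 1)
    msg <- c(msg, "single-trait families need exactly one trait column")
  if (length(msg)) msg else TRUE
})

#' Mixed-model equation system
#'
#' @slot lhs sparse symmetric left-hand side.
#' @slot rhs numeric right-hand side.
#' @slot labels data.frame with columns `effect` (one of `fixed`, `u`,
#'   `pe`, `mat`, `mpe`, `group`), `level` (factor level, animal original
#'   id, or group id) and `trait`, one row per equation.
#' @export
setClass("MMESystem",
  representation(lhs = "Matrix", rhs = "numeric", labels = "data.frame"))

setValidity("MMESystem", function(object) {
  msg <- character(0)
  n <- length(object@rhs)
  if (nrow(object@lhs) != n || ncol(object@lhs) != n)
    msg <- c(msg, "lhs must be square of order length(rhs)")
  if (nrow(object@labels) != n)
    msg <- c(msg, "one label row per equation required")
  if (!all(c("effect", "level", "trait") %in% names(object@labels)))
    msg <- c(msg, "labels need columns effect, level, trait")
  if (length(msg)) msg else TRUE
})

#' Labeled solution vector
#'
#' @slot labels the label schema of the producing [MMESystem-class].
#' @slot values numeric solutions aligned with `labels`.
#' @slot info list of solver metadata (method, iterations, residual).
#' @export
setClass("Solutions",
  representation(labels = "data.frame", values = "numeric", info = "list"))

setValidity("Solutions", function(object) {
  if (nrow(object@labels) != length(object@values))
    "labels and values must align" else TRUE
})

#' Absorbed (Schur-complement) kernel over the retained equations
#'
#' @slot phi dense symmetric matrix over the retained index set
#'   (animals, or animals plus genetic groups).
#' @slot blocks the [InverseBlocks-class] partition used, kept for
#'   back-solving.
#' @slot retainedLabels character labels of phi's rows (animal original
#'   ids, then group ids when extended).
#' @export
setClass("AbsorbedKernel",
  representation(phi = "matrix", blocks = "InverseBlocks",
                 retainedLabels = "character"))

setValidity("AbsorbedKernel", function(object) {
  msg <- character(0)
  if (nrow(object@phi) != ncol(object@phi))
    msg <- c(msg, "phi must be square")
  if (nrow(object@phi) != length(object@blocks@idxP))
    msg <- c(msg, "phi order must match the retained index set")
  if (length(object@retainedLabels) &&
      length(object@retainedLabels) != nrow(object@phi))
    msg <- c(msg, "retainedLabels must match phi's order")
  if (length(msg)) msg else TRUE
})

#' Report comparing full and reduced(+back-solved) solutions
#'
#' @slot table data.frame of shared labels with `full`, `reduced` and
#'   `diff` columns.
#' @slot maxAbs maximum absolute difference over shared labels.
#' @slot tol tolerance the comparison was run at.
#' @slot pass logical, `TRUE` iff `maxAbs <= tol` and no expected label
#'   is missing.
#' @slot nCompared number of shared labels.
#' @slot missingLabels data.frame of expected labels absent from the
#'   reduced solutions (never silently dropped).
#' @export
setClass("EquivalenceReport",
  representation(table = "data.frame", maxAbs = "numeric", tol = "numeric",
                 pass = "logical", nCompared = "integer",
                 missingLabels = "data.frame"))
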