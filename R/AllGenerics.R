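#' Number of animals in a pedigree
#' @param object a [Pedigree-class].
#' @return integer count.
#' @export
setGeneric("nAnimals", function(object) standardGeneric("nAnimals"))

#' @rdname nAnimals
#' @export
setMethod("nAnimals", "Pedigree", function(object) length(object@id))

#' Original animal identifiers
#' @param object a [Pedigree-class] or [GenotypeMatrix-class].
#' @return character (Pedigree) or integer internal ids (GenotypeMatrix).
#' @export
setGeneric("animalIds", function(object) standardGeneric("animalIds"))

#' @rdname animalIds
#' @export
setMethod("animalIds", "Pedigree", function(object) object@id)

#' @rdname animalIds
#' @export
setMethod("animalIds", "GenotypeMatrix", function(object) object@animalIds)

#' Solution values and labels
#' @param object a [Solutions-class].
#' @return numeric vector of solutions.
#' @export
setGeneric("solutionValues", function(object) standardGeneric("solutionValues"))

#' @rdname solutionValues
#' @export
setMethod("solutionValues", "Solutions", function(object) object@values)

#' @rdname solutionValues
#' @export
setGeneric("solutionLabels", function(object) standardGeneric("solutionLabels"))

#' @rdname solutionValues
#' @export
setMethod("solutionLabels", "Solutions", function(object) object@labels)

#' @export
#' @describeIn nAnimals compact pedigree display.
setMethod("show", "Pedigree", function(object) {
  n <- nAnimals(object)
  cat(sprintf("Pedigree of %d animals (%s)\n", n,
              if (object@sorted) "sorted, parents precede offspring"
              else "unsorted"))
  if (length(object@generation))
    cat(sprintf("  generations: %d..%d\n", min(object@generation),
                max(object@generation)))
  founders <- sum(object@sire == 0L & object@dam == 0L)
  cat(sprintf("  founders: %d\n", founders))
  if (length(object@inbreeding) && !anyNA(object@inbreeding))
    cat(sprintf("  mean F: %.4f (max %.4f)\n", mean(object@inbreeding),
                max(object@inbreeding)))
  invisible(object)
})

setMethod("show", "MMESystem", function(object) {
  cat(sprintf("MMESystem of order %d (%d non-zeros)\n",
              length(object@rhs), Matrix::nnzero(object@lhs)))
  print(table(object@labels$effect))
  invisible(object)
})

setMethod("show", "Solutions", function(object) {
  cat(sprintf("Solutions for %d equations", length(object@values)))
  if (!is.null(object@info$method))
    cat(sprintf(" [%s]", object@info$method))
  if (!is.null(object@info$residual))
    cat(sprintf(", relative residual %.2e", object@info$residual))
  cat("\n")
  print(table(object@labels$effect))
  invisible(object)
})

setMethod("show", "EquivalenceReport", function(object) {
  cat(sprintf("Full vs reduced(+back-solved): %d labels compared, max |diff| = %.3e (tol %.1e) -> %s\n",
              object@nCompared, object@maxAbs, object@tol,
              if (object@pass) "PASS" else "FAIL"))
  if (nrow(object@missingLabels))
    cat(sprintf("  %d expected labels missing from the reduced solutions\n",
                nrow(object@missingLabels)))
  invisible(object)
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d animals x %d markers\n",
              nrow(object@M), ncol(object@M)))
  invisible(object)
})

#' @export
as.data.frame.Pedigree <- function(x, ...) {
  data.frame(animal = x@id,
             sire = ifelse(x@sire == 0L, "0", x@id[pmax(x@sire, 1L)]),
             dam = ifelse(x@dam == 0L, "0", x@id[pmax(x@dam, 1L)]),
             generation = if (length(x@generation)) x@generation else NA_integer_,
             sex = if (length(x@sex)) x@sex else NA_character_,
             group = if (length(x@groupLabel)) x@groupLabel else "",
             F = if (length(x@inbreeding)) x@inbreeding else NA_real_,
             stringsAsFactors = FALSE)
}

#' @export
as.data.frame.Solutions <- function(x, ...) {
  cbind(x@labels, value = x@values)
}

#' @export
as.data.frame.EquivalenceReport <- function(x, ...) x@table
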