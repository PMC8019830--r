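## Unknown-parent genetic groups: the Q matrix of group fractions and
## the Quaas-Pollak extended inverse.

#' Group fractions per animal
#'
#' Computes Q by the Westell/Quaas-Pollak recursion in pedigree order:
#' an animal inherits half of each known parent's row; an unknown
#' parent contributes half of the unit row of its group.  Founders with
#' both parents unknown in group g therefore get the unit row for g.
#' The group of an animal's unknown parents is taken from the
#' pedigree's `groupLabel` slot unless `groupOf` overrides it.
#'
#' In lenient mode (default) lineages ending in an ungrouped unknown
#' parent leave row sums below 1 (with a warning); `strict = TRUE`
#' errors instead.
#'
#' @param ped a sorted [Pedigree-class].
#' @param groupOf optional named character vector mapping animal
#'   original id to the group of that animal's unknown parent(s).
#' @param strict error on unknown parents without a group.
#' @return a [GroupMap-class].
#' @export
computeQ <- function(ped, groupOf = NULL, strict = FALSE) {
  .requireSorted(ped)
  n <- nAnimals(ped)
  lab <- if (length(ped@groupLabel)) ped@groupLabel else rep("", n)
  if (!is.null(groupOf)) {
    hit <- match(ped@id, names(groupOf))
    lab[!is.na(hit)] <- as.character(groupOf[hit[!is.na(hit)]])
  }
  hasUnknown <- ped@sire == 0L | ped@dam == 0L
  unmapped <- hasUnknown & (is.na(lab) | lab == "")
  if (any(unmapped) && strict)
    stop("unknown parents without a group (strict mode): animals ",
         paste(utils::head(ped@id[unmapped], 5), collapse = ", "))
  groupIds <- sort(unique(lab[hasUnknown & lab != ""]))
  if (!length(groupIds)) stop("no genetic groups defined")
  g <- length(groupIds)
  Q <- matrix(0, n, g, dimnames = list(ped@id, groupIds))
  for (i in seq_len(n)) {
    for (par in c(ped@sire[i], ped@dam[i])) {
      if (par > 0L) {
        Q[i, ] <- Q[i, ] + 0.5 * Q[par, ]
      } else if (lab[i] != "") {
        Q[i, match(lab[i], groupIds)] <- Q[i, match(lab[i], groupIds)] + 0.5
      }
    }
  }
  if (any(abs(rowSums(Q) - 1) > 1e-12))
    warning("some lineages end in ungrouped unknown parents; ",
            "Q row sums below 1")
  new("GroupMap", groupIds = groupIds, Q = Q)
}

#' Quaas-Pollak extended inverse with genetic-group equations
#'
#' Returns the `(N + g) x (N + g)` matrix
#' `[[A^-1, -A^-1 Q], [-Q' A^-1, Q' A^-1 Q]]`, i.e.
#' `t(cbind(I, -Q)) %*% Ainv %*% cbind(I, -Q)`.  Its animal block is
#' `A^-1` unchanged; the extension is singular by construction (the
#' stacked vector `[Q; I]` spans its null space), so the solver's
#' anchoring/generalized policy governs uniqueness.
#'
#' @param Ainv sparse symmetric pedigree inverse of order N.
#' @param Q numeric matrix of group fractions, N rows.
#' @return sparse symmetric matrix of order `N + ncol(Q)`.
#' @export
extendInverseWithGroups <- function(Ainv, Q) {
  Q <- as.matrix(Q)
  if (nrow(Q) != nrow(Ainv))
    stop("Q must have one row per animal in Ainv")
  B <- Ainv %*% Q                       # N x g, dense-ish but g is small
  Agg <- crossprod(Q, as.matrix(B))
  Agg <- (Agg + t(Agg)) / 2
  out <- rbind(cbind(as(Ainv, "generalMatrix"), -B),
               cbind(Matrix::t(-B), Matrix::Matrix(Agg, sparse = TRUE)))
  cn <- c(rownames(Ainv), colnames(Q))
  if (!is.null(cn) && length(cn) == nrow(out)) dimnames(out) <- list(cn, cn)
  Matrix::forceSymmetric(out)
}
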