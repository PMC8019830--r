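## Pedigree handling: reading, topological renumbering, the tabular
## numerator relationship matrix A (dense oracle), Meuwissen-Luo
## inbreeding, the Henderson/Quaas sparse A-inverse, and n/p
## partitioning of sparse symmetric inverses.

.normalizeParentToken <- function(x, missingTokens) {
  x <- trimws(as.character(x))
  x[is.na(x) | x %in% missingTokens] <- "0"
  x
}

#' Read and validate a pedigree CSV
#'
#' Expects columns `animal,sire,dam` (by name if present, otherwise the
#' first three columns), with an optional unknown-parent `group` column.
#' Unknown parents may be coded `0`, an empty string or `NA`; all are
#' normalized to 0.  Parents that never appear in the animal column are
#' appended as founders unless `strict = TRUE`.
#'
#' @param path CSV file path.
#' @param groupColumn optional name of the unknown-parent group column;
#'   defaults to a column named `group` when one exists.
#' @param strict error (instead of appending founders) on parents absent
#'   from the animal column.
#' @param missingTokens character codes treated as "unknown parent".
#' @return an unsorted [Pedigree-class]; pass it to [sortAndRenumber()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("animal,sire,dam", "3,1,2", "1,0,0", "2,0,0"), f)
#' ped <- sortAndRenumber(readPedigree(f))
#' nAnimals(ped)
#' @export
readPedigree <- function(path, groupColumn = NULL, strict = FALSE,
                         missingTokens = c("0", "", "NA", ".")) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        strip.white = TRUE)
  if (ncol(df) < 3)
    stop("pedigree file needs at least 3 columns (animal, sire, dam)")
  nm <- tolower(names(df))
  pick <- function(want, fallback) {
    hit <- which(nm == want)
    if (length(hit)) df[[hit[1]]] else df[[fallback]]
  }
  animal <- trimws(pick("animal", 1))
  sire <- .normalizeParentToken(pick("sire", 2), missingTokens)
  dam <- .normalizeParentToken(pick("dam", 3), missingTokens)
  grp <- rep("", length(animal))
  gc <- if (!is.null(groupColumn)) which(names(df) == groupColumn)
        else which(nm == "group")
  if (length(gc)) grp <- trimws(df[[gc[1]]])
  grp[is.na(grp)] <- ""
  if (anyDuplicated(animal))
    stop("duplicate animal ids in pedigree: ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  parents <- setdiff(unique(c(sire, dam)), c("0", animal))
  if (length(parents)) {
    if (strict)
      stop("parents not declared as animals (strict mode): ",
           paste(parents, collapse = ", "))
    animal <- c(animal, parents)
    sire <- c(sire, rep("0", length(parents)))
    dam <- c(dam, rep("0", length(parents)))
    grp <- c(grp, rep("", length(parents)))
  }
  ped <- new("Pedigree", id = animal,
             sire = ifelse(sire == "0", 0L, match(sire, animal)),
             dam = ifelse(dam == "0", 0L, match(dam, animal)),
             groupLabel = grp,
             inbreeding = rep(NA_real_, length(animal)), sorted = FALSE)
  .pedigreeDepths(ped)  # errors on cycles (incl. self-ancestry)
  ped
}

## Generation depth of every animal; errors with one offending id if the
## parent links contain a cycle.
.pedigreeDepths <- function(ped) {
  n <- nAnimals(ped)
  s <- ped@sire
  d <- ped@dam
  depth <- rep(NA_integer_, n)
  depth[s == 0L & d == 0L] <- 0L
  repeat {
    unresolved <- which(is.na(depth))
    if (!length(unresolved)) break
    ds <- ifelse(s[unresolved] == 0L, -1L, depth[pmax(s[unresolved], 1L)])
    dd <- ifelse(d[unresolved] == 0L, -1L, depth[pmax(d[unresolved], 1L)])
    ready <- !is.na(ds) & !is.na(dd)
    if (!any(ready))
      stop("pedigree cycle detected involving animal '",
           ped@id[unresolved[1]], "'")
    depth[unresolved[ready]] <- pmax(ds[ready], dd[ready]) + 1L
  }
  depth
}

#' Topologically sort and renumber a pedigree
#'
#' Reorders animals so every parent precedes its offspring, renumbers
#' internal ids to the new row positions, assigns generation numbers
#' (when not already present) and computes inbreeding coefficients.  A
#' pedigree whose order is already valid is returned in identical order,
#' so the operation is idempotent.
#'
#' @param ped a [Pedigree-class].
#' @return a sorted [Pedigree-class] with `inbreeding` filled.
#' @export
sortAndRenumber <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  n <- nAnimals(ped)
  depth <- .pedigreeDepths(ped)
  i <- seq_len(n)
  alreadyValid <- n == 0L || (all(ped@sire < i) && all(ped@dam < i))
  ord <- if (alreadyValid) i else order(depth, i)
  pos <- integer(n)
  pos[ord] <- i
  remap <- function(p) ifelse(p[ord] == 0L, 0L, pos[pmax(p[ord], 1L)])
  out <- new("Pedigree",
             id = ped@id[ord], sire = remap(ped@sire), dam = remap(ped@dam),
             generation = if (length(ped@generation)) ped@generation[ord]
                          else depth[ord],
             sex = if (length(ped@sex)) ped@sex[ord] else character(0),
             groupLabel = if (length(ped@groupLabel)) ped@groupLabel[ord]
                          else character(0),
             inbreeding = numeric(0), sorted = TRUE)
  out@inbreeding <- .inbreedingML(out@sire, out@dam)
  validObject(out)
  out
}

.requireSorted <- function(ped) {
  if (!is(ped, "Pedigree") || !isTRUE(ped@sorted))
    stop("a sorted pedigree is required; call sortAndRenumber() first")
  invisible(TRUE)
}

#' Tabular (recursive) numerator relationship matrix
#'
#' Dense oracle implementation of the tabular method:
#' `A[i,i] = 1 + F_i` and `A[i,j] = (A[j,sire(i)] + A[j,dam(i)])/2`,
#' with unknown parents contributing 0.  Intended for modest pedigrees
#' (a few thousand animals) as the reference for the sparse rules.
#'
#' @param ped a sorted [Pedigree-class].
#' @return dense symmetric matrix of order `nAnimals(ped)`.
#' @export
tabularA <- function(ped) {
  .requireSorted(ped)
  n <- nAnimals(ped)
  A <- matrix(0, n, n)
  s <- ped@sire
  d <- ped@dam
  for (i in seq_len(n)) {
    if (i > 1L) {
      j <- seq_len(i - 1L)
      As <- if (s[i] > 0L) A[j, s[i]] else 0
      Ad <- if (d[i] > 0L) A[j, d[i]] else 0
      A[j, i] <- A[i, j] <- 0.5 * (As + Ad)
    }
    A[i, i] <- 1 + if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0
  }
  dimnames(A) <- list(ped@id, ped@id)
  A
}

## Meuwissen-Luo style recursion: per animal, trace the ancestor set,
## accumulate the L row top-down and A_ii = sum L^2 D.  O(N * ancestors).
.inbreedingML <- function(sire, dam) {
  n <- length(sire)
  Fv <- numeric(n)
  Dv <- numeric(n)
  Lv <- numeric(n)
  for (i in seq_len(n)) {
    s <- sire[i]
    d <- dam[i]
    Dv[i] <- 1 -
      (if (s > 0L) 0.25 * (1 + Fv[s]) else 0) -
      (if (d > 0L) 0.25 * (1 + Fv[d]) else 0)
    if (s == 0L || d == 0L) next  # an unknown parent is assumed unrelated
    anc <- i
    frontier <- i
    while (length(frontier)) {
      par <- c(sire[frontier], dam[frontier])
      par <- unique(par[par > 0L])
      par <- par[!par %in% anc]
      anc <- c(anc, par)
      frontier <- par
    }
    anc <- sort(anc, decreasing = TRUE)
    Lv[i] <- 1
    aii <- 0
    for (j in anc) {
      lj <- Lv[j]
      if (lj == 0) next
      aii <- aii + lj * lj * Dv[j]
      if (sire[j] > 0L) Lv[sire[j]] <- Lv[sire[j]] + lj / 2
      if (dam[j] > 0L) Lv[dam[j]] <- Lv[dam[j]] + lj / 2
    }
    Fv[i] <- aii - 1
    Lv[anc] <- 0
  }
  Fv
}

#' Pedigree inbreeding coefficients
#'
#' Meuwissen-Luo style recursion over each animal's ancestor set;
#' `F_i = A[i,i] - 1` from the tabular relationship matrix, founders 0.
#'
#' @param ped a sorted [Pedigree-class].
#' @return numeric vector F, one coefficient per animal.
#' @export
inbreedingCoefficients <- function(ped) {
  .requireSorted(ped)
  .inbreedingML(ped@sire, ped@dam)
}

## Mendelian-sampling variance share per animal (as a fraction of
## sigma_u^2): 1 - 0.25(1+F_s) - 0.25(1+F_d) over the known parents.
.mendelianShare <- function(sire, dam, Fv, useInbreeding = TRUE) {
  if (!useInbreeding) Fv <- numeric(length(sire))
  1 - ifelse(sire > 0L, 0.25 * (1 + Fv[pmax(sire, 1L)]), 0) -
      ifelse(dam > 0L, 0.25 * (1 + Fv[pmax(dam, 1L)]), 0)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds `A^-1` directly from the pedigree without ever forming A: for
#' each animal, the inverse Mendelian-sampling variance `d_i` is added
#' at `(i,i)`, `-d_i/2` at the animal-parent cells and `d_i/4` between
#' known parents.  With `useInbreeding = TRUE` (default) `d_i` uses the
#' parental inbreeding coefficients; otherwise the classic constants
#' 2, 4/3 and 1 apply.
#'
#' @param ped a sorted [Pedigree-class].
#' @param useInbreeding account for parental inbreeding in `d_i`.
#' @return sparse symmetric matrix equal to `solve(tabularA(ped))`.
#' @export
buildAInverse <- function(ped, useInbreeding = TRUE) {
  .requireSorted(ped)
  n <- nAnimals(ped)
  s <- ped@sire
  d <- ped@dam
  al <- 1 / .mendelianShare(s, d, ped@inbreeding, useInbreeding)
  i <- seq_len(n)
  ks <- which(s > 0L)
  kd <- which(d > 0L)
  kb <- which(s > 0L & d > 0L)
  ii <- c(i, ks, s[ks], s[ks], kd, d[kd], d[kd], s[kb], d[kb])
  jj <- c(i, s[ks], ks, s[ks], d[kd], kd, d[kd], d[kb], s[kb])
  xx <- c(al, -al[ks] / 2, -al[ks] / 2, al[ks] / 4,
          -al[kd] / 2, -al[kd] / 2, al[kd] / 4,
          al[kb] / 4, al[kb] / 4)
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ped@id, ped@id))
  Matrix::forceSymmetric(M)
}

#' Partition a sparse symmetric matrix into n/p blocks
#'
#' Carries index sets instead of physically permuting the matrix: the
#' retained set `idxP` (ascending) and its complement `idxN` select the
#' `(n,n)`, `(n,p)` and `(p,p)` blocks, which reassemble the input
#' exactly.
#'
#' @param K sparse symmetric matrix (e.g. `A^-1`, `H^-1` or the
#'   group-extended inverse).
#' @param idxP integer indices of the retained rows, a subset of
#'   `1:nrow(K)` without duplicates.
#' @return an [InverseBlocks-class].
#' @export
partitionInverse <- function(K, idxP) {
  n <- nrow(K)
  idxP <- as.integer(idxP)
  if (anyDuplicated(idxP)) stop("idxP contains duplicate indices")
  if (length(idxP) && (min(idxP) < 1L || max(idxP) > n))
    stop("idxP contains indices outside 1..", n)
  idxP <- sort(idxP)
  idxN <- setdiff(seq_len(n), idxP)
  new("InverseBlocks", idxN = idxN, idxP = idxP,
      Knn = K[idxN, idxN, drop = FALSE],
      Knp = K[idxN, idxP, drop = FALSE],
      Kpp = K[idxP, idxP, drop = FALSE])
}

#' Reassemble the matrix underlying an n/p partition
#'
#' Inverse of [partitionInverse()]; used to verify that partitioning is
#' an exact round trip.
#'
#' @param blocks an [InverseBlocks-class].
#' @return sparse symmetric matrix in the original index order.
#' @export
reassemblePartition <- function(blocks) {
  n <- length(blocks@idxN) + length(blocks@idxP)
  K <- Matrix::Matrix(0, n, n, sparse = TRUE)
  K[blocks@idxN, blocks@idxN] <- blocks@Knn
  K[blocks@idxN, blocks@idxP] <- blocks@Knp
  K[blocks@idxP, blocks@idxN] <- Matrix::t(blocks@Knp)
  K[blocks@idxP, blocks@idxP] <- blocks@Kpp
  K
}

#' Minimal pedigree of unrelated animals
#'
#' Convenience constructor for model families whose animal universe is
#' not pedigree-based (e.g. GBLUP over a genotyped subset): every animal
#' becomes a founder and kinship comes entirely from elsewhere.
#'
#' @param ids character original animal identifiers.
#' @return a sorted [Pedigree-class] of founders.
#' @export
pedigreeFromIds <- function(ids) {
  n <- length(ids)
  new("Pedigree", id = as.character(ids),
      sire = rep(0L, n), dam = rep(0L, n),
      generation = rep(0L, n), inbreeding = rep(0, n), sorted = TRUE)
}
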