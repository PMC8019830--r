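## Assembly of the full and reduced mixed-model equations for the seven
## model families.  Single-trait systems are assembled on the
## lambda-scale (X'X blocks plus variance-ratio penalties); multi-trait
## systems carry R^-1 explicitly.  Both scalings solve to the same
## estimates.

.labelsDF <- function(effect, level, trait) {
  if (!length(level))
    return(data.frame(effect = character(0), level = character(0),
                      trait = character(0), stringsAsFactors = FALSE))
  data.frame(effect = effect, level = as.character(level), trait = trait,
             stringsAsFactors = FALSE)
}

## Equation labels in assembly order: fixed, u (+groups), pe, mat, mpe.
.systemLabels <- function(spec, ped, design, uIds, groupIds = NULL,
                          matIds = NULL) {
  fam <- spec@family
  id <- ped@id
  if (fam == "multitrait") {
    fixed <- do.call(rbind, lapply(spec@traits, function(tr)
      .labelsDF("fixed", design$xLabels, tr)))
    u <- do.call(rbind, lapply(spec@traits, function(tr)
      .labelsDF("u", id[uIds], tr)))
    return(rbind(fixed, u))
  }
  tr <- spec@traits[1]
  L <- rbind(.labelsDF("fixed", design$xLabels, tr),
             .labelsDF("u", id[uIds], tr))
  if (fam == "groups")
    L <- rbind(L, .labelsDF("group", groupIds, tr))
  if (fam == "repeatability")
    L <- rbind(L, .labelsDF("pe", id[design$idxP], tr))
  if (fam %in% c("maternal_uncorrelated", "maternal_correlated")) {
    L <- rbind(L, .labelsDF("mat", id[matIds], tr))
    if (spec@includeMPE)
      L <- rbind(L, .labelsDF("mpe", id[design$damSet], tr))
  }
  L
}

.newMME <- function(lhs, rhs, labels) {
  new("MMESystem", lhs = Matrix::forceSymmetric(as(lhs, "CsparseMatrix")),
      rhs = as.numeric(rhs), labels = labels)
}

.sp <- function(M) as(Matrix::Matrix(M, sparse = TRUE), "generalMatrix")

.zeros <- function(nr, nc) Matrix::Matrix(0, nr, nc, sparse = TRUE)

.sysBasic <- function(X, Zu, y, P) {
  XtZ <- Matrix::crossprod(X, Zu)
  lhs <- rbind(cbind(Matrix::crossprod(X), XtZ),
               cbind(Matrix::t(XtZ), Matrix::crossprod(Zu) + P))
  rhs <- c(as.numeric(Matrix::crossprod(X, y)),
           as.numeric(Matrix::crossprod(Zu, y)))
  list(lhs = lhs, rhs = rhs)
}

.sysRepeat <- function(X, Zu, W, y, P, alpha) {
  XtZ <- Matrix::crossprod(X, Zu)
  XtW <- Matrix::crossprod(X, W)
  ZtW <- Matrix::crossprod(Zu, W)
  lhs <- rbind(
    cbind(Matrix::crossprod(X), XtZ, XtW),
    cbind(Matrix::t(XtZ), Matrix::crossprod(Zu) + P, ZtW),
    cbind(Matrix::t(XtW), Matrix::t(ZtW),
          Matrix::crossprod(W) + alpha * Matrix::Diagonal(ncol(W))))
  rhs <- c(as.numeric(Matrix::crossprod(X, y)),
           as.numeric(Matrix::crossprod(Zu, y)),
           as.numeric(Matrix::crossprod(W, y)))
  list(lhs = lhs, rhs = rhs)
}

.sysMaternal <- function(X, Zu, S, y, Pu, Pum, Pm, W = NULL, gam = NULL) {
  if (is.null(Pum)) Pum <- .zeros(ncol(Zu), ncol(S))
  XtZ <- Matrix::crossprod(X, Zu)
  XtS <- Matrix::crossprod(X, S)
  ZtS <- Matrix::crossprod(Zu, S)
  r1 <- cbind(Matrix::crossprod(X), XtZ, XtS)
  r2 <- cbind(Matrix::t(XtZ), Matrix::crossprod(Zu) + Pu, ZtS + Pum)
  r3 <- cbind(Matrix::t(XtS), Matrix::t(ZtS + Pum),
              Matrix::crossprod(S) + Pm)
  rhs <- c(as.numeric(Matrix::crossprod(X, y)),
           as.numeric(Matrix::crossprod(Zu, y)),
           as.numeric(Matrix::crossprod(S, y)))
  if (!is.null(W)) {
    XtW <- Matrix::crossprod(X, W)
    ZtW <- Matrix::crossprod(Zu, W)
    StW <- Matrix::crossprod(S, W)
    r1 <- cbind(r1, XtW)
    r2 <- cbind(r2, ZtW)
    r3 <- cbind(r3, StW)
    r4 <- cbind(Matrix::t(XtW), Matrix::t(ZtW), Matrix::t(StW),
                Matrix::crossprod(W) + gam * Matrix::Diagonal(ncol(W)))
    lhs <- rbind(r1, r2, r3, r4)
    rhs <- c(rhs, as.numeric(Matrix::crossprod(W, y)))
  } else {
    lhs <- rbind(r1, r2, r3)
  }
  list(lhs = lhs, rhs = rhs)
}

## Per-record residual precision: for every missingness pattern, the
## rows/columns of missing traits are deleted from R0 before inversion.
.residualPrecision <- function(obs, R0) {
  nRec <- nrow(obs)
  t <- ncol(obs)
  code <- obs %*% (2^(seq_len(t) - 1))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (cd in unique(code)) {
    rows <- which(code == cd)
    sub <- which(obs[rows[1], ])
    Ri <- solve(R0[sub, sub, drop = FALSE])
    for (a in seq_along(sub)) for (b in seq_along(sub)) {
      ii <- c(ii, (sub[a] - 1L) * nRec + rows)
      jj <- c(jj, (sub[b] - 1L) * nRec + rows)
      xx <- c(xx, rep(Ri[a, b], length(rows)))
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nRec * t, nRec * t))
}

.sysMultitrait <- function(X, Zu, yMat, obs, R0, penalty) {
  t <- ncol(yMat)
  Rinv <- .residualPrecision(obs, R0)
  Xbig <- Matrix::bdiag(rep(list(X), t))
  Zbig <- Matrix::bdiag(rep(list(Zu), t))
  y <- as.numeric(yMat)
  RX <- Rinv %*% Xbig
  RZ <- Rinv %*% Zbig
  lhs <- rbind(
    cbind(Matrix::crossprod(Xbig, RX), Matrix::crossprod(Xbig, RZ)),
    cbind(Matrix::crossprod(Zbig, RX),
          Matrix::crossprod(Zbig, RZ) + penalty))
  rhs <- c(as.numeric(Matrix::crossprod(Xbig, Rinv %*% y)),
           as.numeric(Matrix::crossprod(Zbig, Rinv %*% y)))
  list(lhs = lhs, rhs = rhs)
}

.needVC <- function(vc, slots, fam) {
  for (s in slots)
    if (!length(slot(vc, s)))
      stop("family '", fam, "' requires variance component '", s, "'")
  invisible(TRUE)
}

#' Assemble the full mixed-model equations
#'
#' Block layout per family: fixed effects first, then breeding values
#' for every animal (with genetic-group equations appended for the
#' `groups` family under the Quaas-Pollak transformation, whose group
#' rows carry a zero right-hand side), then permanent-environment,
#' maternal and maternal-PE equations.
#'
#' @param spec a [ModelSpec-class].
#' @param vc a [VarianceComponents-class] consistent with the family.
#' @param design output of [buildDesignMatrices()].
#' @param Kinv inverse kinship matrix demanded by the family: `A^-1`
#'   (pedigree families), `G^-1` (gblup), `H^-1` (ssgblup) or the
#'   group-extended inverse (groups family, order N + number of group
#'   equations).
#' @param ped the sorted [Pedigree-class] used to build `design`.
#' @param groupIds group equation names (groups family only).
#' @return an [MMESystem-class].
#' @export
assembleFullMME <- function(spec, vc, design, Kinv, ped, groupIds = NULL) {
  fam <- spec@family
  N <- design$N
  gk <- length(groupIds)
  wantOrder <- if (fam == "groups") N + gk else N
  if (nrow(Kinv) != wantOrder)
    stop("kinship matrix order ", nrow(Kinv), " does not match the ",
         fam, " family (expected ", wantOrder, ")")
  sys <- switch(fam,
    basic = , gblup = , ssgblup = {
      .needVC(vc, c("sigmaU2", "sigmaE2"), fam)
      .sysBasic(design$X, design$Z, design$y,
                (vc@sigmaE2 / vc@sigmaU2) * Kinv)
    },
    groups = {
      .needVC(vc, c("sigmaU2", "sigmaE2"), fam)
      Zg <- cbind(design$Z, .zeros(design$nRec, gk))
      .sysBasic(design$X, Zg, design$y, (vc@sigmaE2 / vc@sigmaU2) * Kinv)
    },
    repeatability = {
      .needVC(vc, c("sigmaU2", "sigmaE2", "sigmaP2"), fam)
      .sysRepeat(design$X, design$Z, design$W, design$y,
                 (vc@sigmaE2 / vc@sigmaU2) * Kinv,
                 vc@sigmaE2 / vc@sigmaP2)
    },
    maternal_uncorrelated = , maternal_correlated = {
      .needVC(vc, c("sigmaU2", "sigmaE2", "sigmaM2"), fam)
      G2 <- .maternalG2(vc, fam == "maternal_correlated")
      lam <- vc@sigmaE2 * solve(G2)
      .sysMaternal(design$X, design$Z, design$S, design$y,
                   Pu = lam[1, 1] * Kinv,
                   Pum = if (fam == "maternal_correlated")
                           lam[1, 2] * Kinv else NULL,
                   Pm = lam[2, 2] * Kinv,
                   W = if (spec@includeMPE) design$W else NULL,
                   gam = if (spec@includeMPE) {
                     .needVC(vc, "sigmaMPE2", fam)
                     vc@sigmaE2 / vc@sigmaMPE2
                   })
    },
    multitrait = {
      if (!length(vc@G0) || !length(vc@R0))
        stop("multitrait family requires G0 and R0")
      penalty <- Matrix::kronecker(Matrix::Matrix(solve(vc@G0)), Kinv)
      .sysMultitrait(design$X, design$Z, design$yMat, design$obs,
                     vc@R0, penalty)
    })
  labels <- .systemLabels(spec, ped, design, uIds = seq_len(N),
                          groupIds = groupIds,
                          matIds = seq_len(N))
  .newMME(sys$lhs, sys$rhs, labels)
}

#' Assemble the reduced (absorbed) mixed-model equations
#'
#' The design is restricted to the retained animals and the inverse
#' kinship penalty is replaced by the absorbed kernel Phi (Theta for
#' single-step models; the directly inverted phenotyped block of G for
#' GBLUP).  For the uncorrelated-maternal family only the direct
#' effect is reduced: the maternal block keeps the complete `A^-1`
#' penalty over all animals, so `Ainv` must be supplied.
#'
#' @param spec,vc,design,ped as in [assembleFullMME()].
#' @param kernel an [AbsorbedKernel-class], or a plain symmetric matrix
#'   over the retained set (plus group columns for the groups family).
#' @param retained integer internal ids of the retained animals,
#'   ascending.
#' @param Ainv full pedigree inverse (uncorrelated-maternal family).
#' @param groupIds group equation names (groups family).
#' @return an [MMESystem-class] whose solutions match the full system's
#'   entries for the retained labels.
#' @export
assembleReducedMME <- function(spec, vc, design, kernel, retained, ped,
                               Ainv = NULL, groupIds = NULL) {
  fam <- spec@family
  phi <- if (is(kernel, "AbsorbedKernel")) kernel@phi else as.matrix(kernel)
  retained <- as.integer(retained)
  gk <- length(groupIds)
  wantOrder <- length(retained) + if (fam == "groups") gk else 0L
  if (nrow(phi) != wantOrder)
    stop("retained-set/kernel mismatch: kernel order ", nrow(phi),
         ", expected ", wantOrder)
  P <- .sp(phi)
  Zr <- design$Z[, retained, drop = FALSE]
  sys <- switch(fam,
    basic = , gblup = , ssgblup = {
      .needVC(vc, c("sigmaU2", "sigmaE2"), fam)
      .sysBasic(design$X, Zr, design$y, (vc@sigmaE2 / vc@sigmaU2) * P)
    },
    groups = {
      .needVC(vc, c("sigmaU2", "sigmaE2"), fam)
      Zg <- cbind(Zr, .zeros(design$nRec, gk))
      .sysBasic(design$X, Zg, design$y, (vc@sigmaE2 / vc@sigmaU2) * P)
    },
    repeatability = {
      .needVC(vc, c("sigmaU2", "sigmaE2", "sigmaP2"), fam)
      .sysRepeat(design$X, Zr, design$W, design$y,
                 (vc@sigmaE2 / vc@sigmaU2) * P, vc@sigmaE2 / vc@sigmaP2)
    },
    maternal_correlated = {
      G2 <- .maternalG2(vc, TRUE)
      lam <- vc@sigmaE2 * solve(G2)
      .sysMaternal(design$X, Zr, design$S[, retained, drop = FALSE],
                   design$y, Pu = lam[1, 1] * P, Pum = lam[1, 2] * P,
                   Pm = lam[2, 2] * P,
                   W = if (spec@includeMPE) design$W else NULL,
                   gam = if (spec@includeMPE) vc@sigmaE2 / vc@sigmaMPE2)
    },
    maternal_uncorrelated = {
      if (is.null(Ainv))
        stop("the uncorrelated-maternal reduced model needs the full ",
             "A^-1 for its maternal block")
      G2 <- .maternalG2(vc, FALSE)
      lam <- vc@sigmaE2 * solve(G2)
      .sysMaternal(design$X, Zr, design$S, design$y,
                   Pu = lam[1, 1] * P, Pum = NULL,
                   Pm = lam[2, 2] * Ainv,
                   W = if (spec@includeMPE) design$W else NULL,
                   gam = if (spec@includeMPE) vc@sigmaE2 / vc@sigmaMPE2)
    },
    multitrait = {
      penalty <- Matrix::kronecker(Matrix::Matrix(solve(vc@G0)), P)
      .sysMultitrait(design$X, Zr, design$yMat, design$obs, vc@R0, penalty)
    })
  matIds <- if (fam == "maternal_uncorrelated") seq_len(design$N) else retained
  labels <- .systemLabels(spec, ped, design, uIds = retained,
                          groupIds = groupIds, matIds = matIds)
  .newMME(sys$lhs, sys$rhs, labels)
}
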