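## Fixtures built in code: tiny hand-checkable pedigrees and a wrapper
## that simulates a seeded dataset for any model family.

## Two founders and their offspring (sorted).
trioPedigree <- function() {
  sortAndRenumber(new("Pedigree", id = c("1", "2", "3"),
                      sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L),
                      inbreeding = rep(NA_real_, 3), sorted = FALSE))
}

## Full sibs 3 and 4 (parents 1 x 2) mated to produce 5: F_5 = 0.25.
fullSibMatingPedigree <- function() {
  sortAndRenumber(new("Pedigree", id = as.character(1:5),
                      sire = c(0L, 0L, 1L, 1L, 3L),
                      dam = c(0L, 0L, 2L, 2L, 4L),
                      inbreeding = rep(NA_real_, 5), sorted = FALSE))
}

## Eight animals, founders 1:3, phenotyped 4:8; a single two-level
## fixed factor.  Numbers are arbitrary but frozen.
eightAnimalFixture <- function() {
  ped <- sortAndRenumber(new("Pedigree", id = as.character(1:8),
                             sire = c(0L, 0L, 0L, 1L, 3L, 1L, 4L, 3L),
                             dam = c(0L, 0L, 0L, 0L, 2L, 2L, 5L, 6L),
                             inbreeding = rep(NA_real_, 8),
                             sorted = FALSE))
  phen <- data.frame(animal = as.character(4:8),
                     sex = c("m", "f", "f", "m", "m"),
                     y = c(4.5, 2.9, 3.9, 3.5, 5.0),
                     stringsAsFactors = FALSE)
  list(ped = ped, phen = phen,
       vc = varComp(sigmaU2 = 1, sigmaE2 = 2),   # lambda = 2
       spec = modelSpec("basic", fixedFactors = "sex"))
}

## Seeded simulated dataset for a family; returns everything
## validateReduction() needs.
familyDataset <- function(family, seed, nTotal = 300, nFounders = 30,
                          nGenerations = 5, phenotypingRate = 0.4,
                          nMarkers = 500, genoRate = 0.3, nGroups = 2) {
  vc <- defaultVarComp(family)
  ped <- simulatePedigree(nFounders = nFounders,
                          nGenerations = nGenerations, nTotal = nTotal,
                          nGroups = if (family == "groups") nGroups else 0,
                          seed = seed)
  traits <- if (family == "multitrait") c("t1", "t2") else "y"
  simFamily <- if (family %in% c("groups", "gblup", "ssgblup")) "basic"
               else family
  sim <- simulateTraits(ped, vc, simFamily,
                        phenotypingRate = phenotypingRate,
                        seed = seed + 1L)
  spec <- modelSpec(family, fixedFactors = "herd", traits = traits)
  extra <- list()
  if (family == "gblup") {
    sub <- sort(sample(seq_len(nTotal), max(2L, round(genoRate * nTotal))))
    g <- simulateGenotypes(ped, nMarkers = nMarkers, subset = sub,
                           seed = seed + 2L)
    pedG <- pedigreeFromIds(animalIds(ped)[sub])
    geno <- genotypeMatrix(g@M, animalIds = seq_along(sub))
    phen <- sim$phen[sim$phen$animal %in% animalIds(pedG), , drop = FALSE]
    return(list(spec = spec, ped = pedG, phen = phen, vc = vc,
                geno = geno, truth = sim$truth))
  }
  if (family == "ssgblup") {
    sub <- sort(sample(seq_len(nTotal), max(2L, round(genoRate * nTotal))))
    extra$geno <- simulateGenotypes(ped, nMarkers = nMarkers,
                                    subset = sub, seed = seed + 2L)
  }
  c(list(spec = spec, ped = ped, phen = sim$phen, vc = vc,
         truth = sim$truth), extra)
}

expectValidates <- function(family, seed, tol = 1e-8, ...) {
  ds <- familyDataset(family, seed, ...)
  val <- validateReduction(ds$spec, ds$ped, ds$phen, ds$vc,
                           tol = tol, geno = ds$geno)
  expect_true(val$report@pass,
              label = sprintf("%s family equivalence (max|diff| = %.3e)",
                              family, val$report@maxAbs))
  invisible(val)
}
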