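## Seeded simulator: discrete-generation pedigrees, true breeding
## values by gene flow with Mendelian-sampling deviates, phenotypes
## with herd effects, and gene-dropped marker genotypes.  The defaults
## mirror the package's reference study: 100 founders, 8 discrete
## generations, 10,000 animals, 2,000 phenotypes in 5 herds.

#' Simulate a discrete-generation pedigree
#'
#' Founders form generation 0 with both sexes; each later generation is
#' produced by random mating of the previous generation (one offspring
#' per mating, no selection).  Deterministic given the seed.
#'
#' @param nFounders number of founders (>= 2, both sexes).
#' @param nGenerations number of offspring generations.
#' @param nTotal total pedigree size; offspring are spread evenly
#'   across generations.
#' @param nGroups if positive, assign founders' unknown parents to this
#'   many genetic groups (round-robin over founders).
#' @param seed mandatory random seed.
#' @return a sorted [Pedigree-class] with generation, sex and
#'   inbreeding filled.
#' @export
simulatePedigree <- function(nFounders = 100, nGenerations = 8,
                             nTotal = 10000, nGroups = 0, seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  set.seed(seed)
  if (nFounders < 2) stop("need at least two founders (both sexes)")
  nOff <- nTotal - nFounders
  if (nOff < nGenerations)
    stop("nTotal too small for the requested number of generations")
  sizes <- as.integer(diff(round(seq(0, nOff, length.out = nGenerations + 1))))
  N <- as.integer(nTotal)
  sire <- integer(N)
  dam <- integer(N)
  gen <- integer(N)
  sex <- character(N)
  sex[seq_len(nFounders)] <- rep(c("M", "F"), length.out = nFounders)
  cur <- as.integer(nFounders)
  prev <- seq_len(nFounders)
  for (g in seq_len(nGenerations)) {
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (!length(males) || !length(females))
      stop("no available mates in generation ", g - 1L)
    k <- sizes[g]
    off <- cur + seq_len(k)
    sire[off] <- males[sample.int(length(males), k, replace = TRUE)]
    dam[off] <- females[sample.int(length(females), k, replace = TRUE)]
    gen[off] <- g
    sex[off] <- sample(rep_len(c("M", "F"), k))  # balanced, shuffled
    prev <- off
    cur <- cur + k
  }
  ped <- new("Pedigree", id = as.character(seq_len(N)), sire = sire,
             dam = dam, generation = gen, sex = sex,
             groupLabel = if (nGroups > 0)
               c(paste0("g", rep_len(seq_len(nGroups), nFounders)),
                 rep("", N - nFounders)) else character(0),
             inbreeding = numeric(0), sorted = FALSE)
  sortAndRenumber(ped)
}

## Gene-flow sampling of true (direct[, maternal]) genetic effects:
## u_i = mean of known parents' values + Mendelian deviate with
## covariance Sigma * d_i, d_i = 1 - 0.25(1+F_s) - 0.25(1+F_d) over
## known parents.
.dropGenetic <- function(ped, Sigma) {
  Sigma <- as.matrix(Sigma)
  t <- nrow(Sigma)
  n <- nAnimals(ped)
  L <- chol(Sigma)
  dv <- .mendelianShare(ped@sire, ped@dam, ped@inbreeding, TRUE)
  z <- matrix(stats::rnorm(n * t), n, t) %*% L
  u <- matrix(0, n, t)
  s <- ped@sire
  d <- ped@dam
  for (i in seq_len(n)) {
    pa <- if (s[i] > 0L) u[s[i], ] else 0
    ma <- if (d[i] > 0L) u[d[i], ] else 0
    u[i, ] <- 0.5 * pa + 0.5 * ma + sqrt(dv[i]) * z[i, ]
  }
  u
}

#' Simulate phenotypes and true effects for a model family
#'
#' True breeding values follow the gene-flow recursion with
#' Mendelian-sampling variance `sigmaU2 * (1 - 0.25(1+F_s) -
#' 0.25(1+F_d))`; maternal families drop a correlated direct/maternal
#' pair.  Phenotypes add a random herd effect (drawn once per herd),
#' the animal's effects, and a residual; a configurable number of
#' animals (optionally restricted to late generations) is phenotyped.
#'
#' @param ped a sorted [Pedigree-class].
#' @param vc a [VarianceComponents-class] for the family.
#' @param family model family name (groups and genomic families use the
#'   `"basic"` trait architecture).
#' @param nPhenotyped number of phenotyped animals (or use
#'   `phenotypingRate`).
#' @param phenotypingRate fraction of eligible animals phenotyped.
#' @param phenoGenerations restrict phenotyping to these generations
#'   (e.g. `6:8`); `NULL` means all.
#' @param nHerds number of herds, assigned uniformly per record.
#' @param herdSD spread of the herd effects (default: residual SD).
#' @param nRecords records per phenotyped animal (repeatability).
#' @param missingRate per-cell missingness for multitrait phenotypes
#'   (records losing every trait are kept on one random trait).
#' @param seed mandatory random seed.
#' @return list with `phen` (phenotype data.frame: `animal`, `herd`,
#'   trait columns) and `truth` (data.frame of true effects per
#'   animal: `u`, and `m` for maternal families).
#' @export
simulateTraits <- function(ped, vc, family = "basic", nPhenotyped = NULL,
                           phenotypingRate = NULL, phenoGenerations = NULL,
                           nHerds = 5, herdSD = NULL, nRecords = 2,
                           missingRate = 0, seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  set.seed(seed)
  .requireSorted(ped)
  n <- nAnimals(ped)
  gen <- if (length(ped@generation)) ped@generation else rep(0L, n)
  maternal <- family %in% c("maternal_uncorrelated", "maternal_correlated")
  multitrait <- family == "multitrait"

  if (multitrait) {
    u <- .dropGenetic(ped, vc@G0)
    sigE <- vc@R0
  } else if (maternal) {
    u <- .dropGenetic(ped, .maternalG2(vc, family == "maternal_correlated"))
    sigE <- vc@sigmaE2
  } else {
    u <- .dropGenetic(ped, matrix(vc@sigmaU2, 1, 1))
    sigE <- vc@sigmaE2
  }

  eligible <- seq_len(n)
  if (!is.null(phenoGenerations))
    eligible <- eligible[gen[eligible] %in% phenoGenerations]
  if (maternal)
    eligible <- eligible[ped@dam[eligible] > 0L]
  if (!length(eligible)) stop("no animals eligible for phenotyping")
  nPhe <- if (!is.null(nPhenotyped)) min(nPhenotyped, length(eligible))
          else if (!is.null(phenotypingRate))
            max(1L, round(phenotypingRate * length(eligible)))
          else length(eligible)
  phe <- sort(eligible[sample.int(length(eligible), nPhe)])

  if (is.null(herdSD))
    herdSD <- sqrt(if (multitrait) mean(diag(vc@R0)) else vc@sigmaE2)
  herdEff <- stats::rnorm(nHerds, 0, herdSD)

  recAnimal <- if (family == "repeatability") rep(phe, each = nRecords)
               else phe
  nRec <- length(recAnimal)
  herd <- sample.int(nHerds, nRec, replace = TRUE)

  if (multitrait) {
    t <- ncol(vc@G0)
    E <- matrix(stats::rnorm(nRec * t), nRec, t) %*% chol(vc@R0)
    Y <- herdEff[herd] + u[recAnimal, , drop = FALSE] + E
    if (missingRate > 0) {
      drop <- matrix(stats::runif(nRec * t) < missingRate, nRec, t)
      allGone <- rowSums(!drop) == 0
      drop[cbind(which(allGone),
                 sample.int(t, sum(allGone), replace = TRUE))] <- FALSE
      Y[drop] <- NA
    }
    phen <- data.frame(animal = ped@id[recAnimal],
                       herd = paste0("h", herd),
                       stringsAsFactors = FALSE)
    for (k in seq_len(t)) phen[[paste0("t", k)]] <- Y[, k]
    truth <- data.frame(animal = ped@id, stringsAsFactors = FALSE)
    for (k in seq_len(t)) truth[[paste0("u_t", k)]] <- u[, k]
    return(list(phen = phen, truth = truth))
  }

  y <- herdEff[herd] + u[recAnimal, 1]
  truth <- data.frame(animal = ped@id, u = u[, 1],
                      stringsAsFactors = FALSE)
  if (family == "repeatability") {
    peEff <- stats::rnorm(n, 0, sqrt(vc@sigmaP2))
    y <- y + peEff[recAnimal]
    truth$pe <- peEff
  }
  if (maternal) {
    dams <- ped@dam[recAnimal]
    mpeEff <- stats::rnorm(n, 0, sqrt(vc@sigmaMPE2))
    y <- y + u[dams, 2] + mpeEff[dams]
    truth$m <- u[, 2]
    truth$mpe <- mpeEff
  }
  y <- y + stats::rnorm(nRec, 0, sqrt(sigE))
  phen <- data.frame(animal = ped@id[recAnimal], herd = paste0("h", herd),
                     y = y, stringsAsFactors = FALSE)
  list(phen = phen, truth = truth)
}

#' Simulate marker genotypes by gene dropping
#'
#' Founder genotypes are drawn from Hardy-Weinberg proportions at the
#' configured allele frequencies; descendants receive one allele from
#' each known parent (transmission probability = parental dosage / 2,
#' markers unlinked); alleles from unknown parents are drawn from the
#' founder frequencies.  Deterministic given the seed.
#'
#' @param ped a sorted [Pedigree-class].
#' @param nMarkers number of markers.
#' @param freq founder allele frequencies, strictly inside (0, 1);
#'   default drawn uniformly from `freqRange`.
#' @param freqRange range for the default frequency draw.
#' @param subset optional internal ids of the animals to genotype
#'   (gene dropping still runs over the whole pedigree).
#' @param seed mandatory random seed.
#' @return a [GenotypeMatrix-class] with -1/0/+1 codes.
#' @export
simulateGenotypes <- function(ped, nMarkers = 500, freq = NULL,
                              freqRange = c(0.1, 0.9), subset = NULL,
                              seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  set.seed(seed)
  .requireSorted(ped)
  n <- nAnimals(ped)
  if (is.null(freq))
    freq <- stats::runif(nMarkers, freqRange[1], freqRange[2])
  if (length(freq) != nMarkers)
    stop("freq must hold one frequency per marker")
  if (any(freq <= 0) || any(freq >= 1))
    stop("founder allele frequencies must lie strictly inside (0, 1)")
  M <- matrix(0, n, nMarkers)
  s <- ped@sire
  d <- ped@dam
  for (i in seq_len(n)) {
    a1 <- if (s[i] > 0L) stats::rbinom(nMarkers, 1L, (M[s[i], ] + 1) / 2)
          else stats::rbinom(nMarkers, 1L, freq)
    a2 <- if (d[i] > 0L) stats::rbinom(nMarkers, 1L, (M[d[i], ] + 1) / 2)
          else stats::rbinom(nMarkers, 1L, freq)
    M[i, ] <- a1 + a2 - 1
  }
  if (!is.null(subset)) {
    subset <- sort(as.integer(subset))
    M <- M[subset, , drop = FALSE]
  } else subset <- seq_len(n)
  genotypeMatrix(M, animalIds = subset)
}
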