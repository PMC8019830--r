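test_that("pedigree simulation is seeded, sorted and sized as configured", {
  trio <- simulatePedigree(nFounders = 2, nGenerations = 1, nTotal = 3,
                           seed = 1)
  expect_equal(nAnimals(trio), 3L)
  expect_equal(trio@sire[3], 1L)
  expect_equal(trio@dam[3], 2L)

  a <- simulatePedigree(nFounders = 20, nGenerations = 4, nTotal = 200,
                        seed = 5)
  b <- simulatePedigree(nFounders = 20, nGenerations = 4, nTotal = 200,
                        seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(sum(a@generation == 0L), 20L)
  i <- seq_len(200)
  expect_true(all(a@sire < i) && all(a@dam < i))

  expect_error(simulatePedigree(nFounders = 1, nGenerations = 1,
                                nTotal = 2, seed = 1), "two founders")
  expect_error(simulatePedigree(nFounders = 10, nGenerations = 2,
                                nTotal = 100), "seed")
})

test_that("trait simulation honours the noise-free limit and the record counts", {
  ped <- pedigreeFromIds(as.character(1:30))
  vc <- varComp(sigmaU2 = 1, sigmaE2 = 0)   # h^2 = 1
  sim <- simulateTraits(ped, vc, "basic", nHerds = 2, seed = 3)
  herd <- as.integer(sub("h", "", sim$phen$herd))
  herdEff <- tapply(sim$phen$y - sim$truth$u, herd, mean)
  expect_equal(sim$phen$y - herdEff[herd], sim$truth$u,
               tolerance = 1e-12, ignore_attr = TRUE)

  ped2 <- simulatePedigree(nFounders = 10, nGenerations = 3, nTotal = 80,
                           seed = 4)
  rep2 <- simulateTraits(ped2, defaultVarComp("repeatability"),
                         "repeatability", nPhenotyped = 20, nRecords = 3,
                         seed = 5)
  expect_equal(nrow(rep2$phen), 60L)
  expect_true(all(table(rep2$phen$animal) == 3L))

  ## a fixed phenotype count restricted to late generations
  ped3 <- simulatePedigree(nFounders = 20, nGenerations = 5, nTotal = 400,
                           seed = 6)
  s3 <- simulateTraits(ped3, defaultVarComp("basic"), "basic",
                       nPhenotyped = 100, phenoGenerations = 4:5,
                       nHerds = 5, seed = 7)
  expect_equal(nrow(s3$phen), 100L)
  gen <- ped3@generation[match(s3$phen$animal, animalIds(ped3))]
  expect_true(all(gen %in% 4:5))
  expect_equal(length(unique(s3$phen$herd)), 5L)
})

test_that("Mendelian-sampling deviates have the expected variance", {
  ## many offspring of one non-inbred pair: var of the deviation from
  ## the parent average must approach sigmaU2 / 2
  n <- 12000
  ped <- new("Pedigree", id = as.character(seq_len(n + 2)),
             sire = c(0L, 0L, rep(1L, n)), dam = c(0L, 0L, rep(2L, n)),
             inbreeding = rep(NA_real_, n + 2), sorted = FALSE)
  ped <- sortAndRenumber(ped)
  vc <- varComp(sigmaU2 = 2, sigmaE2 = 1)
  sim <- simulateTraits(ped, vc, "basic", seed = 11)
  u <- sim$truth$u
  dev <- u[-(1:2)] - 0.5 * (u[1] + u[2])
  expect_lt(abs(var(dev) - 1) / 1, 0.05)   # within 5% of sigmaU2/2
})

test_that("gene dropping is seeded and respects Mendelian inheritance", {
  ped <- simulatePedigree(nFounders = 10, nGenerations = 3, nTotal = 60,
                          seed = 13)
  g1 <- simulateGenotypes(ped, nMarkers = 50, seed = 14)
  g2 <- simulateGenotypes(ped, nMarkers = 50, seed = 14)
  expect_identical(g1@M, g2@M)
  expect_true(all(g1@M %in% c(-1, 0, 1)))
  expect_error(simulateGenotypes(ped, nMarkers = 5, freq = rep(1, 5),
                                 seed = 1), "strictly inside")

  ## full sibs share half their genome on average
  fs <- sortAndRenumber(new("Pedigree", id = as.character(1:4),
                            sire = c(0L, 0L, 1L, 1L),
                            dam = c(0L, 0L, 2L, 2L),
                            inbreeding = rep(NA_real_, 4), sorted = FALSE))
  gfs <- simulateGenotypes(fs, nMarkers = 2000, freq = rep(0.5, 2000),
                           seed = 15)
  r <- cor(gfs@M[3, ], gfs@M[4, ])
  expect_lt(abs(r - 0.5), 0.05)
})

test_that("BLUP on simulated data tracks the true breeding values", {
  ## small-scale sanity check with a Monte-Carlo-sized band; the tight
  ## unbiasedness band at the reference scale lives in the acceptance
  ## suite
  stats <- sapply(1:5, function(s) {
    ped <- simulatePedigree(nFounders = 30, nGenerations = 5,
                            nTotal = 1200, seed = 500 + s)
    vc <- defaultVarComp("basic")
    sim <- simulateTraits(ped, vc, "basic", nPhenotyped = 480,
                          phenoGenerations = 3:5, seed = 600 + s)
    fit <- runEvaluation(modelSpec("basic", fixedFactors = "herd"),
                         ped, sim$phen, vc, mode = "full")
    df <- as.data.frame(fit$solutions)
    ebv <- df$value[df$effect == "u"]
    ebv <- ebv[match(sim$truth$animal, df$level[df$effect == "u"])]
    c(slope = unname(coef(lm(sim$truth$u ~ ebv))[2]),
      cor = cor(sim$truth$u, ebv))
  })
  expect_true(all(stats["cor", ] > 0.3))
  expect_lt(abs(mean(stats["slope", ]) - 1), 0.2)
})
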