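test_that("the absorbed kernel equals the hand Schur complement on the trio", {
  trio <- trioPedigree()
  blocks <- partitionInverse(buildAInverse(trio), 3L)
  kern <- schurComplement(blocks)
  expect_equal(unname(kern@phi), matrix(1))            # = (A_pp)^-1
  ## empty absorbed set: phi is K_pp itself
  all3 <- schurComplement(partitionInverse(buildAInverse(trio), 1:3))
  expect_equal(as.matrix(all3@phi), as.matrix(buildAInverse(trio)),
               ignore_attr = TRUE)
})

test_that("phi equals the dense inverse of the phenotyped block of A", {
  ped <- simulatePedigree(nFounders = 15, nGenerations = 4, nTotal = 200,
                          seed = 17)
  set.seed(18)
  idxP <- sort(sample(200, 60))
  kern <- schurComplement(partitionInverse(buildAInverse(ped), idxP))
  App <- tabularA(ped)[idxP, idxP]
  expect_lt(max(abs(kern@phi - solve(App))), 1e-9)
  ## implied prior variance of retained breeding values: phi^-1 = A_pp
  expect_lt(max(abs(solve(kern@phi) - App)), 1e-8)
})

test_that("theta equals the inverse block of the dense single-step H", {
  ped <- simulatePedigree(nFounders = 12, nGenerations = 4, nTotal = 90,
                          seed = 19)
  geno <- sort(sample(30:90, 20))
  g <- simulateGenotypes(ped, nMarkers = 150, subset = geno, seed = 20)
  inc <- genomicIncrement(buildG(g), ped, geno)
  Hi <- buildHInverse(buildAInverse(ped), geno, inc)
  set.seed(23)
  phe <- sort(sample(40:90, 25))
  ret <- sort(union(phe, geno))
  theta <- schurComplement(partitionInverse(Hi, ret))@phi
  H <- solve(as.matrix(Hi))
  expect_lt(max(abs(theta - solve(H[ret, ret]))), 1e-9)
})

test_that("the basic reduced trio reproduces the full system by hand", {
  trio <- trioPedigree()
  spec <- modelSpec("basic")
  vc <- varComp(sigmaU2 = 1, sigmaE2 = 1)
  phen <- data.frame(animal = "3", y = 2)
  d <- buildDesignMatrices(phen, trio, spec)
  kern <- schurComplement(partitionInverse(buildAInverse(trio), 3L))
  red <- assembleReducedMME(spec, vc, d, kern, 3L, trio)
  expect_equal(unname(as.matrix(red@lhs)), rbind(c(1, 1), c(1, 2)))
  full <- assembleFullMME(spec, vc, d, buildAInverse(trio), trio)
  u3full <- solveDirect(full)@values[4]
  u3red <- solveDirect(red)@values[2]
  expect_equal(u3red, u3full, tolerance = 1e-12)
})

test_that("full and reduced solutions are identical across model families", {
  expectValidates("basic", seed = 101)
  expectValidates("repeatability", seed = 103)
  expectValidates("maternal_uncorrelated", seed = 104)
  expectValidates("maternal_correlated", seed = 105)
  expectValidates("multitrait", seed = 106)
  expectValidates("groups", seed = 107)
  expectValidates("gblup", seed = 108)
  expectValidates("ssgblup", seed = 109)
})

test_that("a gblup model with everyone phenotyped reduces to itself", {
  ped <- pedigreeFromIds(as.character(1:20))
  set.seed(33)
  g <- genotypeMatrix(matrix(sample(c(-1, 0, 1), 20 * 60, replace = TRUE),
                             20, 60))
  vc <- defaultVarComp("gblup")
  phen <- data.frame(animal = as.character(1:20),
                     y = rnorm(20), stringsAsFactors = FALSE)
  spec <- modelSpec("gblup")
  full <- runEvaluation(spec, ped, phen, vc, geno = g, mode = "full")
  red <- runEvaluation(spec, ped, phen, vc, geno = g, mode = "reduced")
  expect_equal(red$solutions@values, full$solutions@values,
               tolerance = 1e-9)
  expect_equal(red$details$nAbsorbed, 0L)
})

test_that("explicitly retained animals of interest skip back-solving", {
  ds <- familyDataset("basic", seed = 211, nTotal = 120, nFounders = 15,
                      nGenerations = 4)
  absorbed <- setdiff(animalIds(ds$ped),
                      unique(ds$phen$animal))
  extras <- absorbed[1:3]
  red <- runEvaluation(ds$spec, ds$ped, ds$phen, ds$vc, mode = "reduced",
                       extras = extras)
  expect_true(all(match(extras, animalIds(ds$ped)) %in%
                    red$details$retained))
  full <- runEvaluation(ds$spec, ds$ped, ds$phen, ds$vc, mode = "full")
  rep <- checkEquivalence(full$solutions, red$solutions)
  expect_true(rep@pass)
})
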