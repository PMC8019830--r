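test_that("design matrices relate records to effects as each family demands", {
  ## one record, overall mean only
  ped1 <- pedigreeFromIds("a")
  d1 <- buildDesignMatrices(data.frame(animal = "a", y = 3),
                            ped1, modelSpec("basic"))
  expect_equal(as.matrix(d1$X), matrix(1, dimnames = list(NULL, "mean")))
  expect_equal(as.matrix(d1$Z), matrix(1), ignore_attr = TRUE)

  ## repeatability: W is the phenotyped block of Z
  trio <- trioPedigree()
  dr <- buildDesignMatrices(
    data.frame(animal = c("3", "3"), y = c(1, 2)),
    trio, modelSpec("repeatability"))
  expect_equal(as.matrix(dr$W), cbind(c(1, 1)), ignore_attr = TRUE)
  expect_equal(as.matrix(dr$W), as.matrix(dr$Z[, dr$idxP]))

  ## maternal: S points each record at its dam
  fx <- eightAnimalFixture()
  dm <- buildDesignMatrices(fx$phen, fx$ped,
                            modelSpec("maternal_correlated",
                                      fixedFactors = "sex"))
  dams <- fx$ped@dam[dm$recAnimal]
  expect_equal(dm$damSet, sort(unique(dams[dams > 0])))
  expect_equal(sum(Matrix::colSums(dm$S) > 0), length(dm$damSet))

  ## errors: unknown animal, rank-deficient fixed design
  expect_error(buildDesignMatrices(data.frame(animal = "zz", y = 1),
                                   trio, modelSpec("basic")),
               "absent from the pedigree")
  bad <- data.frame(animal = c("1", "2"), f1 = c("a", "b"),
                    f2 = c("x", "y"), y = c(1, 2))
  expect_error(buildDesignMatrices(bad, trio,
                                   modelSpec("basic",
                                             fixedFactors = c("f1", "f2"))),
               "rank deficient")
})

test_that("the smallest mixed-model equations match the hand layout", {
  ped1 <- pedigreeFromIds("a")
  spec <- modelSpec("basic")
  vc <- varComp(sigmaU2 = 1, sigmaE2 = 1)   # lambda = 1
  d <- buildDesignMatrices(data.frame(animal = "a", y = 7), ped1, spec)
  sys <- assembleFullMME(spec, vc, d, buildAInverse(ped1), ped1)
  expect_equal(unname(as.matrix(sys@lhs)), rbind(c(1, 1), c(1, 2)))
  expect_equal(sys@rhs, c(7, 7))
  expect_equal(solveDirect(sys)@values, c(7, 0))
})

test_that("two unrelated phenotyped founders solve as derived by hand", {
  ped <- pedigreeFromIds(c("1", "2"))
  spec <- modelSpec("basic")
  vc <- varComp(sigmaU2 = 1, sigmaE2 = 1)
  d <- buildDesignMatrices(data.frame(animal = c("1", "2"), y = c(10, 20)),
                           ped, spec)
  sol <- solveDirect(assembleFullMME(spec, vc, d, buildAInverse(ped), ped))
  expect_equal(sol@values, c(15, -2.5, 2.5))
})

test_that("system orders and labels follow the retained set", {
  fx <- eightAnimalFixture()
  d <- buildDesignMatrices(fx$phen, fx$ped, fx$spec)
  Ai <- buildAInverse(fx$ped)
  full <- assembleFullMME(fx$spec, fx$vc, d, Ai, fx$ped)
  expect_equal(length(full@rhs), 2 + 8)   # order(X'X) + all animals

  blocks <- partitionInverse(Ai, d$idxP)
  kern <- schurComplement(blocks)
  red <- assembleReducedMME(fx$spec, fx$vc, d, kern, d$idxP, fx$ped)
  expect_equal(length(red@rhs), 2 + 5)    # order(X'X) + phenotyped
  expect_equal(red@labels$level[red@labels$effect == "u"],
               as.character(4:8))
  expect_error(assembleReducedMME(fx$spec, fx$vc, d, kern, 1:4, fx$ped),
               "mismatch")
})

test_that("reduced assembly equals generic Schur absorption of the full system", {
  ## independent oracle: absorb the u_n equations of the assembled full
  ## LHS directly and compare block by block
  fx <- eightAnimalFixture()
  d <- buildDesignMatrices(fx$phen, fx$ped, fx$spec)
  Ai <- buildAInverse(fx$ped)
  full <- as.matrix(assembleFullMME(fx$spec, fx$vc, d, Ai, fx$ped)@lhs)
  nEq <- 2 + setdiff(1:8, d$idxP)   # equation rows of the absorbed animals
  keep <- setdiff(seq_len(10), nEq)
  oracle <- full[keep, keep] -
    full[keep, nEq] %*% solve(full[nEq, nEq]) %*% full[nEq, keep]
  red <- as.matrix(assembleReducedMME(
    fx$spec, fx$vc, d, schurComplement(partitionInverse(Ai, d$idxP)),
    d$idxP, fx$ped)@lhs)
  expect_equal(red, oracle, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a diagonal multi-trait model decomposes into single-trait fits", {
  ped <- simulatePedigree(nFounders = 10, nGenerations = 3, nTotal = 60,
                          seed = 21)
  vc2 <- varComp(G0 = diag(c(0.4, 0.4)), R0 = diag(c(0.6, 0.6)))
  sim <- simulateTraits(ped, vc2, "multitrait", phenotypingRate = 0.5,
                        seed = 22)
  spec2 <- modelSpec("multitrait", fixedFactors = "herd",
                     traits = c("t1", "t2"))
  fit2 <- runEvaluation(spec2, ped, sim$phen, vc2, mode = "full")
  df2 <- as.data.frame(fit2$solutions)

  vc1 <- varComp(sigmaU2 = 0.4, sigmaE2 = 0.6)
  spec1 <- modelSpec("basic", fixedFactors = "herd", traits = "t1")
  for (tr in c("t1", "t2")) {
    spec1@traits <- tr
    fit1 <- runEvaluation(spec1, ped, sim$phen, vc1, mode = "full")
    df1 <- as.data.frame(fit1$solutions)
    u2 <- df2$value[df2$effect == "u" & df2$trait == tr]
    u1 <- df1$value[df1$effect == "u"]
    expect_equal(u2, u1, tolerance = 1e-9,
                 label = paste("trait", tr, "breeding values"))
  }
})

test_that("variance-component and kinship mismatches are rejected", {
  fx <- eightAnimalFixture()
  d <- buildDesignMatrices(fx$phen, fx$ped, fx$spec)
  Ai <- buildAInverse(fx$ped)
  expect_error(assembleFullMME(fx$spec, varComp(sigmaU2 = 1), d, Ai, fx$ped),
               "requires variance component")
  expect_error(assembleFullMME(fx$spec, fx$vc, d, Ai[1:5, 1:5], fx$ped),
               "does not match")
  expect_error(varComp(sigmaU2 = -1), "positive")
  expect_error(varComp(G0 = matrix(c(1, 2, 2, 1), 2)), "positive definite")
  ## indefinite direct/maternal covariance
  expect_error(assembleFullMME(
    modelSpec("maternal_correlated", fixedFactors = "sex"),
    varComp(sigmaU2 = 0.1, sigmaM2 = 0.1, sigmaUM = 0.5, sigmaE2 = 1,
            sigmaMPE2 = 0.1),
    buildDesignMatrices(fx$phen, fx$ped,
                        modelSpec("maternal_correlated",
                                  fixedFactors = "sex")),
    Ai, fx$ped), "positive definite")
})
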