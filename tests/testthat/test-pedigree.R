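test_that("pedigree reading validates, normalizes and appends implicit founders", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam", "3,1,2", "1,0,0", "2,NA,"), f)
  ped <- readPedigree(f)
  expect_equal(nAnimals(ped), 3L)
  expect_true(all(ped@sire[ped@id == "3"] != 0L))

  ## parent never declared as an animal: appended as founder
  writeLines(c("animal,sire,dam", "A,X,0", "B,0,0"), f)
  ped <- readPedigree(f, strict = FALSE)
  expect_equal(nAnimals(ped), 3L)
  expect_true("X" %in% animalIds(ped))
  ped2 <- sortAndRenumber(ped)
  expect_equal(nAnimals(ped2), 3L)
  expect_error(readPedigree(f, strict = TRUE), "strict")

  ## duplicates and self-ancestry
  writeLines(c("animal,sire,dam", "A,0,0", "A,0,0"), f)
  expect_error(readPedigree(f), "duplicate")
  writeLines(c("animal,sire,dam", "A,A,0"), f)
  expect_error(readPedigree(f), "cycle")
  writeLines(c("animal,sire,dam", "A,B,0", "B,A,0"), f)
  expect_error(readPedigree(f), "cycle")
})

test_that("sorting places parents before offspring, stably and idempotently", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam", "kid,pa,ma", "pa,0,0", "ma,0,0"), f)
  ped <- sortAndRenumber(readPedigree(f))
  expect_equal(animalIds(ped), c("pa", "ma", "kid"))
  expect_equal(ped@sire, c(0L, 0L, 1L))
  expect_equal(ped@dam, c(0L, 0L, 2L))

  ## an already-valid order is untouched (stability => idempotence)
  again <- sortAndRenumber(ped)
  expect_identical(animalIds(again), animalIds(ped))
  expect_identical(again@sire, ped@sire)

  ## random permutations of a simulated pedigree always end up valid
  base <- simulatePedigree(nFounders = 10, nGenerations = 4,
                           nTotal = 100, seed = 42)
  for (s in 1:3) {
    set.seed(s)
    perm <- sample(100)
    inv <- integer(100)
    inv[perm] <- seq_len(100)
    shuffled <- new("Pedigree", id = animalIds(base)[perm],
                    sire = ifelse(base@sire[perm] == 0L, 0L,
                                  inv[pmax(base@sire[perm], 1L)]),
                    dam = ifelse(base@dam[perm] == 0L, 0L,
                                 inv[pmax(base@dam[perm], 1L)]),
                    inbreeding = rep(NA_real_, 100), sorted = FALSE)
    out <- sortAndRenumber(shuffled)
    i <- seq_len(100)
    expect_true(all(out@sire < i) && all(out@dam < i))
    ## same relationship structure as the original
    expect_equal(tabularA(out)[animalIds(base), animalIds(base)],
                 tabularA(base), tolerance = 1e-12)
  }
})

test_that("tabular A reproduces hand-derived relationship matrices", {
  two <- pedigreeFromIds(c("a", "b"))
  expect_equal(unname(tabularA(two)), diag(2))

  trio <- trioPedigree()
  expect_equal(unname(tabularA(trio)),
               rbind(c(1, 0, 0.5), c(0, 1, 0.5), c(0.5, 0.5, 1)))

  A <- tabularA(fullSibMatingPedigree())
  expect_equal(unname(A[5, 5]), 1.25)

  unsorted <- new("Pedigree", id = c("x", "y"), sire = c(2L, 0L),
                  dam = c(0L, 0L), inbreeding = rep(NA_real_, 2),
                  sorted = FALSE)
  expect_error(tabularA(unsorted), "sorted")
})

test_that("inbreeding recursion matches the tabular diagonal", {
  trio <- trioPedigree()
  expect_equal(inbreedingCoefficients(trio), c(0, 0, 0))
  fs <- fullSibMatingPedigree()
  expect_equal(inbreedingCoefficients(fs), c(0, 0, 0, 0, 0.25))
  ped <- simulatePedigree(nFounders = 8, nGenerations = 6, nTotal = 150,
                          seed = 7)
  expect_equal(inbreedingCoefficients(ped), unname(diag(tabularA(ped))) - 1,
               tolerance = 1e-12)
  expect_gt(max(ped@inbreeding), 0)  # deep small population does inbreed
})

test_that("sparse A-inverse equals the dense inverse of tabular A", {
  trio <- trioPedigree()
  expect_equal(unname(as.matrix(buildAInverse(trio))),
               rbind(c(1.5, 0.5, -1), c(0.5, 1.5, -1), c(-1, -1, 2)))
  expect_equal(unname(as.matrix(buildAInverse(pedigreeFromIds(c("a", "b"))))),
               diag(2))

  fs <- fullSibMatingPedigree()
  expect_lt(max(abs(as.matrix(buildAInverse(fs)) - solve(tabularA(fs)))),
            1e-12)

  ## simulated pedigrees, with and without accounting for inbreeding
  ped <- simulatePedigree(nFounders = 15, nGenerations = 5, nTotal = 400,
                          seed = 9)
  A <- tabularA(ped)
  expect_lt(max(abs(as.matrix(buildAInverse(ped) %*% A) - diag(400))),
            1e-10)
  ## classic-constants mode inverts the relationship matrix of a
  ## hypothetical non-inbred pedigree: check it against the explicit
  ## T D T' construction with D from the classic constants
  Ai0 <- buildAInverse(ped, useInbreeding = FALSE)
  s <- ped@sire; d <- ped@dam
  Dc <- 1 - 0.25 * (s > 0) - 0.25 * (d > 0)
  Tm <- diag(400)
  for (i in seq_len(400)) {
    if (s[i] > 0) Tm[i, ] <- Tm[i, ] + 0.5 * Tm[s[i], ]
    if (d[i] > 0) Tm[i, ] <- Tm[i, ] + 0.5 * Tm[d[i], ]
    Tm[i, i] <- 1
  }
  Tm[upper.tri(Tm)] <- 0
  Astar <- Tm %*% diag(Dc) %*% t(Tm)
  expect_lt(max(abs(as.matrix(Ai0 %*% Astar) - diag(400))), 1e-9)
})

test_that("n/p partitioning is an exact round trip", {
  trio <- trioPedigree()
  Ai <- buildAInverse(trio)
  b <- partitionInverse(Ai, 3L)
  expect_equal(unname(as.matrix(b@Knn)), rbind(c(1.5, 0.5), c(0.5, 1.5)))
  expect_equal(unname(as.matrix(b@Knp)), cbind(c(-1, -1)))
  expect_equal(unname(as.matrix(b@Kpp)), matrix(2))

  all3 <- partitionInverse(Ai, 1:3)
  expect_length(all3@idxN, 0L)
  expect_equal(as.matrix(all3@Kpp), as.matrix(Ai))

  set.seed(31)
  for (rep in 1:5) {
    K <- Matrix::forceSymmetric(Matrix::rsparsematrix(20, 20, 0.3))
    idxP <- sort(sample(20, sample(1:19, 1)))
    blk <- partitionInverse(K, idxP)
    expect_identical(as.matrix(reassemblePartition(blk)), as.matrix(K))
  }
  expect_error(partitionInverse(Ai, c(1L, 99L)), "outside")
  expect_error(partitionInverse(Ai, c(1L, 1L)), "duplicate")
})
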