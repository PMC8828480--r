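test_that("terminal index sets take the top-f memberships and stay
           disjoint", {
  chi <- cbind(c(0.9, 0.1, 0.8, 0.05), c(0.1, 0.9, 0.2, 0.95))
  part <- terminalIndexSets(chi, 1, f = 2)
  expect_identical(part$targetSets[[1]], c(1L, 3L))
  expect_identical(part$transient, c(2L, 4L))
  # f = 1: the argmax cell
  expect_identical(terminalIndexSets(chi, 2, f = 1)$targetSets[[1]], 4L)
  expect_error(terminalIndexSets(chi, 1, f = 2)$targetSets, NA)
  expect_error(terminalIndexSets(chi, c(1, 2), f = 2), "transient")
})

test_that("a cell claimed by two sets goes to its higher membership; the
           loser backfills", {
  chi <- cbind(c(0.6, 0.5, 0.3, 0.05, 0.02, 0.02),
               c(0.39, 0.45, 0.65, 0.9, 0.1, 0.05))
  # cell 3 ranks high for both; column 2 wins (0.65 > 0.3)
  part <- terminalIndexSets(chi, c(1, 2), f = 2)
  expect_identical(part$targetSets[[1]], c(1L, 2L))
  expect_identical(part$targetSets[[2]], c(3L, 4L))
  expect_length(intersect(part$targetSets[[1]], part$targetSets[[2]]), 0)
})

test_that("absorbing rows become self-loops and the [Q|S] blocks keep unit
           row sums", {
  P <- Matrix::Matrix(rbind(c(0, 0.3, 0.7),
                            c(0.2, 0.5, 0.3),
                            c(0.1, 0.1, 0.8)), sparse = TRUE)
  part <- list(targetSets = list(a = 2L, b = 3L), transient = 1L, f = 1L,
               lineageNames = c("a", "b"))
  sys <- makeAbsorbing(P, part)
  expect_equal(as.matrix(sys$Q), matrix(0, 1, 1))
  expect_equal(as.vector(sys$S), c(0.3, 0.7))
  expect_equal(Matrix::rowSums(cbind(sys$Q, sys$S)), 1)
  fm <- absorptionProbabilities(P, part)
  expect_equal(fateProbs(fm)[1, ], c(a = 0.3, b = 0.7),
               ignore_attr = TRUE)
  # absorbing cells are one-hot
  expect_equal(fateProbs(fm)[2, ], c(1, 0), ignore_attr = TRUE)
  expect_equal(fateProbs(fm)[3, ], c(0, 1), ignore_attr = TRUE)
})

test_that("gambler's ruin and the transient-self-loop closed forms hold", {
  # fair walk on 4 states, absorbing ends: from the second state,
  # P(absorb right) = 1/3
  P <- matrix(0, 4, 4)
  P[1, 1] <- 1; P[4, 4] <- 1
  P[2, c(1, 3)] <- 0.5; P[3, c(2, 4)] <- 0.5
  part <- list(targetSets = list(left = 1L, right = 4L),
               transient = c(2L, 3L), f = 1L,
               lineageNames = c("left", "right"))
  fm <- fateProbs(absorptionProbabilities(Matrix::Matrix(P, sparse = TRUE),
                                          part))
  expect_equal(fm[2, ], c(2 / 3, 1 / 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fm[3, ], c(1 / 3, 2 / 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # transient self-loop: row (0.5, 0.25, 0.25) -> (0.5, 0.5)
  P2 <- Matrix::Matrix(rbind(c(0.5, 0.25, 0.25), c(0, 1, 0), c(0, 0, 1)),
                       sparse = TRUE)
  part2 <- list(targetSets = list(a = 2L, b = 3L), transient = 1L, f = 1L,
                lineageNames = c("a", "b"))
  fm2 <- fateProbs(absorptionProbabilities(P2, part2))
  expect_equal(fm2[1, ], c(0.5, 0.5), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("sparse solves match the dense fundamental-matrix oracle and the
           GMRES path", {
  for (seed in 1:4) {
    pl <- plantedAbsorbingChain(80, nTargets = 2, f = 5, seed = seed)
    sys <- makeAbsorbing(pl$P, pl$partition)
    fm <- fateProbs(absorptionProbabilities(pl$P, pl$partition))
    # dense oracle: (I - Q)^-1 S, aggregated per target set
    M <- solve(diag(length(pl$partition$transient)) - as.matrix(sys$Q))
    A.dense <- M %*% as.matrix(sys$S)
    oracle <- vapply(1:2, function(t)
      rowSums(A.dense[, sys$recurrentSet == t, drop = FALSE]),
      numeric(nrow(A.dense)))
    expect_lt(max(abs(fm[pl$partition$transient, ] - oracle)), 1e-8)
    expect_rows_sum_to_one(fm, tol = 1e-6)
    fg <- fateProbs(absorptionProbabilities(pl$P, pl$partition,
                                            solver = "gmres"))
    expect_lt(max(abs(fm - fg)), 1e-6)
  }
})

test_that("unreachable transient cells are reported by index", {
  P <- Matrix::Matrix(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                            c(0, 0, 1, 0), c(0, 0, 0, 1)), sparse = TRUE)
  part <- list(targetSets = list(t1 = 4L), transient = 1:3, f = 1L,
               lineageNames = "t1")
  expect_error(absorptionProbabilities(P, part), "cannot reach")
})

test_that("the Monte-Carlo oracle is exact on deterministic chains and
           reproducible", {
  # deterministic 4-chain into an absorbing end
  P <- matrix(0, 4, 4)
  P[1, 2] <- 1; P[2, 3] <- 1; P[3, 4] <- 1; P[4, 4] <- 1
  part <- list(targetSets = list(end = 4L), transient = 1:3, f = 1L,
               lineageNames = "end")
  fm <- mcAbsorptionOracle(Matrix::Matrix(P, sparse = TRUE), part,
                           nWalks = 50, seed = 3)
  expect_equal(fateProbs(fm)[, 1], rep(1, 4))
  fm2 <- mcAbsorptionOracle(Matrix::Matrix(P, sparse = TRUE), part,
                            nWalks = 50, seed = 3)
  expect_identical(fateProbs(fm), fateProbs(fm2))
})

test_that("Monte-Carlo frequencies agree with the analytic solution within
           binomial error", {
  pl <- plantedAbsorbingChain(200, nTargets = 2, f = 10, K = 8, seed = 9)
  analytic <- fateProbs(absorptionProbabilities(pl$P, pl$partition))
  n <- 10000L
  mc <- fateProbs(mcAbsorptionOracle(pl$P, pl$partition, nWalks = n,
                                     seed = 11))
  se <- sqrt(analytic * (1 - analytic) / n)
  z.ok <- abs(mc - analytic) <= 3 * se + 1 / n
  # per-entry 3-sigma coverage with Binomial multiplicity: expect ~99.7%
  expect_gte(mean(z.ok), 0.99)
})
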