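test_that("sorted Schur of a symmetric 2-state chain is its
           eigendecomposition", {
  P <- Matrix::Matrix(rbind(c(0.9, 0.1), c(0.1, 0.9)), sparse = TRUE)
  s <- sortedSchur(P, 2)
  expect_equal(Re(s@eigenvalues), c(1, 0.8), tolerance = 1e-12)
  expect_equal(Im(s@eigenvalues), c(0, 0))
  expect_lt(max(abs(crossprod(s@Q) - diag(2))), 1e-10)
  expect_lt(max(abs(as.matrix(P %*% s@Q) - s@Q %*% s@R)), 1e-10)
})

test_that("block-diagonal unions carry one unit eigenvalue per block,
           matching the dense eigen oracle", {
  pc <- simulatePlantedChain(c(10, 12), leak = 0)   # two closed blocks
  s <- sortedSchur(pc$P, 4)
  expect_equal(Re(s@eigenvalues[1:2]), c(1, 1), tolerance = 1e-10)
  oracle <- sort(Re(eigen(as.matrix(pc$P), only.values = TRUE)$values),
                 decreasing = TRUE)[1:4]
  expect_equal(Re(s@eigenvalues), oracle, tolerance = 1e-8)
})

test_that("the leading eigenvalue of any row-stochastic matrix is 1", {
  for (seed in 1:5) {
    P <- randomChain(40, seed = seed)
    s <- sortedSchur(P, 3)
    expect_lt(Mod(s@eigenvalues[1] - 1), 1e-10)
    # invariance residual
    expect_lt(norm(as.matrix(P %*% s@Q) - s@Q %*% s@R, "F"),
              1e-6 * norm(as.matrix(P), "F"))
  }
})

test_that("Krylov (ARPACK) path agrees with the dense path", {
  # unequal block sizes give a distinct leading spectrum (ARPACK cannot
  # separate exactly degenerate eigenvalues from a single Krylov sequence)
  pc <- simulatePlantedChain(c(50, 60, 70), leak = 1e-2)
  sd. <- sortedSchur(pc$P, 3, method = "dense")
  sk <- sortedSchur(pc$P, 3, method = "krylov")
  expect_equal(Re(sk@eigenvalues), Re(sd.@eigenvalues), tolerance = 1e-8)
  # the spanned subspaces coincide: projector difference is tiny
  Pd <- tcrossprod(sd.@Q); Pk <- tcrossprod(sk@Q)
  expect_lt(max(abs(Pd - Pk)), 1e-6)
})

test_that("conjugate pairs are never split and the error suggests
           alternatives", {
  pc <- simulatePlantedChain(c(20, 20, 20), leak = 0.2, topology = "cycle")
  ev <- eigen(as.matrix(pc$P), only.values = TRUE)$values
  expect_true(any(abs(Im(ev)) > 1e-8))    # the 3-cycle has a complex pair
  s <- sortedSchur(pc$P, 3)
  expect_true(any(s@conjugatePair))
  expect_error(selectInvariantSubspace(s, 2), "nS = 1 or nS = 3")
  expect_error(sortedSchur(pc$P, 2), "m = 1 or m = 3")
  Qt <- selectInvariantSubspace(s, 3)
  expect_equal(dim(Qt), c(60L, 3L))
})

test_that("rotation initialization recovers an exact indicator simplex", {
  pc <- simulatePlantedChain(c(30, 30, 30), leak = 1e-3)
  s <- sortedSchur(pc$P, 3)
  Qt <- velofate:::.weightedSchurBasis(selectInvariantSubspace(s, 3),
                                       rep(1 / 90, 90))
  A0 <- initializeRotation(Qt)
  expect_identical(length(unique(attr(A0, "vertices"))), 3L)
  chi0 <- Qt %*% A0
  expect_gte(minChi(Qt, A0), -1e-9)
  expect_equal(labelAgreement(apply(chi0, 1, which.max), pc$blocks), 1)
  # n_s = 1 is trivial
  expect_equal(initializeRotation(matrix(1, 10, 1))[1, 1], 1)
})

test_that("optimized memberships recover planted blocks to indicator
           precision", {
  pc <- simulatePlantedChain(c(25, 25), leak = 0)
  res <- gpcca(pc$P, 2)
  chi <- memberships(res)
  ind <- indicatorChi(pc$blocks)
  # resolve column permutation
  perm <- apply(crossprod(chi, ind), 1, which.max)
  expect_lt(max(abs(chi - ind[, order(perm)])), 1e-6)
  expect_gte(res@crispness, 0.999)
  expect_lte(res@objective, velofate:::.rotationObjective(
    velofate:::.fillRotation(initializeRotation(
      velofate:::.weightedSchurBasis(selectInvariantSubspace(res@schur, 2),
                                     rep(1 / 50, 50))),
      velofate:::.weightedSchurBasis(selectInvariantSubspace(res@schur, 2),
                                     rep(1 / 50, 50)))) + 1e-12)
  # single macrostate: all-ones memberships, crispness 1
  res1 <- gpcca(pc$P, 1)
  expect_equal(memberships(res1), matrix(1, 50, 1))
  expect_equal(res1@crispness, 1)
})

test_that("memberships satisfy the feasibility contract exactly", {
  for (leak in c(1e-3, 0.02, 0.1)) {
    P <- simulatePlantedChain(c(15, 20, 25), leak = leak)$P
    res <- gpcca(P, 3)
    chi <- memberships(res)
    expect_gte(min(chi), -1e-10)
    expect_lt(max(abs(rowSums(chi) - 1)), 1e-8)
    expect_lt(max(abs(rowSums(coarseTransition(res)) - 1)), 1e-8)
    # determinism
    res2 <- gpcca(P, res@nStates)
    expect_identical(memberships(res2), chi)
  }
})

test_that("coarse-graining an indicator membership block-averages the
           chain", {
  pc <- simulatePlantedChain(c(10, 15), leak = 0)
  chi <- indicatorChi(pc$blocks)
  expect_equal(coarseGrainTransition(pc$P, chi), diag(2), tolerance = 1e-12)
  # arbitrary chain: direct aggregation oracle
  P <- as.matrix(randomChain(30, seed = 5))
  blocks <- rep(1:3, each = 10)
  chi2 <- indicatorChi(blocks)
  Pc <- coarseGrainTransition(P, chi2)
  oracle <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3)
    oracle[a, b] <- mean(rowSums(P[blocks == a, blocks == b, drop = FALSE]))
  expect_equal(Pc, oracle, tolerance = 1e-10)
})

test_that("projection commutes with propagation on an exact invariant
           subspace", {
  pc <- simulatePlantedChain(c(20, 20, 20), leak = 1e-3)
  res <- gpcca(pc$P, 3)
  chi <- memberships(res)
  N <- nrow(chi)
  set.seed(6)
  d <- stats::runif(N); d <- d / sum(d)
  M <- crossprod(chi) / N
  project <- function(dens) solve(M, crossprod(chi, dens / N))
  lhs <- project(as.vector(Matrix::t(pc$P) %*% d))     # propagate then project
  rhs <- as.vector(t(coarseTransition(res)) %*% project(d))
  expect_lt(max(abs(lhs - rhs)), 1e-8)
})

test_that("crispness is 1 for indicators, 1/nS for maximal mixing, and
           decreases under blending", {
  chi <- indicatorChi(rep(1:3, each = 10))
  expect_equal(crispness(chi), 1)
  mixed <- matrix(1 / 3, 30, 3)
  expect_equal(crispness(mixed), 1 / 3)
  xis <- vapply(seq(0, 1, by = 0.1), function(a)
    crispness((1 - a) * chi + a * mixed), numeric(1))
  expect_true(all(diff(xis) < 1e-12))
})

test_that("minChi flags a poor macrostate count on a mixed chain", {
  # blend a random chain into the planted one so the spectrum is simple:
  # an exactly block-uniform chain has a huge degenerate null space and
  # the third Schur vector would be arbitrary
  pc <- simulatePlantedChain(c(40, 50), leak = 0.05)
  P <- 0.7 * pc$P + 0.3 * randomChain(90, K = 8, seed = 4)
  s <- sortedSchur(P, 3)
  w <- rep(1 / 90, 90)
  # right count: near zero
  Qt2 <- velofate:::.weightedSchurBasis(selectInvariantSubspace(s, 2), w)
  expect_gte(minChi(Qt2, initializeRotation(Qt2)), -1e-6)
  # one macrostate too many on a 2-block chain: strongly negative
  Qt3 <- velofate:::.weightedSchurBasis(selectInvariantSubspace(s, 3), w)
  expect_lt(minChi(Qt3, initializeRotation(Qt3)), -0.01)
})

test_that("eigengap strategy picks the spectral plateau", {
  pc <- simulatePlantedChain(c(50, 50, 50), leak = 1e-3)
  n.s <- suggestNStates(pc$P, range = 2:6, strategy = "eigengap")
  expect_equal(as.integer(n.s), 3L)
})

test_that("crispness scan recovers a planted 4-block chain and prunes
           pair-splitting candidates", {
  # unequal blocks: with exactly symmetric blocks the leading eigenspace
  # is degenerate and merged super-blocks are just as crisp as the true
  # partition, so the scan would be genuinely ambiguous
  pc <- simulatePlantedChain(c(40, 30, 20, 35), leak = 1e-3)
  n.s <- suggestNStates(pc$P, range = 2:5, strategy = "crispness_scan")
  expect_equal(as.integer(n.s), 4L)
  n.s2 <- suggestNStates(pc$P, range = 2:5,
                         strategy = "minchi_then_crispness")
  expect_equal(as.integer(n.s2), 4L)
  # cycle topology: candidate 2 splits the complex pair and is pruned
  pcc <- simulatePlantedChain(c(20, 20, 20), leak = 0.2, topology = "cycle")
  n.s3 <- suggestNStates(pcc$P, range = 2:3, strategy = "eigengap")
  diagn <- attr(n.s3, "diagnostics")
  expect_false(2L %in% diagn$nS)
  expect_error(suggestNStates(pc$P, range = integer()), "empty")
})
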