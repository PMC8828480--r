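test_that("stationary distribution matches the two-state closed form", {
  P <- Matrix::Matrix(rbind(c(0.9, 0.1), c(0.2, 0.8)), sparse = TRUE)
  pi <- stationaryDistribution(P)
  expect_equal(pi, c(2 / 3, 1 / 3), tolerance = 1e-10)
  expect_lt(sum(abs(as.vector(pi %*% P) - pi)), 1e-10)
})

test_that("doubly stochastic chains have the uniform stationary
           distribution", {
  # symmetric random walk on a 5-cycle
  P <- matrix(0, 5, 5)
  for (i in 1:5) { P[i, (i %% 5) + 1] <- 0.5; P[i, ((i - 2) %% 5) + 1] <- 0.5 }
  expect_equal(stationaryDistribution(Matrix::Matrix(P, sparse = TRUE)),
               rep(0.2, 5), tolerance = 1e-12)
})

test_that("pi' P = pi' holds at 1e-10 on random irreducible chains", {
  for (seed in 1:5) {
    P <- randomChain(50, seed = seed)
    pi <- stationaryDistribution(P)
    expect_lt(sum(abs(as.vector(pi %*% P) - pi)), 1e-10)
    expect_equal(sum(pi), 1, tolerance = 1e-12)
    expect_true(all(pi >= 0))
  }
})

test_that("reducible chains are refused with a pointer to
           handleReducible", {
  P <- simulatePlantedChain(c(5, 5), leak = 0)$P
  expect_error(stationaryDistribution(P), "handleReducible")
})

test_that("coarse stationary distribution aggregates block masses", {
  blocks <- rep(1:2, c(3, 2))
  chi <- indicatorChi(blocks)
  pi <- c(0.1, 0.2, 0.3, 0.25, 0.15)
  expect_equal(coarseStationary(chi, pi), c(0.6, 0.4))
  # uniform pi, uniform chi -> uniform
  expect_equal(coarseStationary(matrix(1 / 3, 6, 3), rep(1 / 6, 6)),
               rep(1 / 3, 3))
})

test_that("the CGSD matches the block-level stationary oracle on a planted
           chain", {
  sizes <- c(50, 30, 20); eps <- 0.01; N <- sum(sizes)
  pc <- simulatePlantedChain(sizes, leak = eps)
  res <- gpcca(pc$P, 3)
  pic <- coarseStationary(res, stationaryDistribution(pc$P))
  # oracle: the exact 3-state block-level chain of the construction
  B <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3)
    B[a, b] <- if (a == b) 1 - eps else eps * sizes[b] / (N - sizes[a])
  piB <- stationaryDistribution(Matrix::Matrix(B, sparse = TRUE))
  expect_equal(sort(pic), sort(piB), tolerance = 1e-3)
  expect_equal(sum(pic), 1, tolerance = 1e-8)
})

test_that("terminal classification thresholds the printed stability
           indices", {
  Pc <- diag(c(0.97, 1.00, 0.98, 0.84))
  Pc[4, 1:3] <- (1 - 0.84) / 3
  Pc[1, 4] <- 0.03; Pc[3, 4] <- 0.02
  term <- classifyTerminal(Pc, 0.96)
  expect_identical(as.integer(term), c(1L, 2L, 3L))
  expect_equal(attr(term, "SI"), c(0.97, 1.00, 0.98, 0.84))
  # disconnected blocks: all diagonal 1, all terminal
  expect_identical(as.integer(classifyTerminal(diag(3), 0.96)), 1:3)
  # a single weakly stable macrostate is not terminal; warning is raised
  expect_warning(t2 <- classifyTerminal(matrix(0.84), 0.96), "lowering")
  expect_length(t2, 0)
})

test_that("manual override promotes a weakly stable macrostate to
           terminal", {
  pc <- simulatePlantedChain(c(20, 20, 20), leak = 0.05, topology = "line")
  res <- gpcca(pc$P, 3)
  cls <- classifyStates(res, pc$P, siThreshold = 0.999)
  cls2 <- classifyStates(res, pc$P, siThreshold = 0.999,
                         forceTerminal = setdiff(1:3, cls@terminal)[1])
  expect_gt(length(cls2@terminal), length(cls@terminal))
  expect_length(intersect(cls2@terminal, cls2@initial), 0)
})

test_that("initial classification takes the smallest CGSD entries", {
  pic <- c(2e-6, 0.4, 0.3, 0.3)
  expect_identical(classifyInitial(pic), 1L)
  expect_identical(classifyInitial(c(0.5, 0.2, 0.1, 0.3), nInitial = 2),
                   c(3L, 2L))
  # excluded (terminal) macrostates cannot be initial
  expect_identical(classifyInitial(c(2e-6, 0.4, 0.25, 0.35), exclude = 1L),
                   3L)
  expect_warning(ties <- classifyInitial(c(0.25, 0.25, 0.5)), "tie")
  expect_identical(ties, 1L)
  expect_error(classifyInitial(pic, nInitial = 5), "exceeds")
})

test_that("reducibility handling excludes an isolated clique and restores
           a solvable chain", {
  pc <- simulatePlantedChain(c(40, 5), leak = 0)   # main block + 5-clique
  chi <- indicatorChi(pc$blocks)
  red <- handleReducible(pc$P, chi)
  expect_equal(red$nComponents, 2L)
  expect_identical(red$excludedCells, 41:45)
  expect_identical(red$outlierMacrostates, 2L)
  expect_equal(sum(red$pi), 1, tolerance = 1e-10)
  expect_true(all(red$pi[41:45] == 0))
  # connected chains report a single component and no exclusions
  red2 <- handleReducible(randomChain(30, seed = 2))
  expect_equal(red2$nComponents, 1L)
  expect_length(red2$excludedCells, 0)
})

test_that("reversing the chain turns the planted source into a terminal
           state", {
  sim <- simulateBranchingField(nCells = 300, nGenes = 10, nBranches = 1,
                                seed = 4)
  g <- computeSimilarities(buildKNN(projectPCA(sim$vd, 5), K = 15))
  # forward: the sink is terminal
  vk <- velocityKernel(sim$vd, g, mode = "deterministic")
  ck <- connectivityKernel(g)
  P <- combineKernels(list(vk, ck), c(0.8, 0.2))
  fw <- gpcca(P, 2)
  fw.term <- classifyTerminal(coarseTransition(fw), 0.9)
  expect_length(fw.term, 1)
  top.fw <- order(memberships(fw)[, fw.term], decreasing = TRUE)[1:30]
  expect_gt(mean(sim$trueTime[top.fw]), 0.8)
  # backward: the planted source cells belong to a terminal state of the
  # reversed chain (the old sink may stay weakly metastable too, since the
  # planted flow vanishes there in both directions)
  rev <- recoverInitialByReversal(sim$vd, g, nS = 2, siThreshold = 0.9)
  expect_gte(length(rev$terminal), 1)
  memb.term <- rowSums(memberships(rev$gpcca)[, rev$terminal,
                                              drop = FALSE])
  expect_gt(mean(memb.term[sim$sourceCells]), 0.9)
})

test_that("a zero velocity field makes forward and backward kernels
           identical", {
  set.seed(21)
  x <- matrix(rnorm(30 * 4), 30, 4)
  vd <- VelocityData(x, matrix(0, 30, 4))
  g <- buildKNN(x, K = 4)
  suppressWarnings({
    fw <- velocityKernel(vd, g)
    bw <- velocityKernel(vd, g, backward = TRUE)
  })
  expect_identical(as.matrix(transitionProbs(fw)),
                   as.matrix(transitionProbs(bw)))
})
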