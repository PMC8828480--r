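test_that("velocity correlations reproduce hand-computed cosines", {
  S <- rbind(c(2, 0, -2), c(-2, 0, 2), c(0, 1, -1))
  v <- c(1, 0, -1)
  cc <- velofate:::.pearsonRows(S, v)
  expect_equal(cc, c(1, -1, 0.5), tolerance = 1e-12)
  # zero-variance velocity: whole row undefined
  expect_true(all(is.na(velofate:::.pearsonRows(S, c(2, 2, 2)))))
  # zero-variance state change (duplicated neighbour): neutral 0
  expect_equal(velofate:::.pearsonRows(rbind(c(1, 1, 1)), v), 0)
})

test_that("softmax transform matches direct evaluation and its limits", {
  expect_equal(softmaxTransform(c(0, 0), 3), c(0.5, 0.5))
  p <- softmaxTransform(c(1, -1), 1)
  expect_equal(p, c(exp(2), 1) / (1 + exp(2)), tolerance = 1e-12)
  expect_equal(round(p, 4), c(0.8808, 0.1192))
  expect_gt(softmaxTransform(c(1, -1), 100)[1], 0.9999)
  expect_equal(sum(softmaxTransform(rnorm(10) * 50, 30)), 1)
  expect_error(softmaxTransform(numeric(), 1), "empty")
  expect_error(softmaxTransform(c(1, 2), -1), "sigma")
})

test_that("sigma heuristic inverts the median absolute correlation", {
  expect_equal(estimateSigma(c(0.5, -0.5, 0.5)), 2)
  cc <- c(0.2, -0.4, 0.6, -0.8)
  sg <- estimateSigma(cc)
  expect_equal(sg, 2)
  # after scaling, the median absolute correlation is exactly 1
  expect_equal(stats::median(sg * abs(cc)), 1)
  expect_warning(expect_equal(estimateSigma(c(0, 0, 0)), 1), "sigma = 1")
  # list input (per-cell vectors) with NAs dropped
  expect_equal(estimateSigma(list(c(0.5, NA), c(-0.5))), 2)
})

test_that("velocity moments are neighbourhood means and clipped variances", {
  x <- rbind(c(0, 0), c(1, 0), c(10, 10))
  v <- rbind(c(0, 0), c(2, 2), c(5, 5))
  vd <- VelocityData(x, v)
  g <- buildKNN(x, K = 1)
  mom <- estimateVelocityMoments(vd, g)
  # cell 1's neighbourhood = {1, 2}: velocities (0,0) and (2,2)
  expect_equal(mom@mu[1, ], c(1, 1))
  expect_equal(mom@var[1, ], c(1, 1))
  # identical velocities give zero variance
  vd2 <- VelocityData(x, rbind(c(2, 2), c(2, 2), c(2, 2)))
  mom2 <- estimateVelocityMoments(vd2, g)
  expect_equal(mom2@mu, matrix(2, 3, 2))
  expect_equal(mom2@var, matrix(0, 3, 2))
  expect_true(all(mom@var >= 0))
})

test_that("analytic softmax Hessian diagonal matches central differences", {
  set.seed(7)
  for (rep in 1:5) {
    G <- sample(5:15, 1); K <- sample(3:8, 1)
    S <- matrix(rnorm(K * G), K, G)
    v <- rnorm(G)
    sg <- stats::runif(1, 0.5, 4)
    Ha <- softmaxHessianDiag(v, S, sg)
    Hf <- softmaxHessianDiag(v, S, sg, method = "fd", h = 3e-4)
    expect_lt(max(abs(Ha - Hf)) / max(abs(Hf)), 1e-6)
  }
})

test_that("uncertainty propagation: zero variance reduces to the
           deterministic softmax exactly", {
  set.seed(8)
  S <- matrix(rnorm(5 * 8), 5, 8)
  mu <- rnorm(8)
  er <- velofate:::.expectedRow(mu, rep(0, 8), S, 2)
  expect_false(er$fallback)
  expect_identical(er$p,
                   softmaxTransform(velofate:::.pearsonRows(S, mu), 2))
})

test_that("expected row matches the finite-difference second-order oracle", {
  set.seed(9)
  S <- matrix(rnorm(5 * 10), 5, 10)
  mu <- rnorm(10)
  va <- rep(0.1, 10)
  sg <- 2
  er <- velofate:::.expectedRow(mu, va, S, sg)
  Hf <- softmaxHessianDiag(mu, S, sg, method = "fd", h = 3e-4)
  p0 <- softmaxTransform(velofate:::.pearsonRows(S, mu), sg)
  oracle <- p0 + 0.5 * as.vector(Hf %*% va)
  oracle <- pmax(oracle, 0); oracle <- oracle / sum(oracle)
  expect_lt(max(abs(er$p - oracle)), 1e-6)
})

test_that("expected row agrees with the Monte-Carlo mean within 3 MC
           standard errors in the small-noise regime", {
  set.seed(10)
  S <- matrix(rnorm(6 * 12), 6, 12)
  mu <- rnorm(12)
  va <- rep(0.01, 12)
  sg <- 2
  er <- velofate:::.expectedRow(mu, va, S, sg)
  n <- 50000L
  # per-draw rows, to measure the MC standard error directly
  draws <- matrix(0, n, 6)
  chunk <- matrix(rnorm(n * 12, mean = rep(mu, each = n),
                        sd = rep(sqrt(va), each = n)), n, 12)
  for (r in seq_len(n))
    draws[r, ] <- softmaxTransform(velofate:::.pearsonRows(S, chunk[r, ]), sg)
  mc.mean <- colMeans(draws)
  mc.se <- apply(draws, 2, stats::sd) / sqrt(n)
  expect_true(all(abs(er$p - mc.mean) <= 3 * mc.se + 1e-12))
})

test_that("velocity kernel reproduces the worked three-cell example", {
  x <- rbind(c(0, 0), c(1, 0), c(0, 1))
  v <- rbind(c(1, 0), c(-1, 0), c(0, -1))
  vd <- VelocityData(x, v)
  g <- buildKNN(x, K = 1)      # union graph: 1-{2,3}, 2-{1}, 3-{1}
  tk <- velocityKernel(vd, g, mode = "deterministic")
  # all 2-gene correlations are +/-1, so sigma auto = 1
  expect_equal(tk@params$sigma, 1)
  P <- as.matrix(transitionProbs(tk))
  expect_equal(P[1, 2:3], c(exp(2), 1) / (1 + exp(2)), tolerance = 1e-10)
  expect_equal(round(P[1, 2:3], 4), c(0.8808, 0.1192))
  expect_rows_sum_to_one(transitionProbs(tk))
})

test_that("stochastic mode with zero variance equals deterministic mode
           bit for bit", {
  set.seed(12)
  x <- matrix(rnorm(40 * 4), 40, 4)
  v <- matrix(rnorm(40 * 4), 40, 4)
  vd <- VelocityData(x, v)
  g <- computeSimilarities(buildKNN(x, K = 5))
  mom0 <- new("VelocityMoments", mu = v, var = matrix(0, 40, 4))
  det <- velocityKernel(vd, g, mode = "deterministic")
  sto <- velocityKernel(vd, g, mode = "stochastic", moments = mom0)
  expect_identical(as.matrix(transitionProbs(det)),
                   as.matrix(transitionProbs(sto)))
})

test_that("sampling mode converges to the analytic expectation on a
           synthetic field", {
  # small-noise moments supplied explicitly: the regime where the
  # second-order expansion is valid (it degrades where the velocity
  # magnitude is comparable to its neighbourhood spread)
  sim <- simulateBranchingField(nCells = 100, nGenes = 10, seed = 3,
                                noiseSd = 0.05)
  g <- computeSimilarities(buildKNN(projectPCA(sim$vd, 5), K = 10))
  V <- velocityMatrix(sim$vd)
  mom <- new("VelocityMoments", mu = V,
             var = matrix(0.0025 * rowSums(V^2) / 10, 100, 10))
  sto <- velocityKernel(sim$vd, g, mode = "stochastic", moments = mom)
  sam <- velocityKernel(sim$vd, g, mode = "sampling", nSamples = 10000L,
                        seed = 42, moments = mom)
  d <- max(abs(transitionProbs(sto) - transitionProbs(sam)))
  expect_lt(d, 0.01)
  # seeded sampling is reproducible
  sam2 <- velocityKernel(sim$vd, g, mode = "sampling", nSamples = 100L,
                         seed = 42)
  sam3 <- velocityKernel(sim$vd, g, mode = "sampling", nSamples = 100L,
                         seed = 42)
  expect_identical(as.matrix(transitionProbs(sam2)),
                   as.matrix(transitionProbs(sam3)))
})

test_that("zero-variance velocity rows fall back to uniform with a warning", {
  x <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  v <- rbind(c(1, 1), c(0.5, 0), c(0, 2), c(1, 0))   # cell 1 constant vector
  vd <- VelocityData(x, v)
  g <- buildKNN(x, K = 3)
  expect_warning(tk <- velocityKernel(vd, g, mode = "deterministic"),
                 "fell back")
  P <- as.matrix(transitionProbs(tk))
  expect_equal(P[1, 2:4], rep(1 / 3, 3))
})

test_that("backward kernel equals the forward kernel of the negated field", {
  set.seed(13)
  x <- matrix(rnorm(30 * 5), 30, 5)
  v <- matrix(rnorm(30 * 5), 30, 5)
  g <- buildKNN(x, K = 4)
  for (m in c("deterministic", "stochastic")) {
    fw <- velocityKernel(VelocityData(x, -v), g, mode = m)
    bw <- velocityKernel(VelocityData(x, v), g, mode = m, backward = TRUE)
    expect_identical(as.matrix(transitionProbs(fw)),
                     as.matrix(transitionProbs(bw)))
    expect_true(isBackward(bw))
  }
  # reversal of reversal: negating twice restores the forward kernel
  fw0 <- velocityKernel(VelocityData(x, v), g)
  fw2 <- velocityKernel(VelocityData(x, -(-v)), g)
  expect_identical(as.matrix(transitionProbs(fw0)),
                   as.matrix(transitionProbs(fw2)))
})

test_that("connectivity kernel row-normalizes the adjacency", {
  A <- Matrix::Matrix(rbind(c(0, 2), c(2, 0)), sparse = TRUE)
  P <- as.matrix(transitionProbs(connectivityKernel(A)))
  expect_equal(P, rbind(c(0, 1), c(1, 0)))
  A2 <- Matrix::Matrix(rbind(c(0, 1, 3), c(1, 0, 0), c(3, 0, 0)),
                       sparse = TRUE)
  P2 <- as.matrix(transitionProbs(connectivityKernel(A2)))
  expect_equal(P2[1, ], c(0, 0.25, 0.75))
  expect_true(all(P2 >= 0))
  # isolated cell: self-loop with warning
  A3 <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1, dims = c(3, 3))
  expect_warning(P3 <- connectivityKernel(A3), "isolated")
  expect_equal(as.matrix(transitionProbs(P3))[3, 3], 1)
})

test_that("kernel combination is a row-stochastic convex combination", {
  set.seed(14)
  x <- matrix(rnorm(20 * 3), 20, 3)
  v <- matrix(rnorm(20 * 3), 20, 3)
  vd <- VelocityData(x, v)
  g <- computeSimilarities(buildKNN(x, K = 4))
  vk <- velocityKernel(vd, g)
  ck <- connectivityKernel(g)
  expect_identical(as.matrix(transitionProbs(combineKernels(list(vk, ck),
                                                            c(1, 0)))),
                   as.matrix(transitionProbs(vk)))
  expect_identical(as.matrix(transitionProbs(combineKernels(list(vk, ck),
                                                            c(0, 1)))),
                   as.matrix(transitionProbs(ck)))
  P <- combineKernels(list(vk, ck), c(0.8, 0.2))
  expect_rows_sum_to_one(transitionProbs(P))
  expect_equal(as.matrix(transitionProbs(P)),
               as.matrix(0.8 * transitionProbs(vk) +
                           0.2 * transitionProbs(ck)))
  bk <- velocityKernel(vd, g, backward = TRUE)
  expect_error(combineKernels(list(vk, bk), c(0.5, 0.5)), "backward")
  expect_error(combineKernels(list(vk, ck), c(0.5, 0.6)), "sum to 1")
})
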