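# Small fixtures built in code; all randomness seeded per call.

# three cells in 2 genes with a velocity pointing from cell 1 towards cell 2
toyTriangle <- function() {
  x <- rbind(c(0, 0), c(1, 0), c(0, 1))
  v <- rbind(c(1, 0), c(-1, 1), c(1, -1))
  VelocityData(x, v, cellIds = c("a", "b", "c"), geneIds = c("g1", "g2"))
}

# dense random irreducible row-stochastic chain with sparse-ish support
randomChain <- function(N, K = 5L, seed = 1L, selfLoops = TRUE) {
  set.seed(seed)
  P <- matrix(0, N, N)
  for (i in seq_len(N)) {
    nb <- sample(setdiff(seq_len(N), i), K)
    P[i, nb] <- stats::runif(K)
    if (selfLoops) P[i, i] <- stats::runif(1)
  }
  P <- P + 1e-6            # tiny uniform mass guarantees irreducibility
  P <- P / rowSums(P)
  Matrix::Matrix(P, sparse = TRUE)
}

# random chain with planted absorbing targets: target cells get self-loops
plantedAbsorbingChain <- function(N, nTargets = 2L, f = 5L, K = 6L,
                                  seed = 1L) {
  set.seed(seed)
  P <- as.matrix(randomChain(N, K = K, seed = seed))
  targets <- split(sample.int(N, nTargets * f),
                   rep(seq_len(nTargets), each = f))
  names(targets) <- sprintf("t%d", seq_len(nTargets))
  partition <- list(targetSets = lapply(targets, sort),
                    transient = setdiff(seq_len(N), unlist(targets)),
                    f = f, lineageNames = names(targets))
  list(P = Matrix::Matrix(P, sparse = TRUE), partition = partition)
}

# indicator membership matrix from a block assignment
indicatorChi <- function(blocks) {
  nb <- max(blocks)
  chi <- matrix(0, length(blocks), nb)
  chi[cbind(seq_along(blocks), blocks)] <- 1
  chi
}

# fraction of labels matching a planted block assignment, maximized over
# label permutations (exact for small k)
labelAgreement <- function(labels, truth) {
  k <- max(labels, truth)
  perms <- velofate:::.permutations(seq_len(k))
  best <- 0
  for (r in seq_len(nrow(perms)))
    best <- max(best, mean(perms[r, ][labels] == truth))
  best
}

expect_rows_sum_to_one <- function(P, tol = 1e-10) {
  expect_lt(max(abs(Matrix::rowSums(P) - 1)), tol)
}
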