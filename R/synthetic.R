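.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old.seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old.seed, envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Planted-macrostate Markov chain
#'
#' Block-stochastic chain with known ground truth: within each block the
#' row is uniform over the block (total mass 1 - leak) and the leak mass
#' is spread over other blocks according to the block-level topology:
#' \code{uniform} (all other blocks), \code{line} (block b leaks to b + 1;
#' the last block keeps all mass, a sink) or \code{cycle}.  With leak 0
#' the chain is reducible and the exact GPCCA solution is the indicator
#' membership matrix.
#'
#' The construction is deterministic given its parameters; the seed is
#' stored for provenance.
#'
#' @param blockSizes integer vector of block sizes (each >= 2).
#' @param leak off-block transition mass in [0, 0.5).
#' @param seed stored in the output.
#' @param topology block-level leak topology.
#' @return list with the sparse transition matrix \code{P}, the per-state
#'   \code{blocks} assignment and the parameters.
#' @export
simulatePlantedChain <- function(blockSizes, leak = 1e-3, seed = 1L,
                                 topology = c("uniform", "line", "cycle")) {
  topology <- match.arg(topology)
  if (leak < 0 || leak >= 0.5) stop("leak must lie in [0, 0.5)")
  if (any(blockSizes < 2L)) stop("block sizes must be >= 2")
  nb <- length(blockSizes)
  N <- sum(blockSizes)
  blocks <- rep(seq_len(nb), times = blockSizes)
  P <- matrix(0, N, N)
  for (b in seq_len(nb)) {
    rows <- which(blocks == b)
    targets <- switch(topology,
      uniform = setdiff(seq_len(nb), b),
      line = if (b < nb) b + 1L else integer(),
      cycle = (b %% nb) + 1L)
    eps <- if (length(targets)) leak else 0
    P[rows, rows] <- (1 - eps) / length(rows)
    if (length(targets)) {
      tcells <- which(blocks %in% targets)
      P[rows, tcells] <- eps / length(tcells)
    }
  }
  list(P = methods::as(Matrix::Matrix(P, sparse = TRUE), "CsparseMatrix"),
       blocks = blocks, leak = leak, topology = topology, seed = seed)
}

# cubic Bezier point and derivative
.bezier <- function(ctrl, s) {
  s1 <- 1 - s
  outer(s1^3, ctrl[1L, ]) + outer(3 * s1^2 * s, ctrl[2L, ]) +
    outer(3 * s1 * s^2, ctrl[3L, ]) + outer(s^3, ctrl[4L, ])
}
.bezierDeriv <- function(ctrl, s) {
  s1 <- 1 - s
  outer(3 * s1^2, ctrl[2L, ] - ctrl[1L, ]) +
    outer(6 * s1 * s, ctrl[3L, ] - ctrl[2L, ]) +
    outer(3 * s^2, ctrl[4L, ] - ctrl[3L, ])
}

#' Branching vector field with planted source and attractors
#'
#' Cells are sampled along smooth parametric curves in a low-dimensional
#' latent space embedded into gene space by a random orthonormal map: a
#' shared root segment from the planted source, bifurcating into
#' \code{nBranches} branches that terminate in attractors.  Expression is
#' curve position plus Gaussian noise; velocity is the exact curve
#' derivative (scaled by a speed profile that decays quadratically to zero
#' at the attractors, so terminal neighbourhoods have inward-pointing,
#' vanishing flow) plus Gaussian noise.  Control points cluster near the
#' source and the attractor ends, so sampled cells pile up there — the
#' spatial signature of initial and terminal populations.
#'
#' @param nCells number of cells (default 1000).
#' @param nGenes number of genes (>= 3; default 20).
#' @param nBranches number of branches after the root segment (default 2).
#' @param noiseSd s.d. of the additive Gaussian noise on expression and
#'   velocity (default 0.05).
#' @param seed RNG seed; generation is a pure function of parameters +
#'   seed.
#' @param rootFraction fraction of progression time spent on the shared
#'   root (default 0.4).
#' @return list with \code{vd} (a [VelocityData-class]), \code{trueTime}
#'   (progression in [0, 1]), \code{branch} (factor: root / branch_b),
#'   \code{branchProgress} (branch-local progress, NA on the root),
#'   \code{sourceCells}, \code{attractorCells} (list per branch) and the
#'   parameters.
#' @export
simulateBranchingField <- function(nCells = 1000L, nGenes = 20L,
                                   nBranches = 2L, noiseSd = 0.05,
                                   seed = 1L, rootFraction = 0.4) {
  if (nGenes < 3L) stop("need at least 3 genes")
  if (nBranches < 1L) stop("need at least 1 branch")
  .withSeed(seed, {
    d <- max(3L, nBranches + 1L)
    if (d > nGenes) stop("nGenes too small for this many branches")
    # root: slow start (source), moderate end
    R0 <- rep(0, d)
    R3 <- c(2, rep(0, d - 1L))
    R1 <- c(0.15, rep(0, d - 1L))
    R2 <- c(1.7, rep(0, d - 1L))
    root.ctrl <- rbind(R0, R1, R2, R3)
    # branches: C1 continuation, fanning out in latent dims 1:2 (and 3+),
    # with the last control point close to the end (slow, dense attractor)
    theta <- seq(-pi / 3, pi / 3, length.out = max(nBranches, 2L))
    if (nBranches == 1L) theta <- 0
    br.ctrl <- lapply(seq_len(nBranches), function(b) {
      dir <- rep(0, d)
      dir[1L] <- cos(theta[b]); dir[2L] <- sin(theta[b])
      if (b > 2L && d >= 4L) dir[b + 1L] <- 0.5   # extra separation
      dir <- dir / sqrt(sum(dir^2))
      B0 <- R3
      B1 <- R3 + c(0.3, rep(0, d - 1L))
      E <- R3 + 2 * dir
      B2 <- E - 0.12 * dir
      rbind(B0, B1, B2, E)
    })
    tau <- stats::runif(nCells)
    on.root <- tau < rootFraction
    branch <- integer(nCells)
    branch[!on.root] <- sample.int(nBranches, sum(!on.root), replace = TRUE)
    latent <- matrix(0, nCells, d)
    vel.latent <- matrix(0, nCells, d)
    s.local <- rep(NA_real_, nCells)
    if (any(on.root)) {
      s <- tau[on.root] / rootFraction
      latent[on.root, ] <- .bezier(root.ctrl, s)
      vel.latent[on.root, ] <- .bezierDeriv(root.ctrl, s) / rootFraction
    }
    for (b in seq_len(nBranches)) {
      sel <- branch == b
      if (!any(sel)) next
      s <- (tau[sel] - rootFraction) / (1 - rootFraction)
      s.local[sel] <- s
      latent[sel, ] <- .bezier(br.ctrl[[b]], s)
      vel.latent[sel, ] <- .bezierDeriv(br.ctrl[[b]], s) *
        (1 - s)^2 / (1 - rootFraction)      # flow dies out at the attractor
    }
    basis <- qr.Q(qr(matrix(stats::rnorm(nGenes * d), nGenes, d)))
    expr <- latent %*% t(basis)
    velo <- vel.latent %*% t(basis)
    if (noiseSd > 0) {
      expr <- expr + matrix(stats::rnorm(nCells * nGenes, sd = noiseSd),
                            nCells, nGenes)
      velo <- velo + matrix(stats::rnorm(nCells * nGenes, sd = noiseSd),
                            nCells, nGenes)
    }
    branch.lab <- factor(ifelse(on.root, "root",
                                sprintf("branch_%d", branch)),
                         levels = c("root",
                                    sprintf("branch_%d", seq_len(nBranches))))
    list(vd = VelocityData(expr, velo),
         trueTime = tau,
         branch = branch.lab,
         branchProgress = s.local,
         sourceCells = which(tau <= 0.05),
         attractorCells = lapply(seq_len(nBranches), function(b)
           which(branch == b & s.local >= 0.9)),
         params = list(nCells = nCells, nGenes = nGenes,
                       nBranches = nBranches, noiseSd = noiseSd,
                       rootFraction = rootFraction, seed = seed))
  })
}

#' Noisy gene families with known trend shapes
#'
#' Generates genes from named shape templates along pseudotime with
#' per-gene amplitude jitter and Gaussian noise; the ground-truth curves
#' are returned for oracle comparisons.  Shapes: \code{linear} (monotone
#' up), \code{sigmoid} (switch-like up) and \code{peak} (transient
#' upregulation).
#'
#' @param nGenesPerFamily genes per family.
#' @param shapes family shape names.
#' @param noiseSd additive Gaussian noise s.d.
#' @param seed RNG seed.
#' @param nCells number of cells.
#' @return list with \code{expr} (cells x genes), \code{tau} (sorted
#'   pseudotime), \code{weights} (unit lineage weights), \code{family}
#'   (per-gene factor) and \code{trueCurves} (cells x genes, noiseless).
#' @export
simulateTrendFamilies <- function(nGenesPerFamily = 50L,
                                  shapes = c("linear", "peak"),
                                  noiseSd = 0.05, seed = 1L, nCells = 300L) {
  known <- c("linear", "sigmoid", "peak")
  bad <- setdiff(shapes, known)
  if (length(bad)) stop(sprintf("unknown shape name: %s", bad[1L]))
  if (length(shapes) < 1L) stop("need at least 1 family")
  .withSeed(seed, {
    tau <- base::sort(stats::runif(nCells))
    shapeFun <- function(name, s) switch(name,
      linear = s,
      sigmoid = 1 / (1 + exp(-10 * (s - 0.5))),
      peak = exp(-(s - 0.5)^2 / (2 * 0.15^2)))
    ng <- nGenesPerFamily * length(shapes)
    expr <- matrix(0, nCells, ng)
    truth <- matrix(0, nCells, ng)
    fam <- character(ng)
    g <- 0L
    for (sh in shapes) for (k in seq_len(nGenesPerFamily)) {
      g <- g + 1L
      amp <- stats::runif(1L, 0.7, 1.3)
      truth[, g] <- amp * shapeFun(sh, tau)
      expr[, g] <- truth[, g] + stats::rnorm(nCells, sd = noiseSd)
      fam[g] <- sh
    }
    colnames(expr) <- colnames(truth) <- sprintf("%s_%d", fam,
                                                 stats::ave(seq_len(ng), fam,
                                                            FUN = seq_along))
    list(expr = expr, tau = tau, weights = rep(1, nCells),
         family = factor(fam, levels = shapes), trueCurves = truth,
         params = list(nGenesPerFamily = nGenesPerFamily, shapes = shapes,
                       noiseSd = noiseSd, seed = seed, nCells = nCells))
  })
}
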