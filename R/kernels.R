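#' Local transition context of a cell
#'
#' Collects, for one reference cell, the symmetrized neighbour set, the
#' state-change vectors s_ik = x_k - x_i (restricted to genes with velocity
#' estimates) and the Pearson correlations of the cell's velocity vector
#' with each state-change vector.  The correlation is the cosine of the
#' angle between the mean-centred velocity and the mean-centred state-change
#' vector; +1 means the neighbour lies exactly in the direction the velocity
#' predicts.
#'
#' @param vd a [VelocityData-class] object.
#' @param graph a [NeighborGraph-class] built on the same cells.
#' @param cell cell index.
#' @param backward negate the velocity vector (time-reversed chain).
#' @param velocity optional replacement velocity matrix (used internally to
#'   evaluate the map at the neighbourhood mean velocity).
#' @return list with \code{neighbors}, \code{stateChange} (K_i x G_used),
#'   \code{correlations} (NA when the velocity vector has zero variance) and
#'   \code{usedGenes}.
#' @export
localTransitionContext <- function(vd, graph, cell, backward = FALSE,
                                   velocity = NULL) {
  used <- !missingGenes(vd)
  if (sum(used) < 2L) stop("need at least 2 genes with velocity estimates")
  nbrs <- graph@neighbors[[cell]]
  if (length(nbrs) == 0L) stop(sprintf("cell %d has no neighbours", cell))
  X <- exprMatrix(vd)[, used, drop = FALSE]
  V <- if (is.null(velocity)) velocityMatrix(vd)[, used, drop = FALSE] else
    velocity[, used, drop = FALSE]
  v <- V[cell, ]
  if (backward) v <- -v
  S <- X[nbrs, , drop = FALSE] - rep(X[cell, ], each = length(nbrs))
  list(neighbors = nbrs, stateChange = S,
       correlations = .pearsonRows(S, v), usedGenes = which(used))
}

# Pearson correlation of vector v against each row of S.
# Zero-variance rows get correlation 0 (a neutral direction: a duplicated
# neighbour carries no directional evidence); zero-variance v gives all-NA.
.pearsonRows <- function(S, v) {
  vt <- v - mean(v)
  vn <- sqrt(sum(vt^2))
  if (vn == 0) return(rep(NA_real_, nrow(S)))
  St <- S - rowMeans(S)
  rn <- sqrt(rowSums(St^2))
  cc <- as.vector(St %*% vt) / (pmax(rn, .Machine$double.xmin) * vn)
  cc[rn == 0] <- 0
  pmin(pmax(cc, -1), 1)
}

#' Softmax transform of correlations into transition probabilities
#'
#' p_k = exp(sigma c_k) / sum_l exp(sigma c_l), computed with
#' max-subtraction for numerical stability.  sigma is the inverse
#' temperature: large sigma concentrates mass on the best-aligned
#' neighbour.
#'
#' @param c numeric vector of correlations (finite).
#' @param sigma positive scalar.
#' @return probability vector summing to 1.
#' @export
softmaxTransform <- function(c, sigma) {
  if (length(c) == 0L) stop("empty neighbour set")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  z <- sigma * c
  e <- exp(z - max(z))
  e / sum(e)
}

#' Estimate the softmax inverse temperature from observed correlations
#'
#' sigma = 1 / median(|c_ik|) over all neighbour-pair correlations, so that
#' after scaling the median absolute correlation is exactly 1.  Datasets
#' with weak alignment between velocities and state-change vectors get
#' their correlations upscaled.
#'
#' @param correlations numeric vector or list of per-cell correlation
#'   vectors; NAs (undefined pairs) are dropped.
#' @return sigma (> 0); falls back to 1 with a warning when the median is 0.
#' @export
estimateSigma <- function(correlations) {
  cc <- unlist(correlations, use.names = FALSE)
  cc <- cc[is.finite(cc)]
  if (length(cc) == 0L) stop("no defined correlations to estimate sigma from")
  med <- stats::median(abs(cc))
  if (med == 0) {
    warning("median absolute correlation is 0; falling back to sigma = 1")
    return(1)
  }
  1 / med
}

#' Neighbourhood moments of the velocity field
#'
#' Models each cell's velocity vector as multivariate normal with diagonal
#' covariance, estimating mean and per-gene variance from the velocity
#' vectors of the cell itself and its graph neighbours (population moments
#' E[v^2] - mu^2, clipped at zero).  Including the reference cell
#' stabilizes singleton neighbourhoods.
#'
#' @param vd a [VelocityData-class] object.
#' @param graph a [NeighborGraph-class].
#' @return a [VelocityMoments-class] object (genes without velocity carry
#'   zero moments).
#' @export
estimateVelocityMoments <- function(vd, graph) {
  V <- velocityMatrix(vd)
  N <- nrow(V); G <- ncol(V)
  mu <- matrix(0, N, G); va <- matrix(0, N, G)
  for (i in seq_len(N)) {
    hood <- c(i, graph@neighbors[[i]])
    Vh <- V[hood, , drop = FALSE]
    m <- colMeans(Vh)
    mu[i, ] <- m
    va[i, ] <- pmax(colMeans(Vh^2) - m^2, 0)
  }
  mu[, missingGenes(vd)] <- 0
  va[, missingGenes(vd)] <- 0
  new("VelocityMoments", mu = mu, var = va)
}

#' Diagonal Hessian of the softmax-of-correlation map
#'
#' The map h sends a velocity vector v to the transition-probability row
#' p = softmax(sigma * cor(v, s_k)).  This returns the diagonal of the
#' Hessian of each component h_k with respect to v, either in closed form
#' or by second-order central finite differences (the independent oracle
#' the analytic derivation is checked against).
#'
#' @param v velocity vector (length G).
#' @param S state-change matrix, K x G (rows s_k).
#' @param sigma softmax inverse temperature.
#' @param method "analytic" or "fd".
#' @param h finite-difference step.
#' @return K x G matrix of second derivatives d^2 p_k / d v_j^2.
#' @export
softmaxHessianDiag <- function(v, S, sigma, method = c("analytic", "fd"),
                               h = 3e-4) {
  method <- match.arg(method)
  G <- length(v)
  if (method == "fd") {
    p0 <- softmaxTransform(.pearsonRows(S, v), sigma)
    H <- matrix(0, nrow(S), G)
    for (j in seq_len(G)) {
      vp <- v; vp[j] <- vp[j] + h
      vm <- v; vm[j] <- vm[j] - h
      pp <- softmaxTransform(.pearsonRows(S, vp), sigma)
      pm <- softmaxTransform(.pearsonRows(S, vm), sigma)
      H[, j] <- (pp + pm - 2 * p0) / h^2
    }
    return(H)
  }
  u <- v - mean(v)
  un2 <- sum(u^2)
  if (un2 == 0) stop("velocity vector has zero variance; Hessian undefined")
  uhat <- u / sqrt(un2)
  St <- S - rowMeans(S)
  rn <- sqrt(rowSums(St^2))
  A <- St / pmax(rn, .Machine$double.xmin)   # unit centred state-change rows
  A[rn == 0, ] <- 0
  cc <- as.vector(A %*% uhat)
  p <- softmaxTransform(cc, sigma)
  # gradient of c_k wrt v:  (a_k - c_k uhat) / |u|   (already centred)
  Gm <- (A - outer(cc, uhat)) / sqrt(un2)
  # diagonal Hessian of c_k wrt v
  Hc <- (-2 * A * rep(uhat, each = nrow(A)) +
           outer(cc, 3 * uhat^2) - outer(cc, rep(1 - 1 / G, G))) / un2
  pG <- colSums(p * Gm)        # E_p[grad]
  pG2 <- colSums(p * Gm^2)     # E_p[grad^2]
  pHc <- colSums(p * Hc)
  term1 <- sigma * p * sweep(Hc, 2L, pHc)
  dev <- sweep(Gm, 2L, pG)
  term2 <- sigma^2 * p * sweep(dev^2, 2L, pG2 - pG^2)
  term1 + term2
}

# Expected transition row under v ~ N(mu, diag(var)): second-order Taylor
# correction using only diagonal Hessian terms, clipped and renormalized.
# Falls back to the deterministic row at mu when the correction is not
# finite.  Returns list(p, fallback).
.expectedRow <- function(mu, var, S, sigma) {
  cc <- .pearsonRows(S, mu)
  if (anyNA(cc)) return(list(p = NULL, fallback = TRUE))
  p0 <- softmaxTransform(cc, sigma)
  if (!any(var > 0)) return(list(p = p0, fallback = FALSE))
  H <- tryCatch(softmaxHessianDiag(mu, S, sigma), error = function(e) NULL)
  if (is.null(H) || !all(is.finite(H)))
    return(list(p = p0, fallback = TRUE))
  p <- p0 + 0.5 * as.vector(H %*% var)
  if (!all(is.finite(p))) return(list(p = p0, fallback = TRUE))
  p <- pmax(p, 0)
  s <- sum(p)
  if (s <= 0) return(list(p = p0, fallback = TRUE))
  list(p = p / s, fallback = FALSE)
}

# Monte-Carlo expected row: average softmax rows over draws from
# N(mu, diag(var)).
.sampledRow <- function(mu, var, S, sigma, n.samples) {
  G <- length(mu)
  Vd <- matrix(stats::rnorm(n.samples * G, mean = rep(mu, each = n.samples),
                            sd = rep(sqrt(var), each = n.samples)),
               n.samples, G)
  Vt <- Vd - rowMeans(Vd)
  vn <- sqrt(rowSums(Vt^2))
  St <- S - rowMeans(S)
  rn <- sqrt(rowSums(St^2))
  A <- St / pmax(rn, .Machine$double.xmin)
  A[rn == 0, ] <- 0
  C <- (Vt %*% t(A)) / pmax(vn, .Machine$double.xmin)   # n.samples x K
  Z <- sigma * C
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  colMeans(P)
}

#' Velocity kernel: direct the KNN graph with the velocity field
#'
#' Builds the row-stochastic velocity-based transition matrix.  Per cell,
#' Pearson correlations between the velocity vector and the state-change
#' vectors towards the symmetrized neighbours are pushed through a softmax
#' with inverse temperature sigma (estimated from the data by default).
#' Three modes are available: \code{deterministic} uses each cell's raw
#' velocity vector; \code{stochastic} (the default for noisy data)
#' propagates velocity uncertainty analytically, computing the expected row
#' under v ~ N(mu, diag(var)) with neighbourhood moments and a second-order
#' Taylor correction; \code{sampling} averages softmax rows over Monte-Carlo
#' draws.  \code{backward = TRUE} negates every velocity vector, giving the
#' time-reversed chain whose terminal states are the forward chain's initial
#' states.
#'
#' Rows whose correlations are undefined (zero-variance velocity vector)
#' fall back to a uniform distribution over the neighbours, with a warning.
#'
#' @param vd a [VelocityData-class] object.
#' @param graph a [NeighborGraph-class].
#' @param sigma positive scalar or "auto" (1 / median absolute correlation;
#'   estimated once, at the neighbourhood mean velocity for the uncertainty
#'   modes, and shared across modes).
#' @param mode "deterministic", "stochastic" or "sampling".
#' @param nSamples Monte-Carlo draws per cell in sampling mode.
#' @param backward build the reversed chain.
#' @param moments optional precomputed [VelocityMoments-class] (uncertainty
#'   modes only).
#' @param seed RNG seed for sampling mode.
#' @return a [TransitionMatrix-class].
#' @export
velocityKernel <- function(vd, graph, sigma = "auto",
                           mode = c("deterministic", "stochastic", "sampling"),
                           nSamples = 1000L, backward = FALSE, moments = NULL,
                           seed = NULL) {
  mode <- match.arg(mode)
  N <- nCells(vd)
  used <- !missingGenes(vd)
  if (sum(used) < 2L) stop("need at least 2 genes with velocity estimates")
  X <- exprMatrix(vd)[, used, drop = FALSE]
  V <- velocityMatrix(vd)[, used, drop = FALSE]
  if (backward) V <- -V
  if (mode != "deterministic") {
    if (is.null(moments)) {
      vb <- vd
      vb@velocity[, used] <- V        # moments of the (possibly negated) field
      moments <- estimateVelocityMoments(vb, graph)
    } else if (backward) {
      moments@mu <- -moments@mu
    }
    MU <- moments@mu[, used, drop = FALSE]
    VA <- moments@var[, used, drop = FALSE]
  }
  nbrs <- graph@neighbors
  # reference vector for correlations: raw velocity (deterministic) or the
  # neighbourhood mean (uncertainty modes)
  Ref <- if (mode == "deterministic") V else MU
  ctxS <- vector("list", N)
  cors <- vector("list", N)
  for (i in seq_len(N)) {
    S <- X[nbrs[[i]], , drop = FALSE] - rep(X[i, ], each = length(nbrs[[i]]))
    ctxS[[i]] <- S
    cors[[i]] <- .pearsonRows(S, Ref[i, ])
  }
  all.undefined <- !any(is.finite(unlist(cors, use.names = FALSE)))
  sigma.given <- !identical(sigma, "auto")
  sig <- if (sigma.given) {
    stopifnot(is.numeric(sigma), sigma > 0)
    as.numeric(sigma)
  } else if (all.undefined) 1 else estimateSigma(cors)

  if (mode == "sampling" && !is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old.seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old.seed, envir = globalenv()))
    }
    set.seed(seed)
  }

  n.fallback <- 0L
  rows <- vector("list", N)
  for (i in seq_len(N)) {
    k <- length(nbrs[[i]])
    ci <- cors[[i]]
    if (anyNA(ci)) {
      rows[[i]] <- rep(1 / k, k); n.fallback <- n.fallback + 1L; next
    }
    rows[[i]] <- switch(mode,
      deterministic = softmaxTransform(ci, sig),
      stochastic = {
        r <- .expectedRow(MU[i, ], VA[i, ], ctxS[[i]], sig)
        if (r$fallback && is.null(r$p)) {
          n.fallback <- n.fallback + 1L
          rep(1 / k, k)
        } else {
          if (r$fallback) n.fallback <- n.fallback + 1L
          r$p
        }
      },
      sampling = .sampledRow(MU[i, ], VA[i, ], ctxS[[i]], sig, nSamples))
  }
  if (n.fallback > 0L)
    warning(sprintf("%d row(s) fell back (undefined correlations or non-finite
 uncertainty correction)", n.fallback))
  ii <- rep(seq_len(N), times = lengths(nbrs))
  jj <- unlist(nbrs, use.names = FALSE)
  xx <- unlist(rows, use.names = FALSE)
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
  new("TransitionMatrix", probs = P, backward = backward,
      provenance = sprintf("velocity(mode=%s, sigma=%.4g%s)", mode, sig,
                           if (backward) ", backward" else ""),
      params = list(sigma = sig, sigmaEstimated = !sigma.given, mode = mode,
                    nSamples = if (mode == "sampling") as.integer(nSamples)
                    else NA_integer_))
}

#' Connectivity kernel: transcriptomic-similarity transition matrix
#'
#' Row-normalizes the (optionally density-normalized) similarity adjacency
#' into a transition matrix.  Isolated cells (zero similarity row) get a
#' self-loop with probability 1, with a warning.
#'
#' @param graph a [NeighborGraph-class] with adjacency filled.
#' @param densityNormalize apply [densityNormalize()] first (off by
#'   default).
#' @param backward direction tag so the kernel can be combined with a
#'   backward velocity kernel (similarities are undirected).
#' @return a [TransitionMatrix-class].
#' @export
connectivityKernel <- function(graph, densityNormalize = FALSE,
                               backward = FALSE) {
  A <- if (is(graph, "NeighborGraph")) graph@adjacency else graph
  if (length(A) <= 1L) stop("adjacency not computed; run computeSimilarities()")
  if (densityNormalize) A <- velofate::densityNormalize(A)
  deg <- Matrix::rowSums(A)
  zero <- which(deg == 0)
  if (length(zero)) {
    warning(sprintf("%d isolated cell(s): assigning self-loops", length(zero)))
    A <- A + Matrix::sparseMatrix(i = zero, j = zero, x = 1, dims = dim(A))
    deg <- Matrix::rowSums(A)
  }
  P <- Matrix::Diagonal(x = 1 / deg) %*% A
  new("TransitionMatrix", probs = methods::as(P, "CsparseMatrix"),
      backward = backward,
      provenance = sprintf("connectivity(%s%s)",
                           if (is(graph, "NeighborGraph"))
                             graph@similarityMethod else "custom",
                           if (densityNormalize) ", density-normalized" else ""),
      params = list(densityNormalize = densityNormalize))
}

#' Combine transition kernels by a convex combination
#'
#' P = sum_k w_k P_k with non-negative weights summing to 1; typically
#' P = (1 - lambda) P_velocity + lambda P_similarity with lambda around 0.2
#' to emphasize transcriptomic similarity and buffer noisy velocities.
#'
#' @param kernels list of [TransitionMatrix-class] objects of identical
#'   shape and direction.
#' @param weights non-negative weights, one per kernel, summing to 1.
#' @return the combined [TransitionMatrix-class].
#' @export
combineKernels <- function(kernels, weights) {
  stopifnot(length(kernels) >= 1L, length(weights) == length(kernels))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1")
  dims <- vapply(kernels, function(k) nrow(transitionProbs(k)), integer(1))
  if (length(unique(dims)) != 1L) stop("kernel shapes differ")
  back <- vapply(kernels, isBackward, logical(1))
  if (length(unique(back)) != 1L)
    stop("cannot combine forward and backward kernels")
  P <- Reduce(`+`, Map(function(k, w) w * transitionProbs(k), kernels,
                       as.list(weights)))
  new("TransitionMatrix", probs = methods::as(P, "CsparseMatrix"),
      backward = back[1L],
      provenance = paste(sprintf("%.3g*[%s]", weights,
                                 vapply(kernels, function(k) k@provenance,
                                        character(1))), collapse = " + "),
      params = list(weights = weights))
}
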