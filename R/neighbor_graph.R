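#' Project expression onto leading principal components
#'
#' Mean-centred (optionally unit-variance scaled) linear projection onto the
#' first L principal components, computed by exact singular value
#' decomposition.  The per-component sign is fixed by making the
#' largest-magnitude loading positive, so the projection is fully
#' deterministic.
#'
#' @param expr a [VelocityData-class] object or a cells x genes matrix.
#' @param L number of components (default 30, capped only by the data).
#' @param scale. scale genes to unit variance before projection (default
#'   FALSE: centred, unscaled).
#' @return a [PCARepresentation-class] with cells x L coordinates and the
#'   per-component explained variances.
#' @export
projectPCA <- function(expr, L = 30L, scale. = FALSE) {
  X <- if (is(expr, "VelocityData")) exprMatrix(expr) else as.matrix(expr)
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  if (L > min(dim(X)))
    stop(sprintf("L = %d exceeds min(N, G) = %d", L, min(dim(X))))
  Xc <- scale(X, center = TRUE, scale = scale.)
  sv <- svd(Xc, nu = 0L, nv = L)
  # fix sign: largest-|loading| entry of each right singular vector positive
  for (j in seq_len(L)) {
    k <- which.max(abs(sv$v[, j]))
    if (sv$v[k, j] < 0) sv$v[, j] <- -sv$v[, j]
  }
  coords <- Xc %*% sv$v
  ev <- sv$d[seq_len(L)]^2 / (nrow(X) - 1L)
  new("PCARepresentation", coords = unname(coords),
      explainedVariance = ev,
      totalVariance = sum(Xc^2) / (nrow(X) - 1L))
}

#' Build the symmetrized KNN graph
#'
#' Euclidean K-nearest-neighbour search in PC space, symmetrized by union:
#' cells i and j are neighbours if either is among the other's K nearest, so
#' every cell ends up with at least K neighbours.  Distance ties (including
#' duplicated points) are broken deterministically by ascending cell index.
#'
#' @param pc a [PCARepresentation-class] or a cells x features coordinate
#'   matrix.
#' @param K number of nearest neighbours (default 30).
#' @return a [NeighborGraph-class] with distances filled; call
#'   [computeSimilarities()] to fill the adjacency.
#' @export
buildKNN <- function(pc, K = 30L) {
  coords <- if (is(pc, "PCARepresentation")) pc@coords else as.matrix(pc)
  N <- nrow(coords)
  K <- as.integer(K)
  if (K < 1L || K >= N) stop(sprintf("need 1 <= K < N; got K = %d, N = %d", K, N))
  D <- as.matrix(stats::dist(coords))
  knn.idx <- matrix(0L, N, K)
  knn.dist <- matrix(0, N, K)
  for (i in seq_len(N)) {
    ord <- order(D[i, ], seq_len(N))     # ties broken by ascending index
    ord <- ord[ord != i][seq_len(K)]
    knn.idx[i, ] <- ord
    knn.dist[i, ] <- D[i, ord]
  }
  ii <- rep(seq_len(N), each = K)
  jj <- as.vector(t(knn.idx))
  # union-symmetrize
  a <- pmin(ii, jj); b <- pmax(ii, jj)
  keep <- !duplicated(cbind(a, b))
  a <- a[keep]; b <- b[keep]
  dvals <- D[cbind(a, b)]
  dist.sp <- Matrix::sparseMatrix(i = c(a, b), j = c(b, a), x = rep(dvals, 2L),
                                  dims = c(N, N))
  nbrs <- split(c(b, a), c(a, b))
  nbrs <- lapply(seq_len(N), function(i) {
    v <- nbrs[[as.character(i)]]
    if (is.null(v)) integer() else sort(unique(v))
  })
  new("NeighborGraph", knnIndex = knn.idx, knnDist = knn.dist,
      neighbors = nbrs, distances = dist.sp,
      adjacency = Matrix::Matrix(0, 0, 0, sparse = TRUE), K = K,
      similarityMethod = "")
}

# smooth-k bandwidth: solve sum_j exp(-max(0, d_j - rho)/sigma) = target
.smoothKnnBandwidth <- function(d, rho, target, n.iter = 64L) {
  lo <- 0; hi <- Inf; sigma <- 1
  for (it in seq_len(n.iter)) {
    val <- sum(exp(-pmax(d - rho, 0) / sigma))
    if (abs(val - target) < 1e-9) break
    if (val > target) { hi <- sigma; sigma <- (lo + hi) / 2 }
    else { lo <- sigma; sigma <- if (is.finite(hi)) (lo + hi) / 2 else sigma * 2 }
  }
  max(sigma, 1e-12)
}

#' Fill the similarity adjacency of a KNN graph
#'
#' Two similarity kernels are available.  The fuzzy kernel rescales each
#' cell's neighbour distances to its local scale (nearest-neighbour distance
#' rho_i, smooth-k-normalized bandwidth sigma_i), applies an exponential
#' kernel, and symmetrizes memberships with the probabilistic t-conorm
#' a + b - ab.  The gaussian kernel uses an adaptive per-cell bandwidth
#' (median neighbour distance) and symmetrizes by the mean.  Either way the
#' adjacency is symmetric, lies in (0, 1], is positive exactly on graph
#' edges, and within a cell's own neighbourhood decreases with distance.
#'
#' @param graph a [NeighborGraph-class] with distances filled.
#' @param method "fuzzy" (default) or "gaussian".
#' @return the graph with its adjacency slot filled.
#' @export
computeSimilarities <- function(graph, method = c("fuzzy", "gaussian")) {
  method <- match.arg(method)
  N <- length(graph@neighbors)
  if (any(lengths(graph@neighbors) == 0L)) stop("empty neighbourhood")
  K <- graph@K
  if (method == "fuzzy") {
    target <- log2(K)
    rows <- integer(); cols <- integer(); vals <- numeric()
    for (i in seq_len(N)) {
      d <- graph@knnDist[i, ]
      pos <- d[d > 0]
      rho <- if (length(pos)) min(pos) else 0
      sigma <- .smoothKnnBandwidth(d, rho, target)
      w <- exp(-pmax(d - rho, 0) / sigma)
      rows <- c(rows, rep.int(i, K)); cols <- c(cols, graph@knnIndex[i, ])
      vals <- c(vals, w)
    }
    Wd <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(N, N))
    A <- Wd + Matrix::t(Wd) - Wd * Matrix::t(Wd)    # t-conorm a + b - ab
  } else {
    sig <- apply(graph@knnDist, 1L, stats::median)
    sig[sig <= 0] <- max(mean(sig[sig > 0]), 1e-12)
    ds <- Matrix::summary(graph@distances)
    w.i <- exp(-ds$x^2 / (2 * sig[ds$i]^2))
    w.j <- exp(-ds$x^2 / (2 * sig[ds$j]^2))
    A <- Matrix::sparseMatrix(i = ds$i, j = ds$j, x = (w.i + w.j) / 2,
                              dims = c(N, N))
  }
  # restrict support to graph edges (t-conorm keeps it there by construction)
  A <- Matrix::drop0(A)
  graph@adjacency <- A
  graph@similarityMethod <- method
  graph
}

#' Density-normalize a similarity adjacency
#'
#' Divides each similarity by the product of the two cells' degrees
#' (W' = Dg^-1 W Dg^-1 with Dg the diagonal of row sums), down-weighting
#' edges incident to high-density regions as in anisotropic diffusion-map
#' constructions.  Off by default in the pipeline.
#'
#' @param A symmetric non-negative sparse adjacency (or a
#'   [NeighborGraph-class], whose adjacency is replaced).
#' @return the normalized adjacency (same type as the input).
#' @export
densityNormalize <- function(A) {
  if (is(A, "NeighborGraph")) {
    A@adjacency <- densityNormalize(A@adjacency)
    return(A)
  }
  deg <- Matrix::rowSums(A)
  if (any(deg == 0)) stop("zero-degree node; cannot density-normalize")
  Dinv <- Matrix::Diagonal(x = 1 / deg)
  Dinv %*% A %*% Dinv
}
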