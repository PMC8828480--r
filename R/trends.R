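.weightedQuantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1L]], numeric(1))
}

#' Fate-weighted smoothed expression trend along pseudotime
#'
#' Weighted penalized regression of one gene's expression on pseudotime in
#' a cubic B-spline basis, with each cell weighted by its (clipped) fate
#' probability towards the lineage of interest, so uncommitted cells
#' contribute to several lineages and committed cells are naturally
#' excluded from alternative fates.  Interior knots sit at weighted
#' pseudotime quantiles; the ridge penalty on second divided differences
#' of the spline coefficients (whose null space is exactly the linear
#' functions) is selected by generalized cross-validation over a fixed
#' log-spaced grid.  The smooth trend is predicted at \code{nTest} equally
#' spaced points spanning the contributing cells' pseudotime range, with a
#' residual-s.d. uncertainty band from [trendBand()].
#'
#' Only cells with weight > 0 enter the fit.
#'
#' @param y per-cell expression of one gene.
#' @param tau per-cell pseudotime.
#' @param weights per-cell lineage weights (default all 1); see
#'   [clipWeights()].
#' @param nTest number of equally spaced test points (default 200).
#' @param nKnots number of interior knots (default 8; reduced when the
#'   data supports fewer).
#' @param lambdaGrid fixed log-spaced ridge-penalty grid.
#' @param bandN convention for the band's n: "testPoints" (default) or
#'   "cells".
#' @return a [TrendFit-class].
#' @export
fitTrend <- function(y, tau, weights = NULL, nTest = 200L, nKnots = 8L,
                     lambdaGrid = 10^seq(-8, 4, by = 0.5),
                     bandN = c("testPoints", "cells")) {
  bandN <- match.arg(bandN)
  if (is.null(weights)) weights <- rep(1, length(y))
  stopifnot(length(tau) == length(y), length(weights) == length(y))
  use <- which(weights > 0 & is.finite(y) & is.finite(tau))
  y <- y[use]; tau <- tau[use]; w <- weights[use]
  ux <- unique(tau)
  if (length(ux) < 2L) stop("degenerate design: all pseudotimes equal")
  t0 <- min(tau); t1 <- max(tau)
  nK <- min(as.integer(nKnots), max(length(ux) - 2L, 0L))
  ik <- if (nK > 0L)
    .weightedQuantile(tau, w, seq_len(nK) / (nK + 1L)) else numeric()
  ik <- ik[ik > t0 & ik < t1]
  ik <- unique(ik)
  knots <- c(rep(t0, 4L), ik, rep(t1, 4L))
  B <- splines::splineDesign(knots, tau, ord = 4L)
  nb <- ncol(B)
  # Greville abscissae; second divided differences of coefficients over
  # them vanish exactly on linear functions
  grev <- vapply(seq_len(nb), function(i) mean(knots[i + 1:3]), numeric(1))
  if (nb >= 3L) {
    D <- matrix(0, nb - 2L, nb)
    for (i in seq_len(nb - 2L)) {
      h1 <- grev[i + 1L] - grev[i]; h2 <- grev[i + 2L] - grev[i + 1L]
      D[i, i:(i + 2L)] <- c(1 / h1, -(1 / h1 + 1 / h2), 1 / h2)
    }
    Pen <- crossprod(D)
  } else Pen <- matrix(0, nb, nb)
  BtWB <- crossprod(B, w * B)
  BtWy <- crossprod(B, w * y)
  n <- length(y)
  gcv <- rep(Inf, length(lambdaGrid))
  coefs <- vector("list", length(lambdaGrid))
  for (li in seq_along(lambdaGrid)) {
    lam <- lambdaGrid[li]
    M <- BtWB + lam * Pen
    sol <- tryCatch(solve(M, cbind(BtWy, BtWB)), error = function(e) NULL)
    if (is.null(sol)) next
    beta <- sol[, 1L]
    edf <- sum(diag(sol[, -1L, drop = FALSE]))
    r <- y - as.vector(B %*% beta)
    denom <- (1 - min(edf / n, 1 - 1e-8))^2
    gcv[li] <- (sum(w * r^2) / n) / denom
    coefs[[li]] <- beta
  }
  if (!any(is.finite(gcv))) stop("penalized fit failed for every lambda")
  best <- which.min(gcv)
  beta <- coefs[[best]]
  fitted.cells <- as.vector(B %*% beta)
  res <- y - fitted.cells
  grid <- seq(t0, t1, length.out = as.integer(nTest))
  Bg <- splines::splineDesign(knots, grid, ord = 4L)
  fitted.grid <- as.vector(Bg %*% beta)
  band <- trendBand(res, tau, grid,
                    nConvention = if (bandN == "cells") "cells" else
                      "testPoints")
  new("TrendFit", testGrid = grid, fitted = fitted.grid, band = band,
      coefficients = as.numeric(beta), knots = knots,
      lambda = lambdaGrid[best], weights = w, residuals = res, tau = tau)
}

#' Residual-s.d. uncertainty band along a fitted trend
#'
#' sigma_hat(tau_p) = sqrt(sum_j (y_j - yhat_j)^2 / (n - 2)) *
#' sqrt(1 + 1/n + (tau_p - taubar)^2 / sum_j (tau_j - taubar)^2), with
#' taubar the mean pseudotime of the fitted cells.  By convention n is the
#' number of test points (the default here); the statistically
#' conventional choice n = number of fitted cells is available via
#' \code{nConvention = "cells"}.  The band is smallest at taubar and grows
#' symmetrically away from it.
#'
#' @param residuals fit residuals at the fitted cells.
#' @param tau pseudotimes of the fitted cells.
#' @param testGrid prediction points.
#' @param nConvention "testPoints" or "cells".
#' @return non-negative band values on the grid.
#' @export
trendBand <- function(residuals, tau, testGrid,
                      nConvention = c("testPoints", "cells")) {
  nConvention <- match.arg(nConvention)
  n <- if (nConvention == "testPoints") length(testGrid) else length(tau)
  if (n < 3L) stop("need at least 3 points for the residual band")
  s <- sqrt(sum(residuals^2) / (n - 2))
  tb <- mean(tau)
  ss <- sum((tau - tb)^2)
  s * sqrt(1 + 1 / n + (testGrid - tb)^2 / ss)
}

#' Cluster smoothed gene-expression trends
#'
#' Recovers the main regulation patterns towards a lineage: per-gene
#' z-transform of the smoothed trends, PCA, KNN graph in PC space, and
#' Louvain community detection (seeded).  Returns labels plus pointwise
#' per-cluster mean and s.d. curves over the test grid.
#'
#' @param trends genes x gridPoints matrix of smoothed trends (e.g. the
#'   \code{fitted} slots of [fitTrend()] results).
#' @param nPCs number of principal components (capped by the data).
#' @param K neighbours for the gene-gene KNN graph.
#' @param resolution Louvain resolution (smaller = fewer clusters).
#' @param seed RNG seed for the community detection.
#' @return list with \code{labels} (integer cluster per gene),
#'   \code{mean} and \code{sd} (clusters x gridPoints matrices of the
#'   z-scaled trends) and \code{z} (the z-transformed trends).
#' @export
clusterTrends <- function(trends, nPCs = 50L, K = 30L, resolution = 0.2,
                          seed = 0L) {
  trends <- as.matrix(trends)
  ng <- nrow(trends)
  if (ng < 2L) stop("need at least 2 genes to cluster trends")
  mu <- rowMeans(trends)
  sg <- apply(trends, 1L, stats::sd)
  z <- (trends - mu) / ifelse(sg > 0, sg, 1)
  L <- min(as.integer(nPCs), ng - 1L, ncol(z))
  pcs <- stats::prcomp(z, rank. = L, center = TRUE, scale. = FALSE)$x
  K <- min(as.integer(K), ng - 1L)
  D <- as.matrix(stats::dist(pcs))
  ii <- integer(); jj <- integer()
  for (i in seq_len(ng)) {
    ord <- order(D[i, ], seq_len(ng))
    ord <- ord[ord != i][seq_len(K)]
    ii <- c(ii, rep.int(i, K)); jj <- c(jj, ord)
  }
  g <- igraph::graph_from_edgelist(cbind(ii, jj), directed = FALSE)
  g <- igraph::simplify(g)
  if (exists(".Random.seed", envir = globalenv())) {
    old.seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old.seed, envir = globalenv()))
  }
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(igraph::membership(cl))
  nc <- max(labels)
  mean.mat <- matrix(0, nc, ncol(z))
  sd.mat <- matrix(0, nc, ncol(z))
  for (k in seq_len(nc)) {
    zk <- z[labels == k, , drop = FALSE]
    mean.mat[k, ] <- colMeans(zk)
    sd.mat[k, ] <- apply(zk, 2L, stats::sd)
  }
  sd.mat[!is.finite(sd.mat)] <- 0
  list(labels = labels, mean = mean.mat, sd = sd.mat, z = z)
}
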