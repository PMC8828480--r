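#' @import methods
#' @importFrom Matrix Matrix sparseMatrix Diagonal rowSums colSums t crossprod
#'   readMM writeMM drop0
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Paired expression and velocity matrices
#'
#' Container for a cell-by-gene expression matrix and a velocity matrix of
#' identical shape and identical cell/gene ordering.  Cells are rows, genes
#' are columns.  Expression values are assumed to be normalized, log-scaled
#' (or imputed) and finite; velocities are expression units per unit time on
#' an arbitrary scale.  Genes for which no velocity estimate exists are
#' flagged in \code{missingGenes} and are excluded from all velocity
#' correlations.
#'
#' @slot expr numeric matrix, cells x genes.
#' @slot velocity numeric matrix, same shape as \code{expr}.
#' @slot cellIds character vector of unique cell identifiers.
#' @slot geneIds character vector of unique gene identifiers.
#' @slot missingGenes logical vector, one flag per gene; \code{TRUE} marks
#'   genes without velocity estimates.
#'
#' @seealso [VelocityData()] for the validating constructor.
#' @export
setClass("VelocityData",
  representation(
    expr = "matrix",
    velocity = "matrix",
    cellIds = "character",
    geneIds = "character",
    missingGenes = "logical"
  )
)

setValidity("VelocityData", function(object) {
  msgs <- character()
  N <- nrow(object@expr); G <- ncol(object@expr)
  if (N < 2L) msgs <- c(msgs, "need at least 2 cells")
  if (!identical(dim(object@expr), dim(object@velocity)))
    msgs <- c(msgs, sprintf("expression is %d x %d but velocity is %d x %d",
                            N, G, nrow(object@velocity), ncol(object@velocity)))
  if (length(object@cellIds) != N)
    msgs <- c(msgs, "cellIds length does not match number of rows")
  if (length(object@geneIds) != G)
    msgs <- c(msgs, "geneIds length does not match number of columns")
  if (anyDuplicated(object@cellIds))
    msgs <- c(msgs, sprintf("duplicate cell id: %s",
                            object@cellIds[anyDuplicated(object@cellIds)]))
  if (anyDuplicated(object@geneIds))
    msgs <- c(msgs, sprintf("duplicate gene id: %s",
                            object@geneIds[anyDuplicated(object@geneIds)]))
  if (length(object@missingGenes) != G)
    msgs <- c(msgs, "missingGenes length does not match number of genes")
  if (!all(is.finite(object@expr))) {
    bad <- which(!is.finite(object@expr), arr.ind = TRUE)[1L, ]
    msgs <- c(msgs, sprintf("non-finite expression value at cell %d, gene %d",
                            bad[1L], bad[2L]))
  }
  vel.ok <- object@velocity[, !object@missingGenes, drop = FALSE]
  if (!all(is.finite(vel.ok))) {
    bad <- which(!is.finite(vel.ok), arr.ind = TRUE)[1L, ]
    used <- which(!object@missingGenes)
    msgs <- c(msgs, sprintf(
      "non-finite velocity value at cell %s, gene %s",
      object@cellIds[bad[1L]], object@geneIds[used[bad[2L]]]))
  }
  if (length(msgs)) msgs else TRUE
})

#' Principal-component representation of the expression matrix
#'
#' @slot coords numeric matrix, cells x components.
#' @slot explainedVariance per-component variance, non-increasing.
#' @slot totalVariance total variance of the (centred) data.
#' @export
setClass("PCARepresentation",
  representation(
    coords = "matrix",
    explainedVariance = "numeric",
    totalVariance = "numeric"
  )
)

setValidity("PCARepresentation", function(object) {
  v <- object@explainedVariance
  if (length(v) != ncol(object@coords))
    return("explainedVariance length does not match number of components")
  if (any(v < -1e-12)) return("negative explained variance")
  if (is.unsorted(rev(pmax(v, 0)), strictly = FALSE) &&
      any(diff(v) > 1e-8 * max(v, 1)))
    return("explained variances must be non-increasing")
  TRUE
})

#' Symmetrized k-nearest-neighbour graph
#'
#' Holds the directed KNN lists (one row of \code{knnIndex}/\code{knnDist}
#' per cell), the union-symmetrized neighbour lists, the sparse symmetric
#' distance matrix and, once [computeSimilarities()] has run, the sparse
#' symmetric similarity adjacency in (0, 1].
#'
#' @slot knnIndex integer matrix, cells x K, each cell's K nearest neighbours.
#' @slot knnDist numeric matrix of the corresponding Euclidean distances.
#' @slot neighbors list of integer vectors: union-symmetrized neighbourhoods.
#' @slot distances sparse symmetric distance matrix on graph edges.
#' @slot adjacency sparse symmetric similarity matrix (empty until computed).
#' @slot K neighbour count parameter.
#' @slot similarityMethod "fuzzy", "gaussian" or "" when not yet computed.
#' @export
setClass("NeighborGraph",
  representation(
    knnIndex = "matrix",
    knnDist = "matrix",
    neighbors = "list",
    distances = "Matrix",
    adjacency = "Matrix",
    K = "integer",
    similarityMethod = "character"
  )
)

setValidity("NeighborGraph", function(object) {
  N <- length(object@neighbors)
  for (i in seq_len(N)) {
    if (i %in% object@neighbors[[i]])
      return(sprintf("self-loop in neighbour list of cell %d", i))
  }
  d <- object@distances
  if (nrow(d) != N || ncol(d) != N) return("distance matrix shape mismatch")
  if (max(abs(d - Matrix::t(d))) > 1e-12) return("distances not symmetric")
  if (length(object@adjacency) > 1L) {
    a <- object@adjacency
    if (max(abs(a - Matrix::t(a))) > 1e-12) return("adjacency not symmetric")
    if (any(a@x < 0)) return("negative similarity")
  }
  TRUE
})

#' Row-stochastic cell-cell transition matrix
#'
#' @slot probs sparse N x N row-stochastic matrix; support restricted to
#'   graph edges (plus self-loops where created).
#' @slot backward TRUE when the chain was built from the negated velocity
#'   field (time-reversed dynamics).
#' @slot provenance human-readable kernel recipe.
#' @slot params list of kernel parameters actually used (sigma, lambda, mode,
#'   ...).
#' @export
setClass("TransitionMatrix",
  representation(
    probs = "Matrix",
    backward = "logical",
    provenance = "character",
    params = "list"
  )
)

setValidity("TransitionMatrix", function(object) {
  P <- object@probs
  if (nrow(P) != ncol(P)) return("transition matrix must be square")
  if (any(P@x < 0)) return("negative transition probability")
  rs <- Matrix::rowSums(P)
  if (max(abs(rs - 1)) > 1e-10)
    return(sprintf("row %d sums to %.12f, not 1",
                   which.max(abs(rs - 1)), rs[which.max(abs(rs - 1))]))
  TRUE
})

#' First- and second-order moments of the local velocity distribution
#'
#' Per cell, the mean and per-gene variance of the velocity vectors over the
#' cell itself and its graph neighbours (diagonal covariance model).
#'
#' @slot mu cells x genes matrix of neighbourhood mean velocities.
#' @slot var cells x genes matrix of neighbourhood per-gene variances (>= 0).
#' @export
setClass("VelocityMoments",
  representation(mu = "matrix", var = "matrix")
)

setValidity("VelocityMoments", function(object) {
  if (!identical(dim(object@mu), dim(object@var)))
    return("mu and var shapes differ")
  if (!all(is.finite(object@mu)) || !all(is.finite(object@var)))
    return("non-finite moment")
  if (any(object@var < 0)) return("negative variance")
  TRUE
})

#' Sorted partial real Schur decomposition of a transition matrix
#'
#' Leading m-dimensional invariant-subspace factorization P Q = Q R with
#' orthonormal Schur vectors Q and quasi-upper-triangular R, sorted by
#' descending real part (metastability) or descending modulus (cyclicity).
#' 2 x 2 diagonal blocks of R carry complex-conjugate eigenvalue pairs and
#' are never split.
#'
#' @slot Q N x m matrix of orthonormal Schur vectors; the first column is
#'   constant (the Perron vector of a row-stochastic matrix).
#' @slot R m x m quasi-upper-triangular Schur form.
#' @slot eigenvalues complex vector of the m leading eigenvalues, sorted.
#' @slot conjugatePair logical vector; TRUE at both positions of a 2 x 2
#'   block.
#' @slot sort sorting criterion used.
#' @export
setClass("SchurDecomposition",
  representation(
    Q = "matrix",
    R = "matrix",
    eigenvalues = "complex",
    conjugatePair = "logical",
    sort = "character"
  )
)

setValidity("SchurDecomposition", function(object) {
  m <- ncol(object@Q)
  if (!identical(dim(object@R), c(m, m))) return("R shape mismatch")
  if (length(object@eigenvalues) != m) return("eigenvalue count mismatch")
  orth <- crossprod(object@Q) - diag(m)
  if (max(abs(orth)) > 1e-8) return("Schur vectors not orthonormal")
  TRUE
})

#' GPCCA coarse-graining result
#'
#' Soft membership of cells to macrostates together with the coarse-grained
#' transition matrix and model-selection diagnostics.
#'
#' @slot chi N x nStates membership matrix; rows on the probability simplex.
#' @slot rotation the optimized invertible rotation matrix A with chi = Q A.
#' @slot Pc nStates x nStates coarse-grained transition matrix.
#' @slot crispness trace-based overlap measure xi in (0, 1]; 1 for hard
#'   assignments.
#' @slot minChi most negative entry of the unoptimized membership matrix
#'   (diagnostic for the choice of nStates).
#' @slot objective final value of the rotation objective f(A) = nStates -
#'   trace(S).
#' @slot weights the diagonal weight vector D used (sums to 1).
#' @slot nStates number of macrostates.
#' @slot schur the Schur decomposition the memberships were built from.
#' @slot macrostateNames optional labels.
#' @export
setClass("GPCCAResult",
  representation(
    chi = "matrix",
    rotation = "matrix",
    Pc = "matrix",
    crispness = "numeric",
    minChi = "numeric",
    objective = "numeric",
    weights = "numeric",
    nStates = "integer",
    schur = "SchurDecomposition",
    macrostateNames = "character"
  )
)

setValidity("GPCCAResult", function(object) {
  chi <- object@chi
  if (ncol(chi) != object@nStates) return("chi column count != nStates")
  if (min(chi) < -1e-10) return("chi entry below -1e-10")
  if (max(abs(rowSums(chi) - 1)) > 1e-8) return("chi rows must sum to 1")
  Pc <- object@Pc
  if (min(Pc) < -1e-4)
    return(sprintf("coarse-grained transition entry %.2e < -1e-4: macrostates
 overlap too much; change the number of macrostates", min(Pc)))
  if (max(abs(rowSums(pmax(Pc, 0)) - 1)) > 1e-6)
    return("coarse-grained transition rows must sum to 1")
  TRUE
})

#' Macrostate classification
#'
#' Partition of macrostates into initial, terminal, intermediate and outlier
#' sets, from the stability index (diagonal of the coarse-grained transition
#' matrix) and the coarse-grained stationary distribution (CGSD).
#'
#' @slot terminal,initial,intermediate,outlier integer index sets (disjoint).
#' @slot stabilityIndex diag(Pc).
#' @slot piCoarse CGSD (NA for outlier macrostates).
#' @slot siThreshold the threshold used for terminal classification.
#' @slot macrostateNames labels, recycled from the GPCCA result.
#' @export
setClass("StateClassification",
  representation(
    terminal = "integer",
    initial = "integer",
    intermediate = "integer",
    outlier = "integer",
    stabilityIndex = "numeric",
    piCoarse = "numeric",
    siThreshold = "numeric",
    macrostateNames = "character"
  )
)

setValidity("StateClassification", function(object) {
  all.idx <- c(object@terminal, object@initial, object@intermediate,
               object@outlier)
  if (anyDuplicated(all.idx)) return("classification sets overlap")
  if (!setequal(all.idx, seq_along(object@stabilityIndex)))
    return("classification sets must cover all macrostates")
  TRUE
})

#' Per-cell fate probabilities towards terminal macrostates
#'
#' @slot probs N x nLineages matrix of absorption probabilities; rows sum to
#'   1, and rows of cells inside a terminal index set are one-hot.
#' @slot lineageNames column labels.
#' @slot partition the terminal index partition used (list with targetSets
#'   and transient).
#' @export
setClass("FateMatrix",
  representation(
    probs = "matrix",
    lineageNames = "character",
    partition = "list"
  )
)

setValidity("FateMatrix", function(object) {
  Fm <- object@probs
  if (min(Fm) < -1e-12 || max(Fm) > 1 + 1e-8)
    return("fate probabilities must lie in [0, 1]")
  if (max(abs(rowSums(Fm) - 1)) > 1e-6) return("fate rows must sum to 1")
  TRUE
})

#' Fate-weighted smoothed expression trend along pseudotime
#'
#' @slot testGrid strictly increasing pseudotime grid (200 points by
#'   default).
#' @slot fitted predicted expression on the grid.
#' @slot band residual-s.d. uncertainty band on the grid (>= 0).
#' @slot coefficients spline coefficients of the penalized fit.
#' @slot knots full knot vector of the cubic B-spline basis.
#' @slot lambda the ridge penalty selected by generalized cross-validation.
#' @slot weights the (clipped) lineage weights of the contributing cells.
#' @slot residuals weighted-fit residuals at the contributing cells.
#' @slot tau pseudotime of the contributing cells.
#' @export
setClass("TrendFit",
  representation(
    testGrid = "numeric",
    fitted = "numeric",
    band = "numeric",
    coefficients = "numeric",
    knots = "numeric",
    lambda = "numeric",
    weights = "numeric",
    residuals = "numeric",
    tau = "numeric"
  )
)

setValidity("TrendFit", function(object) {
  if (any(diff(object@testGrid) <= 0)) return("test grid must increase")
  if (!all(is.finite(object@fitted))) return("non-finite fitted value")
  if (any(object@band < 0)) return("negative uncertainty band")
  TRUE
})

#' Circular embedding of fate probabilities
#'
#' Terminal states are evenly spaced on the unit circle (ordering chosen to
#' maximize adjacent-lineage cosine similarity) and each cell is placed at
#' the fate-probability-weighted average of the lineage vertices, hence
#' inside their convex hull.
#'
#' @slot angles lineage angles in radians, in lineage order.
#' @slot coords N x 2 cell coordinates.
#' @slot ordering permutation of lineages around the circle.
#' @slot lineageNames labels.
#' @export
setClass("CircularEmbedding",
  representation(
    angles = "numeric",
    coords = "matrix",
    ordering = "integer",
    lineageNames = "character"
  )
)
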