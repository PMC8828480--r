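.asProbMatrix <- function(P) {
  if (is(P, "TransitionMatrix")) P <- transitionProbs(P)
  P
}

# symmetric/triangular Matrix storage hides half the edges from igraph
.asGeneral <- function(M) {
  if (is(M, "Matrix")) methods::as(M, "generalMatrix") else M
}

# --- dense real Schur with block reordering ---------------------------------
# Diagonal block starts of a quasi-upper-triangular matrix (2x2 blocks have
# a nonzero subdiagonal entry).
.schurBlocks <- function(T) {
  n <- nrow(T)
  tol <- 1e-11 * max(1, max(abs(diag(T))))
  starts <- integer(); sizes <- integer()
  i <- 1L
  while (i <= n) {
    if (i < n && abs(T[i + 1L, i]) > tol) {
      starts <- c(starts, i); sizes <- c(sizes, 2L); i <- i + 2L
    } else {
      starts <- c(starts, i); sizes <- c(sizes, 1L); i <- i + 1L
    }
  }
  list(starts = starts, sizes = sizes)
}

.blockEigen <- function(T, start, size) {
  if (size == 1L) complex(real = T[start, start], imaginary = 0)
  else eigen(T[start + 0:1, start + 0:1], only.values = TRUE)$values[1L]
}

# Swap two adjacent diagonal blocks of the quasi-triangular T (direct
# Sylvester-based exchange); updates T and Q in place and returns them.
# Returns NULL when the exchange is too ill-conditioned (eigenvalues of the
# two blocks nearly coincide) -- the caller then keeps the current order.
.swapSchurBlocks <- function(T, Q, i, p, q) {
  r1 <- i:(i + p - 1L)
  r2 <- (i + p):(i + p + q - 1L)
  A11 <- T[r1, r1, drop = FALSE]
  A12 <- T[r1, r2, drop = FALSE]
  A22 <- T[r2, r2, drop = FALSE]
  # [A11 A12; 0 A22] [X; I] = [X; I] A22  <=>  A11 X - X A22 = -A12,
  # so the leading q columns of the QR of [X; I] span A22's invariant
  # subspace; the orthogonal exchange follows
  K <- kronecker(diag(q), A11) - kronecker(t(A22), diag(p))
  if (rcond(K) < 1e-12) return(NULL)
  X <- matrix(solve(K, -as.vector(A12)), p, q)
  Z <- qr.Q(qr(rbind(X, diag(q))), complete = TRUE)
  rr <- c(r1, r2)
  Tsub <- crossprod(Z, T[rr, rr, drop = FALSE] %*% Z)
  low <- Tsub[(q + 1L):(p + q), 1:q, drop = FALSE]
  if (max(abs(low)) > 1e-7 * max(1, max(abs(Tsub)))) return(NULL)
  T[rr, ] <- crossprod(Z, T[rr, , drop = FALSE])
  T[, rr] <- T[, rr, drop = FALSE] %*% Z
  Q[, rr] <- Q[, rr, drop = FALSE] %*% Z
  # clean the (numerically tiny) sub-block to keep T exactly
  # quasi-triangular
  T[rr[(q + 1L):(p + q)], rr[1:q]] <- 0
  list(T = T, Q = Q)
}

# Real Schur decomposition with the m leading diagonal blocks (by
# descending real part or modulus) exchanged to the front via orthogonal
# block swaps; only the selected blocks are moved, so the cost stays
# O(m * nBlocks) swaps.  Errors when the m-th position would split a 2x2
# block.
.orderedSchur <- function(P, m, sort) {
  s <- Matrix::Schur(as.matrix(P))
  T <- as.matrix(s$T); Q <- as.matrix(s$Q)
  bl <- .schurBlocks(T)
  nb <- length(bl$starts)
  lam <- vapply(seq_len(nb), function(k)
    .blockEigen(T, bl$starts[k], bl$sizes[k]), complex(1))
  keys <- if (sort == "metastability") Re(lam) else Mod(lam)
  sizes <- bl$sizes
  ord <- order(-keys)
  chosen <- integer(); cols <- 0L
  for (b in ord) {
    chosen <- c(chosen, b); cols <- cols + sizes[b]
    if (cols >= m) break
  }
  if (cols > m)
    stop(sprintf(paste0("m = %d would split a complex conjugate eigenvalue",
                        " pair; use m = %d or m = %d"), m, m - 1L, m + 1L))
  # positional order of block ids; move each chosen block to its slot by
  # adjacent orthogonal exchanges
  pos.ids <- seq_len(nb)
  for (k in seq_along(chosen)) {
    id <- chosen[k]
    j <- match(id, pos.ids)
    while (j > k) {
      above <- pos.ids[j - 1L]
      start <- if (j - 1L == 1L) 1L else
        sum(sizes[pos.ids[seq_len(j - 2L)]]) + 1L
      res <- .swapSchurBlocks(T, Q, start, sizes[above], sizes[id])
      if (is.null(res)) {
        # eigenvalues (nearly) coincide: the exchange is ill-posed and the
        # order is immaterial; adopt the blocking block instead
        if (sizes[above] == sizes[id] && !(above %in% chosen) &&
            abs(keys[above] - keys[id]) < 1e-6) {
          chosen[k] <- above
          id <- above
          j <- j - 1L
          next
        }
        stop("Schur block exchange failed: eigenvalue cluster too
 ill-conditioned to reorder")
      }
      T <- res$T; Q <- res$Q
      pos.ids[c(j - 1L, j)] <- pos.ids[c(j, j - 1L)]
      j <- j - 1L
    }
  }
  front <- pos.ids[seq_along(chosen)]
  list(T = T, Q = Q, m = m,
       eigenvalues = lam[front], sizes = sizes[front])
}

#' Sorted partial real Schur decomposition
#'
#' Leading m-dimensional real Schur factorization P Q = Q R of a
#' row-stochastic matrix, with eigenvalues sorted by descending real part
#' (metastability, the default: Schur vectors of eigenvalues near 1 span
#' the metastable subspace) or by descending modulus (cyclicity).  Complex
#' conjugate eigenvalue pairs are kept together as 2 x 2 blocks and never
#' split; if the m-th position falls inside a pair an error suggests
#' m - 1 or m + 1.
#'
#' The dense path eigendecomposes P and assembles the sorted orthonormal
#' basis by ordered Gram-Schmidt over the real/imaginary eigenvector parts,
#' so each leading subspace is invariant and R = Q' P Q is
#' quasi-upper-triangular in sorted order.  The iterative path obtains the
#' leading eigenpairs with ARPACK (Krylov subspaces, exploiting sparsity)
#' and assembles the basis the same way.
#'
#' @param P a [TransitionMatrix-class] or square (sparse) matrix.
#' @param m number of leading Schur vectors.
#' @param sort "metastability" or "cyclicity".
#' @param method "dense" (default; exact, for matrices up to a few thousand
#'   states) or "krylov" (ARPACK).
#' @return a [SchurDecomposition-class].
#' @export
sortedSchur <- function(P, m, sort = c("metastability", "cyclicity"),
                        method = c("dense", "krylov")) {
  sort <- match.arg(sort)
  method <- match.arg(method)
  Pm <- .asProbMatrix(P)
  N <- nrow(Pm)
  m <- as.integer(m)
  if (m < 1L || m > N) stop("need 1 <= m <= N")
  stochastic <- max(abs(Matrix::rowSums(Pm) - 1)) < 1e-8
  if (method == "dense") {
    os <- .orderedSchur(Pm, m, sort)
    Q <- os$Q[, seq_len(m), drop = FALSE]
    ev.out <- complex(m); pair <- logical(m)
    col <- 0L
    for (k in seq_along(os$sizes)) {
      lam <- os$eigenvalues[k]
      if (os$sizes[k] == 1L) {
        col <- col + 1L
        ev.out[col] <- complex(real = Re(lam), imaginary = 0)
      } else {
        lam <- complex(real = Re(lam), imaginary = abs(Im(lam)))
        ev.out[col + 1L] <- lam
        ev.out[col + 2L] <- Conj(lam)
        pair[col + (1:2)] <- TRUE
        col <- col + 2L
      }
    }
    if (stochastic && Mod(ev.out[1L] - 1) < 1e-6)
      Q[, 1L] <- 1 / sqrt(N)       # exact Perron vector of a stochastic P
    qd <- qr(Q)
    if (qd$rank < m) stop("Schur basis is rank deficient")
    Q <- qr.Q(qd)
    if (Q[1L, 1L] < 0) Q[, 1L] <- -Q[, 1L]
    R <- crossprod(Q, as.matrix(Pm %*% Q))
    res <- norm(as.matrix(Pm %*% Q) - Q %*% R, "F")
    if (res > 1e-6 * norm(as.matrix(Pm), "F"))
      warning(sprintf("Schur invariance residual %.3e exceeds tolerance",
                      res))
    return(new("SchurDecomposition", Q = Q, R = R, eigenvalues = ev.out,
               conjugatePair = pair, sort = sort))
  } else {
    nev <- min(N - 2L, m + 2L)
    ncv <- min(N, max(4L * nev, 20L))
    ar <- igraph::arpack(function(x, extra) as.vector(extra %*% x),
                         extra = Pm, sym = FALSE, complex = TRUE,
                         options = list(n = N, nev = nev, ncv = ncv,
                                        which = if (sort == "metastability")
                                          "LR" else "LM",
                                        maxiter = 3000L))
    vals <- as.complex(ar$values)
    vecs <- ar$vectors
    if (is.numeric(vecs)) vecs <- vecs + 0i
    if (length(vals) < m)
      stop("ARPACK returned fewer eigenpairs than requested")
  }
  key <- if (sort == "metastability") -Re(vals) else -Mod(vals)
  ord <- order(key)
  vals <- vals[ord]
  vecs <- vecs[, ord, drop = FALSE]

  basis <- matrix(0, N, m)
  ev.out <- complex(m)
  pair <- logical(m)
  col <- 0L; i <- 1L
  while (col < m) {
    if (i > length(vals)) stop("ran out of eigenpairs while assembling basis")
    lam <- vals[i]
    if (abs(Im(lam)) <= 1e-12 * max(1, Mod(lam))) {
      col <- col + 1L
      basis[, col] <- Re(vecs[, i])
      ev.out[col] <- complex(real = Re(lam), imaginary = 0)
      i <- i + 1L
    } else {
      if (m - col < 2L)
        stop(sprintf(paste0(
          "m = %d would split a complex conjugate eigenvalue pair; ",
          "use m = %d or m = %d"), m, m - 1L, m + 1L))
      # take the positive-imaginary member; skip its conjugate
      vv <- if (Im(lam) > 0) vecs[, i] else Conj(vecs[, i])
      basis[, col + 1L] <- Re(vv)
      basis[, col + 2L] <- Im(vv)
      lam.pos <- complex(real = Re(lam), imaginary = abs(Im(lam)))
      ev.out[col + 1L] <- lam.pos
      ev.out[col + 2L] <- Conj(lam.pos)
      pair[col + (1:2)] <- TRUE
      col <- col + 2L
      # skip conjugate partner (adjacent after the stable sort)
      i <- i + if (i < length(vals) &&
                   Mod(vals[i + 1L] - Conj(lam)) <
                     1e-8 * max(1, Mod(lam))) 2L else 1L
    }
  }
  # The Perron vector of a row-stochastic matrix is the constant vector,
  # exactly; pin it, since with near-degenerate leading eigenvalues the
  # computed eigenvector can be an ill-conditioned mixture.
  stochastic <- max(abs(Matrix::rowSums(Pm) - 1)) < 1e-8
  if (stochastic && Mod(ev.out[1L] - 1) < 1e-6)
    basis[, 1L] <- 1
  qd <- qr(basis)
  if (qd$rank < m) stop("eigenvector basis is rank deficient")
  Q <- qr.Q(qd)
  if (Q[1L, 1L] < 0) Q[, 1L] <- -Q[, 1L]
  R <- crossprod(Q, as.matrix(Pm %*% Q))
  res <- norm(as.matrix(Pm %*% Q) - Q %*% R, "F")
  if (res > 1e-6 * norm(as.matrix(Pm), "F"))
    warning(sprintf("Schur invariance residual %.3e exceeds tolerance", res))
  new("SchurDecomposition", Q = Q, R = R, eigenvalues = ev.out,
      conjugatePair = pair, sort = sort)
}

# positions at which a 2x2 conjugate block starts
.pairStarts <- function(pair) {
  starts <- integer()
  i <- 1L
  while (i <= length(pair)) {
    if (pair[i]) { starts <- c(starts, i); i <- i + 2L } else i <- i + 1L
  }
  starts
}

#' Select the leading invariant subspace
#'
#' Returns the first nS sorted Schur vectors.  Refuses to split a 2 x 2
#' conjugate block: the two columns of a complex pair span a real invariant
#' subspace only when kept together.
#'
#' @param schur a [SchurDecomposition-class].
#' @param nS subspace dimension.
#' @return N x nS matrix of Schur vectors, with the corresponding
#'   quasi-triangular block attached as attribute "R".
#' @export
selectInvariantSubspace <- function(schur, nS) {
  nS <- as.integer(nS)
  if (nS < 1L || nS > ncol(schur@Q))
    stop(sprintf("need 1 <= nS <= %d", ncol(schur@Q)))
  if (nS < ncol(schur@Q) && schur@conjugatePair[nS] &&
      (nS + 1L) <= length(schur@conjugatePair) &&
      nS %in% (.pairStarts(schur@conjugatePair)))
    stop(sprintf(paste0(
      "nS = %d would split a complex conjugate pair; use nS = %d or nS = %d"),
      nS, nS - 1L, nS + 1L))
  Qt <- schur@Q[, seq_len(nS), drop = FALSE]
  attr(Qt, "R") <- schur@R[seq_len(nS), seq_len(nS), drop = FALSE]
  Qt
}

# orthonormalize columns of Q under the weighted inner product <u,v>_D =
# sum w u v, keeping the leading constant direction first (first column
# becomes the all-ones vector).  Two Gram-Schmidt passes for stability.
.weightedSchurBasis <- function(Q, w) {
  N <- nrow(Q); m <- ncol(Q)
  out <- matrix(0, N, m)
  for (j in seq_len(m)) {
    b <- Q[, j]
    for (pass in 1:2) for (i in seq_len(j - 1L))
      b <- b - sum(w * b * out[, i]) * out[, i]
    nrm <- sqrt(sum(w * b^2))
    if (nrm < 1e-12) stop("weighted Schur basis is degenerate")
    out[, j] <- b / nrm
  }
  if (stats::sd(out[, 1L]) > 1e-8 * max(abs(out[, 1L])))
    stop("first Schur vector is not constant; is the matrix row-stochastic?")
  out[, 1L] <- 1     # exact partition-of-unity anchor
  out
}

#' Initialize the GPCCA rotation matrix by inner-simplex vertex search
#'
#' Greedy search for the nS rows of the (weighted) Schur basis that span
#' the largest simplex: the first vertex is the row farthest from the
#' origin, each subsequent vertex is the row farthest from the affine span
#' of the vertices chosen so far.  The initial rotation is the inverse of
#' the selected vertex submatrix, so that those rows map to the unit
#' simplex corners.
#'
#' @param Qt N x nS (weighted) Schur basis with constant first column.
#' @return nS x nS rotation matrix A0 with attribute "vertices" (the chosen
#'   cell indices).
#' @export
initializeRotation <- function(Qt) {
  ns <- ncol(Qt)
  N <- nrow(Qt)
  if (ns == 1L) { A <- matrix(1, 1, 1); attr(A, "vertices") <- 1L; return(A) }
  OS <- Qt
  idx <- integer(ns)
  idx[1L] <- which.max(rowSums(OS^2))
  OS <- OS - rep(Qt[idx[1L], ], each = N)
  for (j in 2:ns) {
    tv <- OS[idx[j - 1L], ]
    nrm <- sqrt(sum(tv^2))
    if (nrm > 0) {
      tv <- tv / nrm
      OS <- OS - outer(as.vector(OS %*% tv), tv)
    }
    idx[j] <- which.max(rowSums(OS^2))
  }
  if (anyDuplicated(idx)) stop("degenerate simplex: duplicate vertex rows")
  Vm <- Qt[idx, , drop = FALSE]
  if (rcond(Vm) < 1e-12) stop("vertex submatrix is numerically singular")
  A <- solve(Vm)
  attr(A, "vertices") <- idx
  A
}

# Rebuild the constrained first row and column of A from its free block,
# then rescale so memberships are feasible (chi >= 0, rows sum to 1).
# Returns NULL when the configuration is degenerate.
.fillRotation <- function(A, Qt) {
  ns <- ncol(A)
  if (ns > 1L) {
    A[2:ns, 1L] <- -rowSums(A[2:ns, 2:ns, drop = FALSE])
    A[1L, ] <- -apply(Qt[, -1L, drop = FALSE] %*% A[-1L, , drop = FALSE],
                      2L, min)
  }
  s <- sum(A[1L, ])
  if (!is.finite(s) || s <= 1e-12) return(NULL)
  A / s
}

# GPCCA objective f(A) = ns - trace(Dtilde^-1 chi' D chi).  With a
# D-orthonormal basis, chi' D chi = A'A and the row sums of chi' D chi are
# the first row of A, so the trace reduces to sum_j (A'A)_jj / A[1, j].
.rotationObjective <- function(A) {
  d <- colSums(A^2)
  a1 <- A[1L, ]
  if (any(a1 <= 1e-12)) return(ncol(A))      # degenerate corner
  ncol(A) - sum(d / a1)
}

#' minChi diagnostic for the number of macrostates
#'
#' Most negative entry of the unoptimized membership matrix chi0 = Qt A0.
#' Values near zero indicate that nS admits a crisp decomposition; strongly
#' negative values flag a poor choice.
#'
#' @param Qt weighted Schur basis (N x nS).
#' @param A0 initial rotation from [initializeRotation()].
#' @return minChi (<= 0 up to numerical noise).
#' @export
minChi <- function(Qt, A0) {
  min(Qt %*% A0)
}

#' Coarse-grain a transition matrix onto macrostates
#'
#' P_c = (chi' D chi)^-1 (chi' D P chi), the invariant-subspace projection
#' of P onto the membership vectors.  When chi spans an exact invariant
#' subspace the projection commutes with propagation.  Rows sum to 1; tiny
#' negative entries (macrostate overlap at numerical precision) are
#' clipped, entries below -1e-4 raise an error.
#'
#' @param P transition matrix (or [TransitionMatrix-class]).
#' @param chi feasible membership matrix.
#' @param weights diagonal weight vector D (default uniform).
#' @return nS x nS coarse-grained transition matrix.
#' @export
coarseGrainTransition <- function(P, chi, weights = NULL) {
  Pm <- .asProbMatrix(P)
  N <- nrow(chi)
  w <- if (is.null(weights)) rep(1 / N, N) else weights / sum(weights)
  M <- crossprod(chi, w * chi)
  if (rcond(M) < 1e-12)
    stop("chi' D chi is singular: collapsed/duplicated macrostates")
  Pc <- solve(M, crossprod(chi, w * as.matrix(Pm %*% chi)))
  if (min(Pc) < -1e-4)
    stop(sprintf(paste0("coarse-grained transition entry %.3e is negative ",
                        "beyond numerical precision; change the number of ",
                        "macrostates"), min(Pc)))
  Pc <- pmax(Pc, 0)
  Pc / rowSums(Pc)
}

#' Crispness of a membership matrix
#'
#' xi = trace(Dtilde^-1 chi' D chi) / nS in (0, 1]: 1 for hard (indicator)
#' assignments, 1/nS for the maximally mixed membership.  Larger is
#' crisper (less overlap between macrostates).
#'
#' @param chi feasible membership matrix.
#' @param weights diagonal weight vector (default uniform).
#' @return xi.
#' @export
crispness <- function(chi, weights = NULL) {
  N <- nrow(chi)
  w <- if (is.null(weights)) rep(1 / N, N) else weights / sum(weights)
  M <- crossprod(chi, w * chi)
  sum(diag(M) / rowSums(M)) / ncol(chi)
}

#' Coarse-grain a Markov chain by GPCCA
#'
#' Generalized Perron Cluster Cluster Analysis: projects the chain onto the
#' leading sorted real Schur basis, then finds the invertible rotation A
#' minimizing f(A) = nS - trace(S) (equivalently maximizing macrostate
#' metastability) over the (nS-1)^2 free entries of A by Nelder-Mead, with
#' the positivity and partition-of-unity constraints re-imposed after every
#' evaluation via the constrained first row/column reconstruction.  The
#' memberships chi = Qt A are clipped to feasibility and the coarse-grained
#' transition matrix, crispness and minChi diagnostics are returned.
#'
#' @param P a [TransitionMatrix-class] or row-stochastic (sparse) matrix.
#' @param nS number of macrostates.
#' @param weights optional cell weight vector defining the weighted scalar
#'   product D (default uniform: no presumption about the cell
#'   distribution).
#' @param schur optional precomputed [SchurDecomposition-class] with at
#'   least nS columns (e.g. one decomposition shared across a crispness
#'   scan).
#' @param sort,method passed to [sortedSchur()] when schur is NULL.
#' @param maxFevals Nelder-Mead function-evaluation budget.
#' @param macrostateNames optional labels.
#' @return a [GPCCAResult-class].
#' @export
gpcca <- function(P, nS, weights = NULL, schur = NULL,
                  sort = "metastability", method = "dense",
                  maxFevals = 10000L, macrostateNames = NULL) {
  Pm <- .asProbMatrix(P)
  N <- nrow(Pm)
  nS <- as.integer(nS)
  w <- if (is.null(weights)) rep(1 / N, N) else weights / sum(weights)
  if (is.null(schur)) schur <- sortedSchur(Pm, m = nS, sort = sort,
                                           method = method)
  Qsub <- selectInvariantSubspace(schur, nS)
  if (is.null(macrostateNames))
    macrostateNames <- sprintf("macrostate_%d", seq_len(nS))
  if (nS == 1L) {
    chi <- matrix(1, N, 1L)
    return(new("GPCCAResult", chi = chi, rotation = matrix(1, 1, 1),
               Pc = matrix(1, 1, 1), crispness = 1, minChi = 0,
               objective = 0, weights = w, nStates = 1L, schur = schur,
               macrostateNames = macrostateNames))
  }
  Qt <- .weightedSchurBasis(Qsub, w)
  A0 <- initializeRotation(Qt)
  mchi <- minChi(Qt, A0)
  A0f <- .fillRotation(A0, Qt)
  if (is.null(A0f)) stop("initial rotation is infeasible")
  obj0 <- .rotationObjective(A0f)
  # optimize f(A) + 1: the objective approaches 0 for crisp chains, where
  # Nelder-Mead's relative stopping rule would otherwise never trigger
  objFun <- function(par) {
    A <- A0f
    A[2:nS, 2:nS] <- par
    A <- .fillRotation(A, Qt)
    if (is.null(A)) return(nS + 1)   # worst possible value on this problem
    .rotationObjective(A) + 1
  }
  par0 <- as.vector(A0f[2:nS, 2:nS, drop = FALSE])
  if (length(par0) == 1L) {
    # one free entry: golden-section search on a generous bracket
    br <- 5 * max(1, abs(par0))
    o <- stats::optimize(objFun, interval = c(par0 - br, par0 + br),
                         tol = 1e-12)
    opt <- list(par = o$minimum, value = o$objective - 1, convergence = 0L)
  } else {
    opt <- stats::optim(par0, objFun, method = "Nelder-Mead",
                        control = list(maxit = as.integer(maxFevals),
                                       reltol = 1e-12))
    opt$value <- opt$value - 1
    if (opt$convergence != 0L)
      warning("rotation optimization did not converge within the evaluation
 budget; returning the best feasible point")
  }
  best <- if (opt$value <= obj0) opt$par else par0
  A <- A0f
  A[2:nS, 2:nS] <- best
  A <- .fillRotation(A, Qt)
  chi <- Qt %*% A
  chi <- pmax(chi, 0)
  chi <- chi / rowSums(chi)
  Pc <- coarseGrainTransition(Pm, chi, w)
  new("GPCCAResult", chi = chi, rotation = A, Pc = Pc,
      crispness = crispness(chi, w), minChi = mchi,
      objective = min(opt$value, obj0), weights = w, nStates = nS,
      schur = schur, macrostateNames = macrostateNames)
}

#' Suggest the number of macrostates
#'
#' Three strategies: \code{eigengap} picks the largest drop in the sorted
#' real parts of the eigenvalues (ties broken towards the smaller count);
#' \code{crispness_scan} runs the full GPCCA optimization for every
#' candidate and picks the crispest; \code{minchi_then_crispness}
#' prefilters candidates with |minChi| <= 0.05 (a cheap feasibility check
#' on the unoptimized memberships) before the crispness scan.  Candidates
#' that would split a complex conjugate pair are pruned automatically.
#'
#' @param P transition matrix (or [TransitionMatrix-class]).
#' @param range integer vector of candidate macrostate counts (>= 2).
#' @param strategy selection strategy.
#' @param weights optional cell weights.
#' @param schur optional precomputed decomposition with at least
#'   max(range) + 1 columns; computed once at max(range) + 1 and truncated
#'   per candidate otherwise.
#' @param method Schur method when computing.
#' @return the suggested number of macrostates, with the per-candidate
#'   diagnostics attached as attribute "diagnostics".
#' @export
suggestNStates <- function(P, range = 2:8,
                           strategy = c("eigengap", "crispness_scan",
                                        "minchi_then_crispness"),
                           weights = NULL, schur = NULL, method = "dense") {
  strategy <- match.arg(strategy)
  range <- sort(unique(as.integer(range)))
  if (length(range) == 0L) stop("empty candidate range")
  Pm <- .asProbMatrix(P)
  m.max <- min(nrow(Pm), max(range) + 1L)
  if (is.null(schur)) {
    schur <- tryCatch(sortedSchur(Pm, m = m.max, method = method),
                      error = function(e) sortedSchur(Pm, m = m.max + 1L,
                                                      method = method))
  }
  starts <- .pairStarts(schur@conjugatePair)
  valid <- range[!(range %in% starts) & range < ncol(schur@Q)]
  if (length(valid) == 0L) stop("no valid candidates (conjugate pairs)")
  re <- Re(schur@eigenvalues)
  if (strategy == "eigengap") {
    gaps <- re[valid] - re[valid + 1L]
    n.s <- valid[which.max(gaps)]     # which.max: first max = smallest nS
    diag.df <- data.frame(nS = valid, eigengap = gaps)
  } else {
    cand <- valid
    mchi <- vapply(cand, function(k) {
      Qt <- .weightedSchurBasis(selectInvariantSubspace(schur, k),
                                if (is.null(weights))
                                  rep(1 / nrow(Pm), nrow(Pm)) else
                                    weights / sum(weights))
      minChi(Qt, initializeRotation(Qt))
    }, numeric(1))
    if (strategy == "minchi_then_crispness") {
      keep <- abs(mchi) <= 0.05
      if (!any(keep)) {
        warning("no candidate passes the minChi prefilter; scanning all")
        keep <- rep(TRUE, length(cand))
      }
      cand <- cand[keep]
    }
    # candidates whose coarse-grained matrix leaves the feasible region
    # (strongly negative entries) are scored out rather than crashing the
    # scan
    xi <- vapply(cand, function(k)
      tryCatch(gpcca(Pm, k, weights = weights, schur = schur)@crispness,
               error = function(e) NA_real_), numeric(1))
    if (all(is.na(xi))) stop("no candidate admits a feasible coarse-graining")
    n.s <- cand[which.max(replace(xi, is.na(xi), -Inf))]
    diag.df <- data.frame(nS = cand, crispness = xi)
  }
  attr(n.s, "diagnostics") <- diag.df
  n.s
}

#' Name macrostates by their dominant cluster label
#'
#' Assigns each macrostate the majority cluster label among the cells most
#' confidently assigned to it (by membership), disambiguating duplicates
#' with a numeric suffix.
#'
#' @param result a [GPCCAResult-class].
#' @param clusters per-cell cluster labels.
#' @param f number of top member cells to vote with.
#' @return the result with macrostateNames replaced.
#' @export
nameMacrostates <- function(result, clusters, f = 30L) {
  clusters <- as.character(clusters)
  chi <- memberships(result)
  nm <- vapply(seq_len(ncol(chi)), function(j) {
    top <- order(chi[, j], decreasing = TRUE)[seq_len(min(f, nrow(chi)))]
    names(base::sort(table(clusters[top]), decreasing = TRUE))[1L]
  }, character(1))
  dup <- duplicated(nm) | duplicated(nm, fromLast = TRUE)
  nm[dup] <- paste0(nm[dup], "_", stats::ave(seq_along(nm), nm,
                                             FUN = seq_along)[dup])
  result@macrostateNames <- nm
  result
}
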