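#' Terminal index sets: cells anchoring each selected macrostate
#'
#' For each selected macrostate, the f cells with the largest membership in
#' its chi column.  A cell ranked into several sets is claimed by the set
#' where its membership is larger; the losing set backfills with its
#' next-best cell, so the sets stay disjoint.  Implemented as a single
#' greedy pass over all (cell, macrostate) memberships in decreasing order.
#'
#' @param chi membership matrix (or a [GPCCAResult-class]).
#' @param macrostates indices (or names, for a GPCCA result) of the
#'   macrostates to absorb into; typically the terminal states.
#' @param f cells per target set (default 30).
#' @return list with \code{targetSets} (list of integer index vectors, one
#'   per macrostate), \code{transient} (the remaining cell indices),
#'   \code{f} and \code{lineageNames}.
#' @export
terminalIndexSets <- function(chi, macrostates, f = 30L) {
  nm <- NULL
  if (is(chi, "GPCCAResult")) {
    nm <- chi@macrostateNames
    if (is.character(macrostates)) macrostates <- match(macrostates, nm)
    chi <- memberships(chi)
  }
  f <- as.integer(f)
  if (f < 1L) stop("f must be >= 1")
  macrostates <- as.integer(macrostates)
  if (anyNA(macrostates) || any(macrostates < 1L | macrostates > ncol(chi)))
    stop("unknown macrostate selection")
  N <- nrow(chi)
  nt <- length(macrostates)
  if (f * nt >= N)
    stop(sprintf("f * n_targets = %d leaves no transient cells (N = %d)",
                 f * nt, N))
  sub <- chi[, macrostates, drop = FALSE]
  if (any(colSums(sub) == 0)) stop("empty membership column")
  ord <- order(sub, decreasing = TRUE)        # over all entries
  cells <- ((ord - 1L) %% N) + 1L
  sets <- ((ord - 1L) %/% N) + 1L
  taken <- logical(N)
  fill <- integer(nt)
  out <- lapply(seq_len(nt), function(i) integer(f))
  for (k in seq_along(ord)) {
    s <- sets[k]; cl <- cells[k]
    if (fill[s] >= f || taken[cl]) next
    fill[s] <- fill[s] + 1L
    out[[s]][fill[s]] <- cl
    taken[cl] <- TRUE
    if (all(fill >= f)) break
  }
  if (!all(fill >= f)) stop("not enough distinct cells to fill target sets")
  out <- lapply(out, sort)
  names(out) <- if (!is.null(nm)) nm[macrostates] else
    sprintf("macrostate_%d", macrostates)
  list(targetSets = out,
       transient = setdiff(seq_len(N), unlist(out)),
       f = f, lineageNames = names(out))
}

#' Make the target sets absorbing and extract the absorption system
#'
#' Replaces the row of every cell in a target set by a self-loop
#' (approximating the sets as recurrent classes) and extracts the
#' transient-to-transient block Q and the transient-to-recurrent block S.
#' Row sums of [Q | S] equal 1.
#'
#' @param P transition matrix (or [TransitionMatrix-class]).
#' @param partition output of [terminalIndexSets()].
#' @return list with sparse \code{Q}, \code{S}, the index bookkeeping and
#'   the per-column target-set assignment of S.
#' @export
makeAbsorbing <- function(P, partition) {
  Pm <- .asProbMatrix(P)
  rec <- unlist(partition$targetSets, use.names = FALSE)
  trans <- partition$transient
  Q <- Pm[trans, trans, drop = FALSE]
  S <- Pm[trans, rec, drop = FALSE]
  list(Q = Q, S = S, transient = trans, recurrent = rec,
       recurrentSet = rep(seq_along(partition$targetSets),
                          lengths(partition$targetSets)))
}

# restarted GMRES with Jacobi preconditioning for A x = b, A = I - Q
.gmres <- function(A, b, tol = 1e-8, restart = 100L, maxOuter = 200L) {
  n <- length(b)
  d <- Matrix::diag(A)
  d[abs(d) < 1e-300] <- 1
  Minv <- 1 / d
  x <- numeric(n)
  bn <- sqrt(sum(b^2))
  if (bn == 0) return(x)
  for (outer in seq_len(maxOuter)) {
    r <- b - as.vector(A %*% x)
    beta <- sqrt(sum(r^2))
    if (beta <= tol * bn) return(x)
    m <- restart
    V <- matrix(0, n, m + 1L)
    H <- matrix(0, m + 1L, m)
    V[, 1L] <- r / beta
    g <- c(beta, numeric(m))
    cs <- numeric(m); sn <- numeric(m)
    for (j in seq_len(m)) {
      wv <- as.vector(A %*% (Minv * V[, j]))
      for (i in seq_len(j)) {
        H[i, j] <- sum(wv * V[, i])
        wv <- wv - H[i, j] * V[, i]
      }
      H[j + 1L, j] <- sqrt(sum(wv^2))
      if (H[j + 1L, j] > 1e-14) V[, j + 1L] <- wv / H[j + 1L, j]
      # apply accumulated Givens rotations
      for (i in seq_len(j - 1L)) {
        t <- cs[i] * H[i, j] + sn[i] * H[i + 1L, j]
        H[i + 1L, j] <- -sn[i] * H[i, j] + cs[i] * H[i + 1L, j]
        H[i, j] <- t
      }
      den <- sqrt(H[j, j]^2 + H[j + 1L, j]^2)
      cs[j] <- H[j, j] / den; sn[j] <- H[j + 1L, j] / den
      H[j, j] <- den; H[j + 1L, j] <- 0
      g[j + 1L] <- -sn[j] * g[j]; g[j] <- cs[j] * g[j]
      if (abs(g[j + 1L]) <= tol * bn || j == m) {
        y <- backsolve(H[seq_len(j), seq_len(j), drop = FALSE], g[seq_len(j)])
        x <- x + Minv * as.vector(V[, seq_len(j), drop = FALSE] %*% y)
        break
      }
    }
    if (abs(g[j + 1L]) <= tol * bn) return(x)
  }
  warning("GMRES did not reach the requested tolerance")
  x
}

#' Fate probabilities by absorption analysis
#'
#' Solves the linear systems (I - Q) a_t = s_t (one per target set, where
#' s_t sums the transient-to-recurrent columns of that set: absorption
#' probabilities towards individual target cells are aggregated by
#' linearity) and assembles the N x n_t fate matrix.  Cells inside a
#' target set get the one-hot row of their lineage.  The fundamental
#' matrix (I - Q)^-1 is never materialized; a sparse LU factorization is
#' the default solver, with restarted GMRES (Jacobi-preconditioned,
#' relative residual 1e-8) as the iterative alternative for large
#' transient sets.
#'
#' @param P transition matrix (or [TransitionMatrix-class]).
#' @param partition output of [terminalIndexSets()].
#' @param solver "direct" or "gmres".
#' @param tol GMRES relative residual tolerance.
#' @return a [FateMatrix-class].
#' @export
absorptionProbabilities <- function(P, partition, solver = c("direct", "gmres"),
                                    tol = 1e-8) {
  solver <- match.arg(solver)
  Pm <- .asProbMatrix(P)
  N <- nrow(Pm)
  sys <- makeAbsorbing(Pm, partition)
  nt <- length(partition$targetSets)
  nT <- length(sys$transient)
  # reachability check: every transient cell needs a path into some target
  reach <- logical(N)
  reach[sys$recurrent] <- TRUE
  supp <- Pm > 0
  repeat {
    newly <- as.vector(supp %*% reach) > 0 & !reach
    if (!any(newly)) break
    reach[newly] <- TRUE
  }
  if (!all(reach[sys$transient])) {
    bad <- sys$transient[!reach[sys$transient]]
    stop(sprintf("%d transient cell(s) cannot reach any target set (first: %s)",
                 length(bad), paste(utils::head(bad, 5L), collapse = ", ")))
  }
  B <- matrix(0, nT, nt)
  for (t in seq_len(nt))
    B[, t] <- Matrix::rowSums(sys$S[, sys$recurrentSet == t, drop = FALSE])
  A <- Matrix::Diagonal(nT) - sys$Q
  X <- if (solver == "direct") {
    as.matrix(Matrix::solve(A, B))
  } else {
    vapply(seq_len(nt), function(t) .gmres(A, B[, t], tol = tol),
           numeric(nT))
  }
  X <- pmax(X, 0)          # clip solver noise at the -1e-10 scale
  X <- X / rowSums(X)
  Fm <- matrix(0, N, nt)
  Fm[sys$transient, ] <- X
  for (t in seq_len(nt)) Fm[partition$targetSets[[t]], t] <- 1
  new("FateMatrix", probs = Fm, lineageNames = partition$lineageNames,
      partition = partition)
}

#' Monte-Carlo absorption oracle
#'
#' Empirical first-hit frequencies from seeded random walks: for every
#' transient start cell, nWalks walks are run until a target set is hit,
#' and the hit frequencies estimate the fate probabilities.  A test oracle
#' for small chains; walks exceeding maxSteps are counted as failures and
#' reported in the "failures" attribute.
#'
#' @param P transition matrix (or [TransitionMatrix-class]).
#' @param partition output of [terminalIndexSets()].
#' @param nWalks walks per start cell.
#' @param seed RNG seed.
#' @param maxSteps bail-out walk length.
#' @return a [FateMatrix-class] of empirical frequencies.
#' @export
mcAbsorptionOracle <- function(P, partition, nWalks = 1000L, seed = 1L,
                               maxSteps = 1e6) {
  Pm <- .asProbMatrix(P)
  N <- nrow(Pm)
  if (N > 500L) stop("Monte-Carlo oracle is intended for small chains (N <= 500)")
  nt <- length(partition$targetSets)
  target <- integer(N)
  for (t in seq_len(nt)) target[partition$targetSets[[t]]] <- t
  R <- methods::as(methods::as(Pm, "generalMatrix"), "RsparseMatrix")
  if (exists(".Random.seed", envir = globalenv())) {
    old.seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old.seed, envir = globalenv()))
  }
  set.seed(seed)
  res <- cpp_absorption_walks(R@p, R@j, R@x, target, nt,
                              as.integer(partition$transient) - 1L,
                              as.integer(nWalks), as.numeric(maxSteps))
  counts <- res$counts
  fails <- res$failures
  Fm <- matrix(0, N, nt)
  done <- pmax(nWalks - fails, 1L)
  Fm[partition$transient, ] <- counts / done
  for (t in seq_len(nt)) Fm[partition$targetSets[[t]], t] <- 1
  if (any(fails > 0))
    warning(sprintf("%d walk(s) exceeded maxSteps", sum(fails)))
  fm <- new("FateMatrix", probs = Fm, lineageNames = partition$lineageNames,
            partition = partition)
  attr(fm, "failures") <- fails
  fm
}
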