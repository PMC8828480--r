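#' Stationary distribution of an irreducible chain
#'
#' Left Perron eigenvector of P normalized to sum 1, computed by a direct
#' sparse solve of pi' P = pi' with the normalization replacing one
#' redundant equation.  Errors on reducible chains and points the caller
#' to [handleReducible()].
#'
#' @param P a [TransitionMatrix-class] or row-stochastic (sparse) matrix.
#' @param check verify irreducibility first (strong connectivity of the
#'   support graph).
#' @return non-negative vector pi with sum(pi) = 1 and ||pi'P - pi'||_1 at
#'   numerical precision.
#' @export
stationaryDistribution <- function(P, check = TRUE) {
  Pm <- .asGeneral(.asProbMatrix(P))
  N <- nrow(Pm)
  if (check) {
    g <- igraph::graph_from_adjacency_matrix(Pm > 0, mode = "directed")
    if (igraph::count_components(g, mode = "strong") > 1L)
      stop("chain is reducible; use handleReducible() to exclude outlying
 components first")
  }
  M <- Matrix::t(Pm) - Matrix::Diagonal(N)
  M[N, ] <- 1
  b <- c(rep(0, N - 1L), 1)
  pi <- as.vector(Matrix::solve(M, b))
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

#' Coarse-grained stationary distribution (CGSD)
#'
#' pi_c = chi' pi: long-run occupancy of the macrostates.  Small entries
#' flag macrostates the process is unlikely to revisit after leaving, i.e.
#' initial states.
#'
#' @param chi membership matrix.
#' @param pi fine-grained stationary distribution.
#' @return vector of macrostate occupancies summing to 1.
#' @export
coarseStationary <- function(chi, pi) {
  if (is(chi, "GPCCAResult")) chi <- memberships(chi)
  as.vector(crossprod(chi, pi))
}

#' Classify terminal macrostates by the stability index
#'
#' The stability index (SI) of a macrostate is its self-transition
#' probability, the corresponding diagonal entry of the coarse-grained
#' transition matrix.  Macrostates with SI >= the threshold (0.96 by
#' default) are terminal: cells there distribute essentially all transition
#' mass within their own population.
#'
#' @param Pc coarse-grained transition matrix (or a [GPCCAResult-class]).
#' @param siThreshold classification threshold.
#' @return integer vector of terminal macrostate indices, with the SI
#'   vector attached as attribute "SI"; warns when empty (threshold may be
#'   lowered, or states promoted manually).
#' @export
classifyTerminal <- function(Pc, siThreshold = 0.96) {
  if (is(Pc, "GPCCAResult")) Pc <- coarseTransition(Pc)
  si <- diag(Pc)
  term <- which(si >= siThreshold)
  if (length(term) == 0L)
    warning(sprintf("no macrostate reaches SI >= %.3g (max SI %.3g); consider
 lowering the threshold or assigning terminal states manually",
                    siThreshold, max(si)))
  attr(term, "SI") <- si
  term
}

#' Classify initial macrostates by the CGSD
#'
#' The nInitial non-excluded macrostates with the smallest coarse-grained
#' stationary mass.  Terminal macrostates and outliers are excluded from
#' the candidate set.  Ties are broken by ascending index with a warning.
#'
#' @param piCoarse CGSD vector.
#' @param nInitial number of initial states (default 1).
#' @param exclude indices to exclude (terminal states, outliers).
#' @return integer vector of initial macrostate indices.
#' @export
classifyInitial <- function(piCoarse, nInitial = 1L, exclude = integer()) {
  cand <- setdiff(seq_along(piCoarse), exclude)
  if (length(cand) < nInitial)
    stop(sprintf("nInitial = %d exceeds the %d available macrostates",
                 nInitial, length(cand)))
  vals <- piCoarse[cand]
  ord <- order(vals, cand)
  sel <- cand[ord[seq_len(nInitial)]]
  if (nInitial < length(cand)) {
    cut <- vals[ord[nInitial]]
    if (sum(vals == cut) > 1L && vals[ord[nInitial + 1L]] == cut)
      warning("CGSD tie at the initial-state cutoff; broken by ascending
 macrostate index")
  }
  sel
}

# Stationary distribution of a possibly reducible chain with a single
# recurrent class: zero on transient states, the recurrent-class stationary
# distribution on that class.  Errors when several recurrent classes exist
# (the long-run distribution is then not unique).
.stationarySingleSink <- function(Pm) {
  Pm <- .asGeneral(Pm)
  N <- nrow(Pm)
  g <- igraph::graph_from_adjacency_matrix(Pm > 0, mode = "directed")
  sc <- igraph::components(g, mode = "strong")
  recurrent <- integer()
  for (k in seq_len(sc$no)) {
    memb <- which(sc$membership == k)
    out <- Matrix::rowSums(Pm[memb, -memb, drop = FALSE])
    if (all(out < 1e-14)) recurrent <- c(recurrent, k)
  }
  if (length(recurrent) == 0L) stop("no recurrent class found")
  if (length(recurrent) > 1L)
    stop("several recurrent classes: the stationary distribution is not
 unique; exclude outlying components first")
  keep <- which(sc$membership == recurrent)
  pi <- rep(0, N)
  if (length(keep) == N) return(stationaryDistribution(Pm, check = FALSE))
  pi[keep] <- stationaryDistribution(Pm[keep, keep, drop = FALSE],
                                     check = FALSE)
  pi
}

#' Analyse a (possibly reducible) chain and flag outlier macrostates
#'
#' Connected-component analysis of the transition support graph.  A chain
#' built from a connected KNN graph is irreducible (backward transitions
#' have small but positive probability); disconnected graph components
#' produce macrostates with zero coarse in- and out-flow, which are flagged
#' as outliers and excluded from initial-state computation.  The stationary
#' distribution is then computed on the remaining main component and
#' re-embedded with zeros elsewhere.
#'
#' @param P transition matrix (or [TransitionMatrix-class]).
#' @param chi optional membership matrix, to map outlying cells to
#'   macrostates.
#' @return list with \code{nComponents}, \code{componentSizes},
#'   \code{membership} (per-cell component), \code{mainComponent},
#'   \code{excludedCells}, \code{outlierMacrostates} and \code{pi} (the
#'   stationary distribution supported on the main component).
#' @export
handleReducible <- function(P, chi = NULL) {
  Pm <- .asGeneral(.asProbMatrix(P))
  N <- nrow(Pm)
  g <- igraph::graph_from_adjacency_matrix(Pm > 0, mode = "directed")
  comp <- igraph::components(g, mode = "weak")
  main <- which.max(comp$csize)
  excluded <- which(comp$membership != main)
  keep <- which(comp$membership == main)
  sub <- Pm[keep, keep, drop = FALSE]
  pi <- rep(0, N)
  pi[keep] <- .stationarySingleSink(sub)
  outlier <- integer()
  if (!is.null(chi)) {
    if (is(chi, "GPCCAResult")) chi <- memberships(chi)
    if (length(excluded)) {
      mass.out <- colSums(chi[excluded, , drop = FALSE])
      mass.all <- colSums(chi)
      outlier <- which(mass.out / mass.all > 0.5)
    }
  }
  list(nComponents = comp$no,
       componentSizes = as.integer(comp$csize),
       membership = as.integer(comp$membership),
       mainComponent = main,
       excludedCells = excluded,
       outlierMacrostates = outlier,
       pi = pi)
}

#' Classify all macrostates from a GPCCA result
#'
#' Wraps stability-index terminal classification, reducibility handling,
#' the coarse-grained stationary distribution and initial-state selection
#' into one [StateClassification-class].  Terminal macrostates are removed
#' from the initial-state candidates (the roles are disjoint), and manual
#' promotion of weakly stable macrostates to terminal is supported via
#' \code{forceTerminal} (e.g. a rare population picked up as a macrostate
#' but just below the SI threshold).
#'
#' @param result a [GPCCAResult-class].
#' @param P the fine-grained transition matrix the result was computed
#'   from.
#' @param siThreshold stability-index threshold for terminal states.
#' @param nInitial number of initial states.
#' @param forceTerminal macrostate indices or names to promote to terminal.
#' @return a [StateClassification-class].
#' @export
classifyStates <- function(result, P, siThreshold = 0.96, nInitial = 1L,
                           forceTerminal = NULL) {
  Pc <- coarseTransition(result)
  nS <- result@nStates
  term <- suppressWarnings(classifyTerminal(Pc, siThreshold))
  si <- attr(term, "SI")
  if (!is.null(forceTerminal)) {
    if (is.character(forceTerminal))
      forceTerminal <- match(forceTerminal, result@macrostateNames)
    term <- sort(union(as.integer(term), as.integer(forceTerminal)))
  }
  if (length(term) == 0L)
    warning("no terminal macrostates at this threshold")
  red <- handleReducible(P, result)
  pic <- coarseStationary(result, red$pi)
  outlier <- red$outlierMacrostates
  pic[outlier] <- NA_real_
  init <- classifyInitial(replace(pic, is.na(pic), Inf), nInitial = nInitial,
                          exclude = union(term, outlier))
  inter <- setdiff(seq_len(nS), c(term, init, outlier))
  new("StateClassification",
      terminal = as.integer(term), initial = as.integer(init),
      intermediate = as.integer(inter), outlier = as.integer(outlier),
      stabilityIndex = as.numeric(si), piCoarse = as.numeric(pic),
      siThreshold = siThreshold,
      macrostateNames = result@macrostateNames)
}

#' Recover initial states by reversing the Markov chain
#'
#' Initial states that traverse their trajectory too quickly to be
#' metastable under the forward dynamics become terminal (metastable)
#' states of the time-reversed chain, obtained by flipping every velocity
#' vector.  This runs the kernel + GPCCA + classification pipeline with
#' \code{backward = TRUE} and reports the terminal macrostates of the
#' reversed chain as initial states of the forward dynamics.
#'
#' @param vd a [VelocityData-class] object.
#' @param graph a [NeighborGraph-class] with adjacency filled.
#' @param nS number of macrostates for the reversed chain.
#' @param lambda connectivity-kernel weight.
#' @param mode velocity-kernel mode.
#' @param siThreshold stability threshold on the reversed chain.
#' @param ... further arguments to [velocityKernel()].
#' @return list with the backward \code{gpcca} result, the backward
#'   \code{terminal} macrostate indices (= forward initial states) and the
#'   backward transition matrix.
#' @export
recoverInitialByReversal <- function(vd, graph, nS, lambda = 0.2,
                                     mode = "deterministic",
                                     siThreshold = 0.96, ...) {
  vk <- velocityKernel(vd, graph, mode = mode, backward = TRUE, ...)
  ck <- connectivityKernel(graph, backward = TRUE)
  P <- combineKernels(list(vk, ck), c(1 - lambda, lambda))
  res <- gpcca(P, nS)
  term <- classifyTerminal(coarseTransition(res), siThreshold)
  list(gpcca = res, terminal = term, transition = P)
}
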