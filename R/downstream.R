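#' Circular embedding of fate probabilities
#'
#' Evenly spaces the lineages around the unit circle and places each cell
#' at the fate-probability-weighted average of the lineage vertices:
#' x_i = sum_t F_it cos(alpha_t), y_i = sum_t F_it sin(alpha_t).  Committed
#' cells sit at their lineage's vertex, uncommitted cells near the centre.
#' The arrangement of lineages matters, so the circular ordering is chosen
#' to maximize the summed cosine similarity between the fate columns of
#' adjacent lineages: exhaustively over circular permutations (first
#' lineage fixed, reflections deduplicated) for up to 8 lineages, by greedy
#' insertion beyond.
#'
#' @param F a [FateMatrix-class] or an N x n_t fate-probability matrix.
#' @return a [CircularEmbedding-class].
#' @export
circularProjection <- function(F) {
  nm <- NULL
  if (is(F, "FateMatrix")) { nm <- lineageNames(F); F <- fateProbs(F) }
  nt <- ncol(F)
  if (nt < 2L) stop("need at least 2 lineages for a circular embedding")
  if (is.null(nm)) nm <- colnames(F)
  if (is.null(nm)) nm <- sprintf("lineage_%d", seq_len(nt))
  cosSim <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
  }
  Smat <- matrix(0, nt, nt)
  for (i in seq_len(nt - 1L)) for (k in (i + 1L):nt)
    Smat[i, k] <- Smat[k, i] <- cosSim(F[, i], F[, k])
  score <- function(perm) {
    adj <- cbind(perm, c(perm[-1L], perm[1L]))
    sum(Smat[adj])
  }
  if (nt <= 8L) {
    perms <- .permutations(seq_len(nt - 1L) + 1L)
    best <- NULL; best.s <- -Inf
    for (r in seq_len(nrow(perms))) {
      perm <- c(1L, perms[r, ])
      if (nt > 2L && perm[2L] > perm[nt]) next   # reflection duplicate
      s <- score(perm)
      if (s > best.s) { best.s <- s; best <- perm }
    }
    ordering <- best
  } else {
    ordering <- c(1L, 2L)
    for (l in 3:nt) {
      cand <- lapply(seq_along(ordering), function(pos)
        append(ordering, l, after = pos))
      ordering <- cand[[which.max(vapply(cand, score, numeric(1)))]]
    }
  }
  angles.pos <- 2 * pi * (seq_len(nt) - 1L) / nt
  angles <- numeric(nt)
  angles[ordering] <- angles.pos
  coords <- cbind(x = as.vector(F %*% cos(angles)),
                  y = as.vector(F %*% sin(angles)))
  new("CircularEmbedding", angles = angles, coords = coords,
      ordering = as.integer(ordering), lineageNames = nm)
}

.permutations <- function(v) {
  n <- length(v)
  if (n <= 1L) return(matrix(v, nrow = 1L))
  out <- vector("list", n)
  for (i in seq_len(n))
    out[[i]] <- cbind(v[i], .permutations(v[-i]))
  do.call(rbind, out)
}

#' Lineage-priming entropy
#'
#' S_i = -sum_t F_it ln F_it (natural log; 0 ln 0 := 0).  High entropy
#' marks uncommitted, multipotent cells; zero entropy marks full
#' commitment.  Bounded by ln(n_t).
#'
#' @param F fate matrix (rows on the simplex) or [FateMatrix-class].
#' @return per-cell entropy vector.
#' @export
primingEntropy <- function(F) {
  if (is(F, "FateMatrix")) F <- fateProbs(F)
  Fl <- ifelse(F > 0, F * log(F), 0)
  -rowSums(Fl)
}

#' Lineage-priming KL divergence
#'
#' KL(F_i || Fbar) with Fbar the column-mean fate distribution; zero for
#' cells at the dataset-average fate bias, growing monotonically as cells
#' commit.  Infinite when a cell has mass on a lineage with zero average
#' mass (reported as Inf).
#'
#' @param F fate matrix or [FateMatrix-class].
#' @return per-cell divergence vector with the mean fate distribution
#'   attached as attribute "meanFate".
#' @export
primingKL <- function(F) {
  if (is(F, "FateMatrix")) F <- fateProbs(F)
  fbar <- colMeans(F)
  kl <- apply(F, 1L, function(fi) {
    pos <- fi > 0
    if (any(pos & fbar == 0)) return(Inf)
    sum(fi[pos] * log(fi[pos] / fbar[pos]))
  })
  kl <- pmax(kl, 0)       # Gibbs inequality; clip arithmetic noise
  attr(kl, "meanFate") <- fbar
  kl
}

#' Rank putative driver genes for a lineage
#'
#' Pearson correlation of each gene's expression with the lineage's fate
#' probabilities, optionally restricted to cells from predefined clusters
#' (where the fate decision is expected to occur).  Genes with zero
#' expression variance are flagged undefined and ranked last.
#'
#' @param expr cells x genes expression matrix or [VelocityData-class].
#' @param fateColumn per-cell fate probabilities for one lineage.
#' @param clusters optional per-cell cluster labels.
#' @param restrictTo cluster labels to restrict the correlation to.
#' @return data.frame with gene, correlation and rank, sorted by
#'   decreasing correlation (undefined last).
#' @export
rankDrivers <- function(expr, fateColumn, clusters = NULL, restrictTo = NULL) {
  genes <- NULL
  if (is(expr, "VelocityData")) { genes <- geneIds(expr); expr <- exprMatrix(expr) }
  if (is.null(genes))
    genes <- if (!is.null(colnames(expr))) colnames(expr) else
      sprintf("gene_%d", seq_len(ncol(expr)))
  keep <- seq_len(nrow(expr))
  if (!is.null(restrictTo)) {
    if (is.null(clusters)) stop("restrictTo given without cluster labels")
    keep <- which(as.character(clusters) %in% as.character(restrictTo))
    if (length(keep) == 0L) stop("cluster restriction matches no cells")
    if (length(keep) < 3L) stop("need >= 3 cells in the restriction")
  }
  X <- expr[keep, , drop = FALSE]
  fc <- fateColumn[keep]
  sds <- apply(X, 2L, stats::sd)
  r <- rep(NA_real_, ncol(X))
  ok <- sds > 0 & stats::sd(fc) > 0
  if (any(ok)) r[ok] <- suppressWarnings(as.vector(stats::cor(X[, ok,
    drop = FALSE], fc)))
  ord <- order(-r, na.last = TRUE)
  data.frame(gene = genes[ord], correlation = r[ord],
             rank = seq_along(ord), undefined = is.na(r[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Clip fate weights from below
#'
#' Lineage weights below the threshold are raised to it, so that early
#' cells with near-zero fate probability towards a rare lineage still
#' contribute (weakly) to its expression-trend fit.  Used only for trend
#' fitting.
#'
#' @param w fate-probability weights.
#' @param threshold clip value (default 0.01).
#' @return clipped weights, all >= threshold.
#' @export
clipWeights <- function(w, threshold = 0.01) {
  if (threshold < 0) stop("threshold must be >= 0")
  pmax(w, threshold)
}

#' Neighbour-average expression smoothing
#'
#' Repeatedly replaces each cell's expression by the mean over the cell
#' and its graph neighbours (a row-stochastic smoothing operator applied
#' \code{steps} times).  A simple built-in alternative to external
#' KNN-based imputation for stabilizing per-gene trends.
#'
#' @param expr cells x genes matrix or [VelocityData-class] (whose
#'   expression layer is smoothed in place).
#' @param graph a [NeighborGraph-class].
#' @param steps number of smoothing passes (0 = identity).
#' @return same type as the input.
#' @export
smoothExpression <- function(expr, graph, steps = 1L) {
  vd <- NULL
  if (is(expr, "VelocityData")) { vd <- expr; expr <- exprMatrix(vd) }
  steps <- as.integer(steps)
  if (steps > 0L) {
    N <- nrow(expr)
    nbrs <- graph@neighbors
    ii <- c(seq_len(N), rep(seq_len(N), times = lengths(nbrs)))
    jj <- c(seq_len(N), unlist(nbrs, use.names = FALSE))
    M <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(N, N))
    M <- Matrix::Diagonal(x = 1 / Matrix::rowSums(M)) %*% M
    for (s in seq_len(steps)) expr <- as.matrix(M %*% expr)
  }
  if (!is.null(vd)) { vd@expr <- expr; vd } else expr
}
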