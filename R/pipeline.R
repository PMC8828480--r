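#' Run the full fate-mapping pipeline in memory
#'
#' Orchestrates graph construction, kernel assembly, GPCCA coarse-graining,
#' macrostate classification, absorption-probability fate mapping and the
#' fate-derived summaries (priming scores; circular embedding when at
#' least two terminal states exist), driven by a [defaultRunConfig()]
#' configuration.
#'
#' @param vd a [VelocityData-class] object.
#' @param config a RunConfig list.
#' @param clusters optional per-cell cluster labels, used to name
#'   macrostates.
#' @param forceTerminal optional manual promotion of macrostates to
#'   terminal (indices or, with clusters, names).
#' @param verbose print stage messages.
#' @return list with \code{graph}, \code{pca}, \code{transition},
#'   \code{gpcca}, \code{classification}, \code{fate} (NULL when no
#'   terminal states), \code{priming}, \code{circular} and a
#'   machine-readable \code{report}.
#' @export
runFateMapping <- function(vd, config = defaultRunConfig(), clusters = NULL,
                           forceTerminal = NULL, verbose = FALSE) {
  config <- validateRunConfig(config)
  say <- function(...) if (verbose) message(sprintf(...))
  say("projecting onto %d PCs", min(config$L, min(dim(exprMatrix(vd)))))
  L <- min(config$L, min(dim(exprMatrix(vd))))
  pca <- projectPCA(vd, L = L, scale. = config$scalePCA)
  say("building KNN graph (K = %d)", config$K)
  graph <- buildKNN(pca, K = min(config$K, nCells(vd) - 1L))
  graph <- computeSimilarities(graph, method = config$similarity)
  if (config$densityNormalize) graph <- densityNormalize(graph)
  say("assembling %s velocity kernel", config$mode)
  vk <- velocityKernel(vd, graph, sigma = config$sigma, mode = config$mode,
                       nSamples = config$nSamples,
                       backward = config$backward, seed = config$seed)
  ck <- connectivityKernel(graph, backward = config$backward)
  P <- combineKernels(list(vk, ck), c(1 - config$lambda, config$lambda))
  nS <- config$nMacrostates
  schur <- NULL
  if (identical(nS, "auto")) {
    rng <- config$macrostateRange
    rng <- rng[rng < nCells(vd)]
    nS <- suggestNStates(P, range = rng, strategy = config$strategy)
    say("selected %d macrostates (%s)", nS, config$strategy)
  }
  nS <- as.integer(nS)
  say("coarse-graining into %d macrostates", nS)
  res <- tryCatch(gpcca(P, nS),
                  error = function(e) {
                    if (grepl("conjugate pair", conditionMessage(e)))
                      gpcca(P, nS + 1L) else stop(e)
                  })
  if (!is.null(clusters)) res <- nameMacrostates(res, clusters, f = config$f)
  cls <- classifyStates(res, P, siThreshold = config$siThreshold,
                        nInitial = config$nInitial,
                        forceTerminal = forceTerminal)
  fate <- NULL; priming <- NULL; circ <- NULL
  if (length(cls@terminal) >= 1L &&
      config$f * length(cls@terminal) < nCells(vd)) {
    say("computing fate probabilities towards %d terminal state(s)",
        length(cls@terminal))
    part <- terminalIndexSets(res, cls@terminal, f = config$f)
    fate <- absorptionProbabilities(P, part)
    priming <- list(entropy = primingEntropy(fate), kl = primingKL(fate))
    if (length(cls@terminal) >= 2L) circ <- circularProjection(fate)
  } else {
    warning("no usable terminal states; fate probabilities skipped")
  }
  report <- list(
    package = "velofate",
    version = as.character(utils::packageVersion("velofate")),
    config = config[setdiff(names(config), "macrostateRange")],
    nCells = nCells(vd), nGenes = nGenes(vd),
    diagnostics = list(
      sigma = vk@params$sigma,
      crispness = res@crispness,
      minChi = res@minChi,
      eigenvalues = list(re = Re(res@schur@eigenvalues),
                         im = Im(res@schur@eigenvalues)),
      stabilityIndex = cls@stabilityIndex,
      piCoarse = cls@piCoarse,
      terminal = cls@terminal, initial = cls@initial,
      intermediate = cls@intermediate, outlier = cls@outlier,
      components = handleReducible(P, res)$nComponents))
  list(pca = pca, graph = graph, velocityKernel = vk,
       connectivityKernel = ck, transition = P, gpcca = res,
       classification = cls, fate = fate, priming = priming,
       circular = circ, report = report)
}

.writeNamedTSV <- function(m, path, idCol, ids, colNames) {
  df <- data.frame(ids, as.matrix(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(idCol, colNames)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the pipeline on files and write every artifact
#'
#' File-based wrapper around [runFateMapping()]: reads the expression and
#' velocity matrices (and optional pseudotime / cluster files), runs the
#' pipeline and writes memberships, the coarse-grained transition matrix,
#' the state classification, fate probabilities, priming scores, the
#' circular embedding, the combined transition matrix (MTX + metadata)
#' and a JSON run report into \code{outDir}.
#'
#' @param exprPath,velocityPath input matrices (see [readMatrixFile()]).
#' @param outDir output directory (created).
#' @param config RunConfig list.
#' @param pseudotimePath,clustersPath optional per-cell TSVs.
#' @param verbose print stage messages.
#' @return the [runFateMapping()] result, invisibly.
#' @export
runPipeline <- function(exprPath, velocityPath, outDir,
                        config = defaultRunConfig(), pseudotimePath = NULL,
                        clustersPath = NULL, verbose = FALSE) {
  for (p in c(exprPath, velocityPath, pseudotimePath, clustersPath))
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p))
  ex <- readMatrixFile(exprPath)
  ve <- readMatrixFile(velocityPath)
  if (!identical(ex$geneIds, ve$geneIds) ||
      !identical(ex$cellIds, ve$cellIds))
    stop("expression and velocity id orders differ")
  vd <- VelocityData(ex$values, ve$values, cellIds = ex$cellIds,
                     geneIds = ex$geneIds)
  clusters <- if (!is.null(clustersPath)) readVectorFile(clustersPath)
  out <- runFateMapping(vd, config, clusters = clusters, verbose = verbose)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(outDir, x)
  res <- out$gpcca; cls <- out$classification
  .writeNamedTSV(memberships(res), fp("memberships.tsv"), "cell",
                 cellIds(vd), res@macrostateNames)
  .writeNamedTSV(coarseTransition(res), fp("coarse_transition.tsv"),
                 "macrostate", res@macrostateNames, res@macrostateNames)
  klass <- rep("intermediate", res@nStates)
  klass[cls@terminal] <- "terminal"; klass[cls@initial] <- "initial"
  klass[cls@outlier] <- "outlier"
  utils::write.table(
    data.frame(macrostate = res@macrostateNames,
               SI = cls@stabilityIndex, piCoarse = cls@piCoarse,
               class = klass, stringsAsFactors = FALSE),
    fp("states.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeTransitionMatrixFile(out$transition, fp("transition.mtx"))
  if (!is.null(out$fate)) {
    .writeNamedTSV(fateProbs(out$fate), fp("fate.tsv"), "cell",
                   cellIds(vd), lineageNames(out$fate))
    utils::write.table(
      data.frame(cell = cellIds(vd), entropy = out$priming$entropy,
                 kl = out$priming$kl, stringsAsFactors = FALSE),
      fp("priming.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(out$circular))
      utils::write.table(
        data.frame(cell = cellIds(vd), x = out$circular@coords[, 1L],
                   y = out$circular@coords[, 2L], stringsAsFactors = FALSE),
        fp("circular.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(out$report, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(out)
}
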