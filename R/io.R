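#' Read a cell-by-gene matrix with ids
#'
#' Supported formats: Matrix Market coordinate files (1-based indices on
#' disk, converted to this package's internal indexing) with sidecar id
#' files \code{<path>.rows} (cell ids) and \code{<path>.cols} (gene ids),
#' and delimited TSV/CSV with a header row of gene ids and a first column
#' of cell ids.
#'
#' @param path input file.
#' @param format "auto" (by extension), "mtx", "tsv" or "csv".
#' @return list with \code{values} (dense matrix), \code{cellIds} and
#'   \code{geneIds}.
#' @export
readMatrixFile <- function(path, format = c("auto", "mtx", "tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", "tsv")
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    rows.f <- paste0(path, ".rows"); cols.f <- paste0(path, ".cols")
    if (!file.exists(rows.f) || !file.exists(cols.f))
      stop(sprintf("missing sidecar id files %s / %s", rows.f, cols.f))
    cell.ids <- readLines(rows.f)
    gene.ids <- readLines(cols.f)
    if (length(cell.ids) != nrow(m) || length(gene.ids) != ncol(m))
      stop("sidecar id counts do not match the matrix dimensions")
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    cell.ids <- as.character(df[[1L]])
    gene.ids <- colnames(df)[-1L]     # before subsetting mangles duplicates
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("malformed matrix file: non-numeric values")
  }
  if (anyDuplicated(cell.ids))
    stop(sprintf("duplicate cell id: %s",
                 cell.ids[anyDuplicated(cell.ids)]))
  if (anyDuplicated(gene.ids))
    stop(sprintf("duplicate gene id: %s",
                 gene.ids[anyDuplicated(gene.ids)]))
  dimnames(m) <- NULL
  list(values = m, cellIds = cell.ids, geneIds = gene.ids)
}

#' Write a cell-by-gene matrix with ids
#'
#' Inverse of [readMatrixFile()]; round-trips values to full printed
#' precision.
#'
#' @param values matrix (cells x genes).
#' @param path output file.
#' @param cellIds,geneIds id vectors.
#' @param format "mtx", "tsv" or "csv".
#' @return the path, invisibly.
#' @export
writeMatrixFile <- function(values, path, cellIds = NULL, geneIds = NULL,
                            format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (is.null(cellIds)) cellIds <- sprintf("cell_%d", seq_len(nrow(values)))
  if (is.null(geneIds)) geneIds <- sprintf("gene_%d", seq_len(ncol(values)))
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(as.matrix(values), sparse = TRUE), path)
    writeLines(cellIds, paste0(path, ".rows"))
    writeLines(geneIds, paste0(path, ".cols"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(cell = cellIds, as.matrix(values),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("cell", geneIds)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a per-cell vector (pseudotime, cluster labels)
#'
#' One- or two-column delimited file; with two columns the first is the
#' cell id.
#'
#' @param path input TSV.
#' @return (possibly named) vector; numeric when all values parse as
#'   numbers.
#' @export
readVectorFile <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  v <- df[[ncol(df)]]
  if (ncol(df) >= 2L) names(v) <- as.character(df[[1L]])
  v
}

#' Write / read a transition matrix as Matrix Market plus metadata
#'
#' The matrix goes to a 1-based general-coordinate MTX file; the direction
#' flag, kernel recipe and parameters go to a JSON sidecar
#' \code{<path>.meta.json}.
#'
#' @param tm a [TransitionMatrix-class].
#' @param path output .mtx path.
#' @return the path, invisibly.
#' @export
writeTransitionMatrixFile <- function(tm, path) {
  Matrix::writeMM(transitionProbs(tm), path)
  meta <- list(backward = isBackward(tm), provenance = tm@provenance,
               params = tm@params)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeTransitionMatrixFile
#' @export
readTransitionMatrixFile <- function(path) {
  P <- methods::as(Matrix::readMM(path), "CsparseMatrix")
  meta.f <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta.f)) jsonlite::read_json(meta.f,
    simplifyVector = TRUE) else list(backward = FALSE,
                                     provenance = "precomputed",
                                     params = list())
  new("TransitionMatrix", probs = P,
      backward = isTRUE(meta$backward),
      provenance = as.character(meta$provenance),
      params = as.list(meta$params))
}

.configDefaults <- function() list(
  K = 30L,                  # nearest neighbours
  L = 30L,                  # principal components
  scalePCA = FALSE,
  similarity = "fuzzy",
  densityNormalize = FALSE,
  lambda = 0.2,             # connectivity-kernel weight
  mode = "stochastic",
  sigma = "auto",
  nSamples = 1000L,
  backward = FALSE,
  nMacrostates = "auto",    # eigengap heuristic
  macrostateRange = 2:8,
  strategy = "eigengap",
  siThreshold = 0.96,
  nInitial = 1L,
  f = 30L,                  # cells per terminal index set
  clip = 0.01,              # trend-weight clip threshold
  nTest = 200L,
  seed = 1L
)

#' Pipeline run configuration
#'
#' All pipeline defaults in one validated list: K = 30 neighbours, L = 30
#' PCs, lambda = 0.2 connectivity weight, analytic-uncertainty
#' ("stochastic") kernel mode with sigma estimated from the data,
#' eigengap-selected number of macrostates, stability-index threshold
#' 0.96, one initial state, 30 cells per terminal index set, trend-weight
#' clip 0.01 and a 200-point trend grid.
#'
#' @param ... overrides for individual fields (unknown names are
#'   rejected).
#' @return a validated RunConfig list.
#' @export
defaultRunConfig <- function(...) {
  cfg <- .configDefaults()
  over <- list(...)
  validateRunConfig(utils::modifyList(cfg, over[lengths(over) > 0]),
                    names(over))
}

#' @rdname defaultRunConfig
#' @param path YAML file with configuration overrides.
#' @export
readRunConfig <- function(path) {
  over <- yaml::read_yaml(path)
  if (is.null(over)) over <- list()
  validateRunConfig(utils::modifyList(.configDefaults(), over), names(over))
}

#' @rdname defaultRunConfig
#' @param config candidate configuration list.
#' @param newNames names being introduced (checked against the known
#'   fields).
#' @export
validateRunConfig <- function(config, newNames = names(config)) {
  known <- names(.configDefaults())
  unknown <- setdiff(newNames, known)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  config <- config[known]
  stopifnot(config$K >= 1, config$L >= 1,
            config$lambda >= 0, config$lambda <= 1,
            config$mode %in% c("deterministic", "stochastic", "sampling"),
            identical(config$sigma, "auto") ||
              (is.numeric(config$sigma) && config$sigma > 0),
            config$nSamples >= 1,
            config$similarity %in% c("fuzzy", "gaussian"),
            identical(config$nMacrostates, "auto") ||
              (is.numeric(config$nMacrostates) && config$nMacrostates >= 1),
            config$strategy %in% c("eigengap", "crispness_scan",
                                   "minchi_then_crispness"),
            config$siThreshold > 0, config$siThreshold <= 1,
            config$nInitial >= 1, config$f >= 1, config$clip >= 0,
            config$nTest >= 10)
  config
}
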