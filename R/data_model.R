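#' Construct a validated expression/velocity pair
#'
#' Validates that the expression and velocity matrices have identical shape
#' and cell/gene order, that expression values are finite, and that velocity
#' values are finite outside the missing-gene mask.  Genes whose velocity
#' column is entirely \code{NA} are flagged missing automatically and are
#' excluded from all velocity correlations downstream.
#'
#' @param expr numeric matrix, cells x genes (normalized log expression or
#'   imputed expression).
#' @param velocity numeric matrix of the same shape (expression units per
#'   unit time; scale arbitrary).
#' @param cellIds,geneIds optional id vectors; taken from dimnames when
#'   absent, generated otherwise.
#' @param missingGenes optional logical mask of genes without velocity
#'   estimates; merged with genes detected as all-\code{NA}.
#' @return a [VelocityData-class] object.
#' @examples
#' x <- matrix(rnorm(12), 3, 4)
#' v <- matrix(rnorm(12), 3, 4)
#' vd <- VelocityData(x, v)
#' nCells(vd)
#' @export
VelocityData <- function(expr, velocity, cellIds = NULL, geneIds = NULL,
                         missingGenes = NULL) {
  expr <- as.matrix(expr)
  velocity <- as.matrix(velocity)
  if (is.null(cellIds))
    cellIds <- if (!is.null(rownames(expr))) rownames(expr) else
      sprintf("cell_%d", seq_len(nrow(expr)))
  if (is.null(geneIds))
    geneIds <- if (!is.null(colnames(expr))) colnames(expr) else
      sprintf("gene_%d", seq_len(ncol(expr)))
  if (!identical(dim(expr), dim(velocity)))
    stop(sprintf("shape mismatch: expression %d x %d, velocity %d x %d",
                 nrow(expr), ncol(expr), nrow(velocity), ncol(velocity)))
  auto.missing <- apply(velocity, 2L, function(col) all(is.na(col)))
  if (is.null(missingGenes)) missingGenes <- auto.missing
  else missingGenes <- as.logical(missingGenes) | auto.missing
  velocity[, missingGenes] <- 0
  new("VelocityData", expr = expr, velocity = velocity,
      cellIds = as.character(cellIds), geneIds = as.character(geneIds),
      missingGenes = missingGenes)
}

#' Validate a paired expression/velocity input
#'
#' Re-runs the full pairing contract on an existing object (or a pair of
#' matrices) and reports genes flagged missing in the velocity layer.
#' Validation is idempotent: a valid object is returned unchanged.
#'
#' @param expr a [VelocityData-class] object, or an expression matrix.
#' @param velocity velocity matrix when \code{expr} is a matrix.
#' @param ... passed on to [VelocityData()].
#' @return the validated [VelocityData-class] object (invisibly reports
#'   missing-velocity genes via a message when present).
#' @export
validatePairedInputs <- function(expr, velocity = NULL, ...) {
  vd <- if (is(expr, "VelocityData")) expr else VelocityData(expr, velocity, ...)
  validObject(vd)
  n.miss <- sum(vd@missingGenes)
  if (n.miss > 0L)
    message(sprintf("%d gene(s) without velocity estimates: %s", n.miss,
                    paste(utils::head(vd@geneIds[vd@missingGenes], 5L),
                          collapse = ", ")))
  vd
}
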