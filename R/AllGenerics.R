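#' @rdname densityReport
#' @export
setGeneric("densityReport", function(x, ...) standardGeneric("densityReport"))

#' @rdname frobeniusNorm
#' @export
setGeneric("frobeniusNorm", function(x) standardGeneric("frobeniusNorm"))

#' @rdname matricize
#' @export
setGeneric("matricize", function(x, mode) standardGeneric("matricize"))

#' Number of stored (non-zero) entries
#'
#' @param x a [SparseTensor3-class] object.
#' @return integer count of stored entries.
#' @export
setGeneric("nnzCount", function(x) standardGeneric("nnzCount"))

#' @rdname nnzCount
setMethod("nnzCount", "SparseTensor3", function(x) nrow(x@subs))

#' Tensor axis labels
#'
#' @param x a [SparseTensor3-class] object.
#' @return list with elements terms, genes, tfs.
#' @export
setGeneric("axisLabels", function(x) standardGeneric("axisLabels"))

#' @rdname axisLabels
setMethod("axisLabels", "SparseTensor3", function(x) x@axisLabels)

#' @describeIn SparseTensor3 tensor extents (m, n, p).
#' @param x a SparseTensor3.
#' @export
setMethod("dim", "SparseTensor3", function(x) x@dims)

setMethod("show", "SparseTensor3", function(object) {
  d <- object@dims
  cat(sprintf("SparseTensor3 %d x %d x %d (term x gene x TF)\n",
              d[1], d[2], d[3]))
  dr <- densityReport(object)
  cat(sprintf("  nnz: %d / %.0f (density %.4g)\n",
              dr$nnz, dr$total, dr$density))
})

setMethod("show", "CitationCorpus", function(object) {
  genes <- setdiff(names(object@geneToPmids), object@tfIds)
  cat("CitationCorpus:", length(genes), "genes,",
      length(object@tfIds), "TFs,",
      length(object@abstracts), "abstracts\n")
  if (nzchar(object@provenance))
    cat("  source:", object@provenance, "\n")
})

setMethod("show", "FactorModel", function(object) {
  cat(sprintf(
    "FactorModel rank %d: A %dx%d, B %dx%d, C %dx%d\n",
    object@rank, nrow(object@A), ncol(object@A),
    nrow(object@B), ncol(object@B), nrow(object@C), ncol(object@C)))
  cat(sprintf("  %d sweeps, converged: %s, final fit %.4f\n",
              object@iterations, object@converged,
              if (length(object@fitHistory))
                object@fitHistory[length(object@fitHistory)] else NA_real_))
  cat("  lambda:", paste(signif(head(object@lambda, 5), 4), collapse = " "),
      if (object@rank > 5) "..." else "", "\n")
})

setMethod("show", "ATM", function(object) {
  cat(sprintf("ATM %d of k=%d run (lambda %.4g): %d terms, %d genes, %d TFs\n",
              object@componentIndex, object@kOfRun, object@lambda,
              nrow(object@terms), nrow(object@genes), nrow(object@tfs)))
  if (length(object@degenerate))
    cat("  degenerate modes:", paste(object@degenerate, collapse = ", "), "\n")
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "sets over a universe of",
      length(object@universe), "identifiers\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport:\n")
  cat("  enrichment rows:", nrow(object@enrichment), "\n")
  cat("  ATMs with AUC:", nrow(object@auc), "\n")
  cat("  ATMs with precision:", nrow(object@precision), "\n")
  if (length(object@precisionTest))
    cat(sprintf("  precision vs matched controls: p = %.3g\n",
                object@precisionTest$p))
})

#' Accessors for FactorModel slots
#'
#' @param x a [FactorModel-class].
#' @return `factorMatrices()` returns a list with elements A, B, C;
#'   `lambdas()` the component weight vector; `fitHistory()` the per-sweep
#'   fit trace.
#' @export
factorMatrices <- function(x) {
  stopifnot(is(x, "FactorModel"))
  list(A = x@A, B = x@B, C = x@C)
}

#' @rdname factorMatrices
#' @export
lambdas <- function(x) {
  stopifnot(is(x, "FactorModel"))
  x@lambda
}

#' @rdname factorMatrices
#' @export
fitHistory <- function(x) {
  stopifnot(is(x, "FactorModel"))
  x@fitHistory
}

#' Accessors for ATM slots
#'
#' @param x an [ATM-class] object.
#' @param mode one of "terms", "genes", "tfs".
#' @return `atmEntities()` returns the ranked data.frame for one mode;
#'   `atmMembers()` the pooled gene + TF identifiers (the module's
#'   membership set used by enrichment and precision).
#' @export
atmEntities <- function(x, mode = c("terms", "genes", "tfs")) {
  stopifnot(is(x, "ATM"))
  slot(x, match.arg(mode))
}

#' @rdname atmEntities
#' @export
atmMembers <- function(x) {
  stopifnot(is(x, "ATM"))
  unique(c(x@genes$entity, x@tfs$entity))
}
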