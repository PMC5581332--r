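#' @import methods
#' @importFrom stats phyper pt rbinom rnorm runif setNames t.test var
#' @importFrom utils head read.delim write.table combn
#' @importFrom tools md5sum
NULL

#' CitationCorpus: gene/TF citation map plus abstract texts
#'
#' Holds the filtered document collection from which the term x gene x TF
#' tensor is built: a map from entity identifier (gene or transcription
#' factor symbol, stored upper-cased) to the set of citation identifiers
#' (PMIDs) curated for it, the subset of identifiers designated as TFs,
#' and the text (title concatenated with abstract) of every citation.
#'
#' Identifiers in \code{tfIds} are treated as transcription factors; all
#' other keys of \code{geneToPmids} form the non-TF gene universe, so the
#' two entity classes are disjoint by construction. Every PMID referenced
#' by the citation map has an entry in \code{abstracts}; the constructor
#' drops dangling references and reports how many were removed.
#'
#' @slot geneToPmids named list; each element a character vector of PMIDs.
#' @slot tfIds character; identifiers designated as transcription factors.
#' @slot abstracts named character; PMID -> title + abstract text.
#' @slot provenance character(1); free-text source label.
#'
#' @seealso [citationCorpus()], [buildPairDocuments()], [filterCitations()]
#' @export
setClass("CitationCorpus",
  slots = c(
    geneToPmids = "list",
    tfIds = "character",
    abstracts = "character",
    provenance = "character"
  )
)

setValidity("CitationCorpus", function(object) {
  msg <- character()
  if (length(object@geneToPmids) &&
      (is.null(names(object@geneToPmids)) || anyNA(names(object@geneToPmids)) ||
       any(names(object@geneToPmids) == "")))
    msg <- c(msg, "geneToPmids must be a fully named list")
  if (anyDuplicated(names(object@geneToPmids)))
    msg <- c(msg, "duplicate entity identifiers in geneToPmids")
  refd <- unique(unlist(object@geneToPmids, use.names = FALSE))
  if (length(refd) && !all(refd %in% names(object@abstracts)))
    msg <- c(msg, "every referenced PMID must have an abstract entry")
  if (length(object@tfIds) && !all(object@tfIds %in% names(object@geneToPmids)))
    msg <- c(msg, "tfIds must be a subset of the geneToPmids keys")
  if (length(msg)) msg else TRUE
})

#' SparseTensor3: a sparse 3-mode tensor in coordinate form
#'
#' Coordinate (COO) representation of an m x n x p tensor of weighted term
#' frequencies: mode 1 indexes terms, mode 2 genes, mode 3 transcription
#' factors. Only strictly positive entries are stored; coordinates are
#' 1-based internally and unique (the constructor merges duplicates by
#' summation). The on-disk dump format uses 0-based indices.
#'
#' @slot dims integer(3); extents (m terms, n genes, p TFs).
#' @slot subs integer matrix with nnz rows and columns i, j, k (1-based).
#' @slot vals numeric; the stored entry values, all finite and > 0.
#' @slot axisLabels list of three character vectors labelling each mode
#'   (terms, genes, tfs); lengths match \code{dims}.
#'
#' @seealso [sparseTensor()], [buildTensor()], [matricize()],
#'   [densityReport()]
#' @export
setClass("SparseTensor3",
  slots = c(
    dims = "integer",
    subs = "matrix",
    vals = "numeric",
    axisLabels = "list"
  )
)

setValidity("SparseTensor3", function(object) {
  msg <- character()
  d <- object@dims
  if (length(d) != 3L || anyNA(d) || any(d < 1L))
    msg <- c(msg, "dims must be three positive integers")
  s <- object@subs
  if (!is.integer(s) || ncol(s) != 3L)
    msg <- c(msg, "subs must be an integer matrix with 3 columns")
  if (nrow(s) != length(object@vals))
    msg <- c(msg, "subs and vals lengths differ")
  if (length(object@vals)) {
    if (!all(is.finite(object@vals)) || any(object@vals <= 0))
      msg <- c(msg, "all values must be finite and > 0")
    if (length(d) == 3L && is.integer(s) && ncol(s) == 3L) {
      if (any(s < 1L) || any(s[, 1] > d[1]) || any(s[, 2] > d[2]) ||
          any(s[, 3] > d[3]))
        msg <- c(msg, "coordinates out of range")
      key <- (s[, 3] - 1) * as.double(d[1]) * d[2] +
        (s[, 2] - 1) * as.double(d[1]) + s[, 1]
      if (anyDuplicated(key))
        msg <- c(msg, "duplicate coordinates")
    }
  }
  if (length(object@axisLabels) == 3L && length(d) == 3L) {
    ok <- mapply(function(lab, n) is.null(lab) || length(lab) == n,
                 object@axisLabels, d)
    if (!all(ok)) msg <- c(msg, "axisLabels lengths must match dims")
  } else if (length(object@axisLabels) != 3L) {
    msg <- c(msg, "axisLabels must have three elements")
  }
  if (length(msg)) msg else TRUE
})

#' FactorModel: a rank-k non-negative CP (PARAFAC) decomposition
#'
#' The result of [ntf()]: non-negative factor matrices A (terms x k),
#' B (genes x k), C (TFs x k) with unit 2-norm columns, and a weight
#' vector lambda sorted non-increasingly, so the tensor is approximated
#' as sum_i lambda_i (a_i o b_i o c_i). \code{fitHistory} records the fit
#' (1 - relative Frobenius error) after each alternating sweep.
#'
#' @slot A,B,C non-negative numeric matrices with k columns each.
#' @slot lambda numeric(k); component weights, lambda_1 >= ... >= lambda_k.
#' @slot fitHistory numeric; fit after each sweep.
#' @slot rank integer(1); k.
#' @slot iterations integer(1); sweeps performed.
#' @slot converged logical(1); TRUE if the fit-change tolerance was met.
#' @slot seed integer(1); seed used for rank-deficient initializer padding.
#'
#' @seealso [ntf()], [extractATMs()]
#' @export
setClass("FactorModel",
  slots = c(
    A = "matrix", B = "matrix", C = "matrix",
    lambda = "numeric",
    fitHistory = "numeric",
    rank = "integer",
    iterations = "integer",
    converged = "logical",
    seed = "integer"
  )
)

setValidity("FactorModel", function(object) {
  msg <- character()
  k <- object@rank
  if (length(k) != 1L) return(TRUE)   # empty shell during construction
  for (nm in c("A", "B", "C")) {
    M <- slot(object, nm)
    if (ncol(M) != k) msg <- c(msg, sprintf("%s must have rank columns", nm))
    if (any(M < 0)) msg <- c(msg, sprintf("%s has negative entries", nm))
  }
  if (length(object@lambda) != k)
    msg <- c(msg, "lambda length must equal rank")
  if (any(object@lambda < 0)) msg <- c(msg, "lambda must be non-negative")
  if (is.unsorted(rev(object@lambda)))
    msg <- c(msg, "lambda must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' ATM: one annotated transcriptional module
#'
#' The significant entities of one rank-1 component of a factorization:
#' ranked terms, genes, and TFs that pass the entropy-based significance
#' rule after truncation. Each ranked slot is a data.frame with columns
#' \code{entity} and \code{score}, sorted by score descending with
#' lexicographic tie-breaks.
#'
#' @slot componentIndex integer(1); component number within its run (after
#'   lambda sorting).
#' @slot kOfRun integer(1); the approximation rank of the run.
#' @slot lambda numeric(1); the component weight.
#' @slot terms,genes,tfs data.frames with columns entity, score.
#' @slot degenerate character; modes whose factor column was all zero
#'   (empty when none).
#'
#' @seealso [extractATMs()], [atmMembers()], [atmTable()]
#' @export
setClass("ATM",
  slots = c(
    componentIndex = "integer",
    kOfRun = "integer",
    lambda = "numeric",
    terms = "data.frame",
    genes = "data.frame",
    tfs = "data.frame",
    degenerate = "character"
  )
)

setValidity("ATM", function(object) {
  msg <- character()
  for (nm in c("terms", "genes", "tfs")) {
    df <- slot(object, nm)
    if (!all(c("entity", "score") %in% names(df)))
      msg <- c(msg, sprintf("%s needs entity and score columns", nm))
    else if (nrow(df) > 1 && is.unsorted(rev(df$score)))
      msg <- c(msg, sprintf("%s not sorted by score descending", nm))
  }
  if (length(msg)) msg else TRUE
})

#' GeneSetCollection: gold-standard category sets with descriptions
#'
#' Named categories (e.g. pathways or ontology terms) with free-text
#' descriptions and member identifiers, restricted to a universe. Used
#' for hypergeometric enrichment, term AUC gold standards, precision,
#' and category prediction.
#'
#' @slot sets named list; each element a list with fields \code{name},
#'   \code{description}, \code{members} (character).
#' @slot universe character; the identifier universe.
#'
#' @seealso [geneSetCollection()], [readGMT()], [hypergeomEnrich()]
#' @export
setClass("GeneSetCollection",
  slots = c(sets = "list", universe = "character")
)

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || any(names(object@sets) == ""))
      msg <- c(msg, "sets must be named")
    ok <- vapply(object@sets, function(s)
      all(c("name", "description", "members") %in% names(s)) &&
        length(s$members) > 0 && all(s$members %in% object@universe),
      logical(1))
    if (!all(ok))
      msg <- c(msg, "each set needs name/description/non-empty members within universe")
  }
  if (length(msg)) msg else TRUE
})

#' EvaluationReport: per-module and corpus-level evaluation statistics
#'
#' Collects the evaluation of a list of ATMs against a gene-set
#' collection: per-(ATM, category) hypergeometric enrichment, per-ATM
#' term-ranking AUC and precision, the precision significance test
#' against matched random controls, pairwise Jaccard redundancy, and
#' per-run diversity coefficients.
#'
#' @slot enrichment data.frame of hypergeometric results.
#' @slot auc data.frame of per-ATM term AUCs.
#' @slot precision data.frame of per-ATM precisions.
#' @slot precisionTest list; Welch right-tailed test of ATM precisions
#'   against matched random-control precisions.
#' @slot redundancy data.frame of pairwise Jaccard coefficients.
#' @slot diversity data.frame of per-run diversity coefficients.
#'
#' @seealso [evaluateATMs()]
#' @export
setClass("EvaluationReport",
  slots = c(
    enrichment = "data.frame",
    auc = "data.frame",
    precision = "data.frame",
    precisionTest = "list",
    redundancy = "data.frame",
    diversity = "data.frame"
  )
)
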