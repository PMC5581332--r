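#' Construct a SparseTensor3 from coordinates
#'
#' Duplicate coordinates are merged by summation and entries are sorted
#' by (k, j, i); zero values are dropped.
#'
#' @param i,j,k integer coordinate vectors (1-based).
#' @param value numeric entry values (non-negative).
#' @param dims integer(3) extents (m, n, p).
#' @param labels optional list of three character vectors (terms, genes,
#'   tfs) labelling the modes.
#' @return a [SparseTensor3-class] object.
#' @examples
#' sparseTensor(i = 1:2, j = c(1, 2), k = c(1, 1), value = c(2, 3),
#'              dims = c(2, 2, 2))
#' @export
sparseTensor <- function(i, j, k, value, dims,
                         labels = list(NULL, NULL, NULL)) {
  stopifnot(length(i) == length(j), length(j) == length(k),
            length(k) == length(value), length(dims) == 3L)
  if (any(value < 0)) stop("negative frequency")
  dims <- as.integer(dims)
  keep <- value != 0
  i <- as.integer(i[keep]); j <- as.integer(j[keep])
  k <- as.integer(k[keep]); value <- as.numeric(value[keep])
  if (length(i)) {
    key <- (k - 1) * as.double(dims[1]) * dims[2] +
      (j - 1) * as.double(dims[1]) + i
    if (anyDuplicated(key)) {
      agg <- rowsum(value, group = key, reorder = TRUE)
      key2 <- as.numeric(rownames(agg))
      value <- as.numeric(agg)
      i <- as.integer((key2 - 1) %% dims[1] + 1)
      j <- as.integer(((key2 - 1) %/% dims[1]) %% dims[2] + 1)
      k <- as.integer((key2 - 1) %/% (as.double(dims[1]) * dims[2]) + 1)
    } else {
      ord <- order(key)
      i <- i[ord]; j <- j[ord]; k <- k[ord]; value <- value[ord]
    }
  }
  names(labels) <- c("terms", "genes", "tfs")
  new("SparseTensor3", dims = dims,
      subs = cbind(i = i, j = j, k = k), vals = value,
      axisLabels = labels)
}

#' Logarithmic term-frequency weighting
#'
#' Scales a raw frequency f to log2(1 + f), discounting very frequent
#' common terms in favour of specific ones. Applied entrywise when the
#' weighted tensor is built.
#'
#' @param f numeric vector of non-negative counts.
#' @return log2(1 + f).
#' @examples
#' logWeight(c(0, 1, 3))  # 0 1 2
#' @export
logWeight <- function(f) {
  if (any(f < 0)) stop("negative frequency")
  log2(1 + f)
}

#' Build the weighted term x gene x TF tensor from term counts
#'
#' @param counts result of [countTerms()].
#' @param weighting "log2" (default) stores log2(1 + f) per entry;
#'   "raw" stores the frequency f itself.
#' @return a [SparseTensor3-class] with axis labels taken from the
#'   count structure.
#' @export
buildTensor <- function(counts, weighting = c("log2", "raw")) {
  weighting <- match.arg(weighting)
  e <- counts$entries
  v <- if (weighting == "log2") logWeight(e$count) else as.numeric(e$count)
  sparseTensor(e$term, e$gene, e$tf, v,
               dims = c(length(counts$vocabulary), length(counts$genes),
                        length(counts$tfs)),
               labels = list(counts$vocabulary, counts$genes, counts$tfs))
}

#' Matricize (unfold) a 3-mode tensor
#'
#' Flattens the tensor along one mode into a sparse matrix under fixed
#' 0-based column orderings: mode 1 gives an m x (n p) matrix with column
#' index k*n + j (gene index fastest, TF slowest), matching the
#' Khatri-Rao factor C (x) B; mode 2 gives n x (m p) with column k*m + i;
#' mode 3 gives p x (m n) with column j*m + i. Indices here are written
#' 0-based; the returned matrix is an ordinary 1-based R sparse matrix.
#'
#' @param x a [SparseTensor3-class].
#' @param mode 1, 2, or 3.
#' @return a \code{Matrix::sparseMatrix} (dgCMatrix).
#' @seealso [foldTensor()] for the inverse, [khatriRao()]
#' @export
setMethod("matricize", "SparseTensor3", function(x, mode) {
  if (!mode %in% 1:3) stop("mode must be 1, 2, or 3")
  d <- as.double(x@dims)
  s <- x@subs
  i <- s[, 1]; j <- s[, 2]; k <- s[, 3]
  rc <- switch(mode,
    list(r = i, c = (k - 1) * d[2] + j, nr = d[1], nc = d[2] * d[3]),
    list(r = j, c = (k - 1) * d[1] + i, nr = d[2], nc = d[1] * d[3]),
    list(r = k, c = (j - 1) * d[1] + i, nr = d[3], nc = d[1] * d[2]))
  Matrix::sparseMatrix(i = rc$r, j = rc$c, x = x@vals,
                       dims = c(rc$nr, rc$nc))
})

#' Fold a matricization back into a SparseTensor3
#'
#' Inverse of [matricize()] under the same column-ordering conventions.
#'
#' @param m a sparse or dense matrix produced by unfolding.
#' @param mode the mode that was unfolded (1, 2, or 3).
#' @param dims integer(3) original tensor extents.
#' @param labels optional axis labels.
#' @return a [SparseTensor3-class].
#' @export
foldTensor <- function(m, mode, dims, labels = list(NULL, NULL, NULL)) {
  if (!mode %in% 1:3) stop("mode must be 1, 2, or 3")
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "TsparseMatrix")
  r <- m@i + 1L
  cc <- m@j     # 0-based column index
  d <- as.double(dims)
  ijk <- switch(mode,
    cbind(r, cc %% d[2] + 1, cc %/% d[2] + 1),
    cbind(cc %% d[1] + 1, r, cc %/% d[1] + 1),
    cbind(cc %% d[1] + 1, cc %/% d[1] + 1, r))
  sparseTensor(ijk[, 1], ijk[, 2], ijk[, 3], m@x, dims = dims,
               labels = labels)
}

#' Khatri-Rao (column-wise Kronecker) product
#'
#' Column t of the result is \code{kronecker(U[, t], V[, t])}: the entry
#' for (row a of U, row b of V) lands at row (a-1)*nrow(V) + b, the same
#' ordering the mode matricizations use.
#'
#' @param U,V matrices with an equal number of columns.
#' @return a dense (nrow(U)*nrow(V)) x k matrix.
#' @examples
#' khatriRao(matrix(1:2), matrix(3:4))  # column (3, 4, 6, 8)
#' @export
khatriRao <- function(U, V) {
  U <- as.matrix(U); V <- as.matrix(V)
  if (ncol(U) != ncol(V)) stop("column counts differ")
  out <- vapply(seq_len(ncol(U)),
                function(t) kronecker(U[, t], V[, t]),
                numeric(nrow(U) * nrow(V)))
  matrix(out, nrow = nrow(U) * nrow(V), ncol = ncol(U))
}

#' Frobenius norm of a sparse tensor
#'
#' @param x a [SparseTensor3-class].
#' @return sqrt of the sum of squared stored entries.
#' @export
setMethod("frobeniusNorm", "SparseTensor3", function(x) {
  sqrt(sum(x@vals^2))
})

#' Tensor sparsity bookkeeping
#'
#' Reports the number of stored entries, the total number of cells
#' m*n*p (computed in double precision, exact well beyond 10^12), and
#' their ratio. `densityReport` accepts either a tensor or its printed
#' dimensions plus non-zero count.
#'
#' @param x a [SparseTensor3-class], or a numeric vector of three
#'   extents (m, n, p).
#' @param nnz number of non-zero entries (only when \code{x} gives
#'   extents directly).
#' @param ... unused.
#' @return list with elements \code{nnz}, \code{total}, \code{density}.
#' @examples
#' densityReport(c(10, 10, 10), nnz = 1)$density  # 0.001
#' @export
setMethod("densityReport", "SparseTensor3", function(x, ...) {
  densityReport(as.numeric(x@dims), nnz = nnzCount(x))
})

#' @rdname densityReport
#' @export
setMethod("densityReport", "numeric", function(x, nnz, ...) {
  stopifnot(length(x) == 3L, all(x >= 1))
  total <- prod(as.double(x))
  if (total == 0) stop("zero-size tensor")
  list(nnz = nnz, total = total, density = nnz / total)
})
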