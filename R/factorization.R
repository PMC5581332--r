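## Mode conventions used throughout the solver, matching matricize():
##   mode 1 update of A uses Z = C (x) B   (slow factor C, fast factor B)
##   mode 2 update of B uses Z = C (x) A
##   mode 3 update of C uses Z = B (x) A
.modeParts <- function(x, mode) {
  s <- x@subs
  d <- x@dims
  switch(mode,
    list(r = s[, 1], u = s[, 3], v = s[, 2],
         nr = d[1], nu = d[3], nv = d[2]),
    list(r = s[, 2], u = s[, 3], v = s[, 1],
         nr = d[2], nu = d[3], nv = d[1]),
    list(r = s[, 3], u = s[, 2], v = s[, 1],
         nr = d[3], nu = d[2], nv = d[1]))
}

#' Matricized tensor times Khatri-Rao product (MTTKRP)
#'
#' Computes \code{matricize(x, mode) \%*\% khatriRao(U, V)} without ever
#' materializing the Khatri-Rao product against the full cell count: the
#' work is proportional to nnz(x) * k. This kernel dominates the cost of
#' the alternating solver.
#'
#' @param x a [SparseTensor3-class].
#' @param U the slow-index factor of the Khatri-Rao product (C for mode
#'   1 and 2, B for mode 3).
#' @param V the fast-index factor (B for mode 1, A for modes 2 and 3).
#' @param mode 1, 2, or 3.
#' @return a dense matrix of size dim(x)[mode] x k.
#' @export
mttkrp <- function(x, U, V, mode) {
  stopifnot(is(x, "SparseTensor3"))
  if (!mode %in% 1:3) stop("mode must be 1, 2, or 3")
  U <- as.matrix(U); V <- as.matrix(V)
  if (ncol(U) != ncol(V)) stop("column counts differ")
  p <- .modeParts(x, mode)
  if (nrow(U) != p$nu || nrow(V) != p$nv)
    stop("factor dimensions do not match the tensor")
  k <- ncol(U)
  res <- matrix(0, p$nr, k)
  if (!length(x@vals)) return(res)
  E <- x@vals * U[p$u, , drop = FALSE] * V[p$v, , drop = FALSE]
  acc <- rowsum(E, group = p$r, reorder = TRUE)
  res[as.integer(rownames(acc)), ] <- acc
  res
}

#' One multiplicative update of a factor matrix
#'
#' Updates the factor of the given mode while the other two are held
#' fixed, by the epsilon-stabilized multiplicative rule
#' F <- F * (X_(mode) Z) / (F Z'Z + eps), with Z the Khatri-Rao product
#' of the other two factors. The numerator is evaluated sparsely by
#' [mttkrp()] and Z'Z by the Khatri-Rao Gram identity
#' (U'U) * (V'V) (elementwise), so Z itself is never formed. Zeros in F
#' are preserved and non-negativity is maintained by construction.
#'
#' @param F current factor (non-negative), rows matching the mode.
#' @param x a [SparseTensor3-class].
#' @param U,V the other two factors (slow, fast; see [mttkrp()]).
#' @param mode 1, 2, or 3.
#' @param eps stabilizer added to the denominator (default 1e-9).
#' @return the updated factor matrix.
#' @export
multiplicativeUpdate <- function(F, x, U, V, mode, eps = 1e-9) {
  stopifnot(eps > 0, all(F >= 0))
  num <- mttkrp(x, U, V, mode)
  gram <- crossprod(U) * crossprod(V)
  Fnew <- F * num / (F %*% gram + eps)
  if (!all(is.finite(Fnew)))
    stop("numerical failure in multiplicative update (mode ", mode, ")")
  Fnew
}

#' SVD-based deterministic initialization of the factors
#'
#' Each factor is initialized to the elementwise absolute value of the k
#' leading left singular vectors of the corresponding mode
#' matricization. Left singular vectors are obtained from the
#' eigenvectors of the (small) mode Gram matrix X_(mode) X_(mode)',
#' which avoids forming the wide unfolding. Each eigenvector is
#' sign-flipped so its largest-magnitude entry is positive before taking
#' absolute values (fixes near-tie behaviour); entries below 1e-12 are
#' raised to 1e-12 so multiplicative updates are not zero-locked by
#' round-off. If k exceeds the numerical rank of an unfolding, remaining
#' columns are filled with seeded uniform(0, 1) draws and a warning is
#' issued.
#'
#' @param x a [SparseTensor3-class].
#' @param k approximation rank (>= 1).
#' @param seed integer seed governing rank-deficient padding only.
#' @return list with non-negative matrices A, B, C.
#' @export
initFactors <- function(x, k, seed = 1L) {
  stopifnot(is(x, "SparseTensor3"), k >= 1)
  k <- as.integer(k)
  rng <- .seededRNG(seed)
  out <- lapply(1:3, function(mode) {
    M <- matricize(x, mode)
    G <- as.matrix(Matrix::tcrossprod(M))
    eg <- eigen(G, symmetric = TRUE)
    evals <- pmax(eg$values, 0)
    tolRank <- max(evals) * 1e-8
    r <- sum(evals > tolRank)
    use <- min(k, r, nrow(G))
    Fm <- matrix(0, nrow(G), k)
    if (use > 0) {
      vec <- eg$vectors[, seq_len(use), drop = FALSE]
      flip <- apply(vec, 2, function(v) sign(v[which.max(abs(v))]))
      flip[flip == 0] <- 1
      Fm[, seq_len(use)] <- abs(sweep(vec, 2, flip, `*`))
    }
    if (use < k) {
      warning("rank of mode-", mode, " unfolding (", use,
              ") below k = ", k, "; padding with seeded uniform draws")
      Fm[, (use + 1L):k] <- matrix(rng(nrow(G) * (k - use)),
                                   nrow(G), k - use)
    }
    pmax(Fm, 1e-12)
  })
  names(out) <- c("A", "B", "C")
  out
}

# Counter-based uniform stream: deterministic for a given seed, isolated
# from (and non-destructive to) the global RNG state.
.seededRNG <- function(seed) {
  state <- new.env(parent = emptyenv())
  state$counter <- 0L
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed) + state$counter)
    state$counter <- state$counter + 1L
    runif(n)
  }
}

# squared Frobenius norm of the CP reconstruction via factor Grams
.modelNormSq <- function(A, B, C) {
  sum(crossprod(A) * crossprod(B) * crossprod(C))
}

# inner product <X, [[A, B, C]]> evaluated over the stored entries only
.innerProd <- function(x, A, B, C) {
  if (!length(x@vals)) return(0)
  s <- x@subs
  sum(x@vals * rowSums(A[s[, 1], , drop = FALSE] *
                         B[s[, 2], , drop = FALSE] *
                         C[s[, 3], , drop = FALSE]))
}

#' Fit quality of a CP model against a sparse tensor
#'
#' fit = 1 - ||X - Xhat||_F / ||X||_F, evaluated sparsely through
#' ||X||^2 - 2 <X, Xhat> + ||Xhat||^2 with the factor-Gram identity for
#' the last part, so the cost is proportional to nnz(X) * k.
#'
#' @param x a [SparseTensor3-class].
#' @param A,B,C factor matrices (weights may be folded in or given).
#' @param lambda optional component weights (default all 1).
#' @return the fit value (1 is a perfect reconstruction).
#' @export
cpFit <- function(x, A, B, C, lambda = NULL) {
  if (!is.null(lambda)) A <- sweep(A, 2, lambda, `*`)
  normX <- frobeniusNorm(x)
  if (normX == 0) stop("zero norm")
  err2 <- normX^2 - 2 * .innerProd(x, A, B, C) + .modelNormSq(A, B, C)
  1 - sqrt(max(err2, 0)) / normX
}

#' Non-negative PARAFAC (CP) factorization by multiplicative updates
#'
#' Decomposes the tensor as a sum of k non-negative rank-1 components
#' lambda_i (a_i o b_i o c_i). Each sweep updates A, then B, then C by
#' the epsilon-stabilized multiplicative rule
#' ([multiplicativeUpdate()]), holding the other factors fixed — the
#' alternating solution of the three non-negative least-squares
#' sub-problems for the mode unfoldings. Iteration stops when the
#' absolute change in fit falls below \code{tol} or after
#' \code{maxIter} sweeps. On exit each factor column is normalized to
#' unit 2-norm, the removed norms are accumulated into lambda, and
#' components are sorted by lambda descending (stable in the original
#' component index).
#'
#' @param x a [SparseTensor3-class] with at least one entry.
#' @param k approximation rank (>= 1).
#' @param tol convergence tolerance on the change in fit (default 1e-4).
#' @param maxIter maximum number of alternating sweeps (default 100).
#' @param innerIter multiplicative steps applied to each mode's
#'   sub-problem within one sweep (default 3): a single multiplicative
#'   step per mode makes very small progress, so each non-negative
#'   least-squares sub-problem is advanced a few steps before moving to
#'   the next mode. Monotonicity of the fit is unaffected.
#' @param eps multiplicative-update stabilizer (default 1e-9).
#' @param seed integer seed (used only for rank-deficient initializer
#'   padding).
#' @return a [FactorModel-class].
#' @examples
#' x <- synthTensor(plantedModel(
#'   nTerms = 12, nGenes = 10, nTfs = 4,
#'   blocks = list(list(terms = 1:6, genes = 1:5, tfs = 1:2,
#'                      intensity = 2))))$tensor
#' m <- ntf(x, k = 1, tol = 1e-6)
#' lambdas(m)
#' @export
ntf <- function(x, k, tol = 1e-4, maxIter = 100L, innerIter = 3L,
                eps = 1e-9, seed = 1L) {
  stopifnot(is(x, "SparseTensor3"))
  if (k < 1) stop("k must be >= 1")
  if (!length(x@vals)) stop("zero norm")
  k <- as.integer(k)
  normX <- frobeniusNorm(x)

  f <- initFactors(x, k, seed = seed)
  A <- f$A; B <- f$B; C <- f$C
  fitHist <- numeric(0)
  fitPrev <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    for (r in seq_len(innerIter))
      A <- multiplicativeUpdate(A, x, C, B, mode = 1, eps = eps)
    for (r in seq_len(innerIter))
      B <- multiplicativeUpdate(B, x, C, A, mode = 2, eps = eps)
    for (r in seq_len(innerIter))
      C <- multiplicativeUpdate(C, x, B, A, mode = 3, eps = eps)
    fit <- cpFit(x, A, B, C)
    fitHist <- c(fitHist, fit)
    if (abs(fit - fitPrev) < tol) {
      converged <- TRUE
      break
    }
    fitPrev <- fit
  }

  na <- sqrt(colSums(A^2)); nb <- sqrt(colSums(B^2)); nc <- sqrt(colSums(C^2))
  lambda <- na * nb * nc
  scl <- function(M, nrm) {
    nz <- nrm > 0
    M[, nz] <- sweep(M[, nz, drop = FALSE], 2, nrm[nz], `/`)
    M
  }
  A <- scl(A, na); B <- scl(B, nb); C <- scl(C, nc)
  lab <- x@axisLabels
  rownames(A) <- if (!is.null(lab$terms)) lab$terms else
    sprintf("term%05d", seq_len(nrow(A)))
  rownames(B) <- if (!is.null(lab$genes)) lab$genes else
    sprintf("gene%05d", seq_len(nrow(B)))
  rownames(C) <- if (!is.null(lab$tfs)) lab$tfs else
    sprintf("tf%04d", seq_len(nrow(C)))
  ord <- order(-lambda)      # stable: ties keep original component order
  .newFactorModel(A[, ord, drop = FALSE], B[, ord, drop = FALSE],
                  C[, ord, drop = FALSE], lambda[ord],
                  fitHistory = fitHist, rank = k, iterations = iter,
                  converged = converged, seed = as.integer(seed))
}

# new("FactorModel", C = ...) would partially match new()'s Class
# argument, so the object is filled slot-by-slot instead
.newFactorModel <- function(A, B, C, lambda, fitHistory, rank,
                            iterations, converged, seed) {
  obj <- new("FactorModel")
  obj@A <- A; obj@B <- B; obj@C <- C
  obj@lambda <- lambda
  obj@fitHistory <- fitHistory
  obj@rank <- as.integer(rank)
  obj@iterations <- as.integer(iterations)
  obj@converged <- converged
  obj@seed <- as.integer(seed)
  validObject(obj)
  obj
}

#' Dense reconstruction of a CP model (small tensors only)
#'
#' @param A,B,C factor matrices.
#' @param lambda component weights (default all 1).
#' @return a dense m x n x p array sum_i lambda_i (a_i o b_i o c_i).
#' @export
cpReconstruct <- function(A, B, C, lambda = rep(1, ncol(A))) {
  out <- array(0, c(nrow(A), nrow(B), nrow(C)))
  for (t in seq_len(ncol(A)))
    out <- out + lambda[t] * outer(outer(A[, t], B[, t]), C[, t])
  out
}

#' Dense array view of a sparse tensor (small tensors only)
#'
#' @param x a [SparseTensor3-class].
#' @return a dense m x n x p array.
#' @export
denseTensor <- function(x) {
  out <- array(0, x@dims)
  if (length(x@vals)) out[x@subs] <- x@vals
  out
}
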