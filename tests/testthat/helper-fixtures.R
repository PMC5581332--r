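# Shared fixtures and independent oracles, all built in code.

# dense m x n x p array -> SparseTensor3 (positive cells only)
tensorFromArray <- function(arr, labels = list(NULL, NULL, NULL)) {
  idx <- which(arr > 0, arr.ind = TRUE)
  sparseTensor(idx[, 1], idx[, 2], idx[, 3], arr[idx], dims = dim(arr),
               labels = labels)
}

# random sparse tensor with positive entries, reproducible
randomSparseTensor <- function(dims, nnz, seed = 1) {
  set.seed(seed)
  total <- prod(dims)
  cells <- sample(total, nnz)
  i <- (cells - 1) %% dims[1] + 1
  j <- ((cells - 1) %/% dims[1]) %% dims[2] + 1
  k <- (cells - 1) %/% (dims[1] * dims[2]) + 1
  sparseTensor(i, j, k, runif(nnz, 0.5, 3), dims = dims)
}

# the planted rank-3 solver fixture: 50 x 40 x 10, uniform(0,1) factors
plantedRank3 <- function(seed = 42) {
  set.seed(seed)
  A <- matrix(runif(50 * 3), 50)
  B <- matrix(runif(40 * 3), 40)
  C <- matrix(runif(10 * 3), 10)
  list(A = A, B = B, C = C,
       tensor = tensorFromArray(cpReconstruct(A, B, C)))
}

# character-walk tokenizer oracle: no regexes, one pass over characters
tokenizeOracle <- function(text, stoplist = character()) {
  chars <- strsplit(tolower(text), "")[[1]]
  ok <- chars %in% c(letters, as.character(0:9), "-", "_")
  chars[!ok] <- " "
  toks <- strsplit(paste(chars, collapse = ""), " +")[[1]]
  toks <- toks[nzchar(toks)]
  toks <- vapply(toks, function(t) {
    while (nchar(t) && substr(t, 1, 1) == "-") t <- substring(t, 2)
    while (nchar(t) && substr(t, nchar(t), nchar(t)) == "-")
      t <- substr(t, 1, nchar(t) - 1)
    t
  }, character(1), USE.NAMES = FALSE)
  toks <- toks[nchar(toks) >= 3]
  toks[!(toks %in% tolower(stoplist))]
}

# exhaustive hypergeometric upper-tail oracle: enumerate every draw of
# size ns from a universe of N with M marked, count overlap >= x
hyperOracle <- function(N, M, ns, x) {
  draws <- utils::combn(N, ns)
  marked <- seq_len(M)
  mean(apply(draws, 2, function(d) sum(d %in% marked) >= x))
}

# pair-counting AUC oracle
aucOracle <- function(rankedTerms, relevant) {
  pos <- which(rankedTerms %in% relevant)
  neg <- which(!(rankedTerms %in% relevant))
  if (!length(pos) || !length(neg)) return(NA_real_)
  wins <- 0
  for (p in pos) for (n in neg) {
    if (p < n) wins <- wins + 1
    else if (p == n) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# tiny hand-built corpus used across corpus-module tests
tinyCorpus <- function() {
  citationCorpus(
    geneToPmids = list(
      Wnt1 = c("11", "12"),
      Notch1 = c("13"),
      Shh = c("12", "14"),
      Lef1 = c("12", "13"),
      Gli1 = c("14", "15")),
    tfIds = c("Lef1", "Gli1"),
    abstracts = c(
      `11` = "Wnt signalling in development",
      `12` = "Wnt and Lef1 target activation signalling",
      `13` = "Notch1 repression by Lef1 complex",
      `14` = "Shh pathway activates Gli1 transcription",
      `15` = "Gli1 expression in cerebellum"),
    provenance = "unit-test fixture")
}

# standard two-block planted model for recovery tests
twoBlockModel <- function(seed = 7, noise = 0.1) {
  plantedModel(
    nTerms = 60, nGenes = 20, nTfs = 4,
    blocks = list(
      list(terms = 1:30, genes = 1:10, tfs = 1:2, intensity = 2),
      list(terms = 31:60, genes = 11:20, tfs = 3:4, intensity = 2)),
    noiseRate = noise, seed = seed)
}

# map each ATM to the planted block whose genes it overlaps most
atmBlockAssignment <- function(atms, truth) {
  vapply(atms, function(a) {
    ov <- vapply(truth, function(b)
      length(intersect(a@genes$entity, b$genes)), numeric(1))
    which.max(ov)
  }, integer(1))
}
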