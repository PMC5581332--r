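#' Hypergeometric enrichment of a module in a category
#'
#' Upper-tail hypergeometric test: the probability that a random draw of
#' the module's size from the universe overlaps the category at least as
#' much as observed, P(X >= x) with X ~ hypergeometric(N, M, n_s). The
#' module membership is the pooled set of its genes and TFs.
#'
#' @param atmMembers character; module member identifiers (non-empty,
#'   within the universe).
#' @param category character; category member identifiers.
#' @param universe character; identifier universe.
#' @param alpha significance level for the enriched flag (default 0.05).
#' @return list with x, atmSize, categorySize, universeSize, p, enriched.
#' @examples
#' hypergeomEnrich(c("A", "B", "C"), c("A", "B", "D", "E"), LETTERS[1:10])
#' @export
hypergeomEnrich <- function(atmMembers, category, universe, alpha = 0.05) {
  atmMembers <- unique(atmMembers)
  category <- unique(category)
  universe <- unique(universe)
  if (!length(atmMembers)) stop("empty ATM")
  if (!length(universe)) stop("empty universe")
  stopifnot(all(atmMembers %in% universe), all(category %in% universe))
  N <- length(universe)
  M <- length(category)
  ns <- length(atmMembers)
  x <- length(intersect(atmMembers, category))
  p <- phyper(x - 1, M, N - M, ns, lower.tail = FALSE)
  list(x = x, atmSize = ns, categorySize = M, universeSize = N,
       p = p, enriched = p <= alpha)
}

#' Enrichment of every ATM against every category
#'
#' @param atms list of [ATM-class] objects.
#' @param gsc a [GeneSetCollection-class]; its universe is the test
#'   universe (genes and TFs pooled).
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per (ATM, category) pair whose module
#'   members lie in the universe; columns atm_id, run_k, category, x,
#'   atmSize, categorySize, universeSize, p, enriched.
#' @export
enrichATMs <- function(atms, gsc, alpha = 0.05) {
  stopifnot(is(gsc, "GeneSetCollection"))
  uni <- gsc@universe
  rows <- lapply(seq_along(atms), function(ai) {
    a <- atms[[ai]]
    mem <- intersect(atmMembers(a), uni)
    if (!length(mem)) return(NULL)
    do.call(rbind, lapply(names(gsc@sets), function(cid) {
      r <- hypergeomEnrich(mem, gsc@sets[[cid]]$members, uni, alpha)
      data.frame(atm_id = a@componentIndex, run_k = a@kOfRun,
                 category = cid, x = r$x, atmSize = r$atmSize,
                 categorySize = r$categorySize,
                 universeSize = r$universeSize, p = r$p,
                 enriched = r$enriched, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(atm_id = integer(), run_k = integer(),
                      category = character(), x = integer(),
                      atmSize = integer(), categorySize = integer(),
                      universeSize = integer(), p = numeric(),
                      enriched = logical())
  rownames(out) <- NULL
  out
}

#' Ranking AUC of a term list against a relevant set
#'
#' Mann-Whitney AUC of the ranked list with the relevant terms as
#' positives: 1 when every relevant term precedes every irrelevant one,
#' 0.5 in expectation for a random ordering, 0 for the worst ordering.
#' If explicit scores are supplied, tied scores contribute 0.5 per tied
#' (positive, negative) pair via midranks; without scores the list
#' positions themselves are the ranking (no ties possible).
#'
#' @param rankedTerms character; the ranked list, best first.
#' @param relevant character; the gold-standard relevant terms.
#' @param scores optional numeric scores aligned with rankedTerms
#'   (higher is better).
#' @return AUC in [0, 1], or NA (with a warning) when the list has no
#'   positive or no negative terms.
#' @examples
#' termAUC(c("r1", "n1", "r2", "n2"), c("r1", "r2"))  # 0.75
#' @export
termAUC <- function(rankedTerms, relevant, scores = NULL) {
  stopifnot(length(rankedTerms) > 0)
  pos <- rankedTerms %in% relevant
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  if (nPos == 0 || nNeg == 0) {
    warning("AUC undefined: need both relevant and irrelevant terms")
    return(NA_real_)
  }
  if (is.null(scores)) scores <- rev(seq_along(rankedTerms))
  r <- rank(scores)                    # midranks handle ties
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Precision of a module against a gold-standard set
#'
#' The fraction of the module's pooled genes and TFs found in the gold
#' standard: |members n gold| / |members|.
#'
#' @param atmMembers character; non-empty member identifiers.
#' @param gold character; gold-standard identifiers.
#' @return precision in [0, 1].
#' @export
atmPrecision <- function(atmMembers, gold) {
  atmMembers <- unique(atmMembers)
  if (!length(atmMembers)) stop("empty ATM")
  length(intersect(atmMembers, gold)) / length(atmMembers)
}

#' Right-tailed two-sample Welch's t-test
#'
#' Tests whether the mean of the first sample exceeds that of the
#' second, without assuming equal variances (Welch-Satterthwaite
#' degrees of freedom). Used to compare ATM precisions against the
#' precisions of matched random gene-TF sets. Identical non-degenerate
#' samples give t = 0 and p = 0.5.
#'
#' @param sample1,sample2 numeric vectors with >= 2 values each.
#' @return list with t, df, p.
#' @export
welchRightTailed <- function(sample1, sample2) {
  stopifnot(length(sample1) >= 2, length(sample2) >= 2)
  if (stats::var(sample1) + stats::var(sample2) == 0)
    stop("zero pooled variance")
  tt <- t.test(sample1, sample2, alternative = "greater",
               var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

# run fn with a private, seeded RNG state; global state is untouched
.withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  fn()
}

#' Random gene-TF control sets
#'
#' Draws \code{reps} control sets, each holding \code{nGenes} genes and
#' \code{nTfs} TFs sampled without replacement from the tensor's pools.
#' The defaults (8 genes, 2 TFs, 1,000 repetitions) are the median
#' module sizes used for the enrichment control.
#'
#' @param genePool,tfPool character pools to sample from.
#' @param nGenes,nTfs set sizes.
#' @param reps number of control sets.
#' @param seed integer seed; draws are reproducible and do not disturb
#'   the global RNG state.
#' @return list of \code{reps} lists, each with elements genes and tfs.
#' @export
randomControlSets <- function(genePool, tfPool, nGenes = 8L, nTfs = 2L,
                              reps = 1000L, seed = 1L) {
  if (length(genePool) < nGenes || length(tfPool) < nTfs)
    stop("pool smaller than requested set size")
  .withSeed(seed, function() {
    lapply(seq_len(reps), function(r)
      list(genes = sample(genePool, nGenes),
           tfs = sample(tfPool, nTfs)))
  })
}

#' Control sets matched to the size distribution of given ATMs
#'
#' For each ATM, draws \code{repsPerAtm} random sets with exactly that
#' ATM's gene and TF counts (200 per ATM by default, i.e. 200 x n sets
#' for n ATMs), forming the null for the precision significance test.
#'
#' @param atms list of [ATM-class] objects.
#' @param genePool,tfPool character pools.
#' @param repsPerAtm draws per ATM (default 200).
#' @param seed integer seed.
#' @return flat list of matched control sets (lists with genes, tfs).
#' @export
matchedControlSets <- function(atms, genePool, tfPool, repsPerAtm = 200L,
                               seed = 1L) {
  .withSeed(seed, function() {
    out <- lapply(atms, function(a) {
      ng <- min(nrow(a@genes), length(genePool))
      nt <- min(nrow(a@tfs), length(tfPool))
      lapply(seq_len(repsPerAtm), function(r)
        list(genes = sample(genePool, ng), tfs = sample(tfPool, nt)))
    })
    do.call(c, out)
  })
}

#' Jaccard similarity of two sets
#'
#' |A n B| / |A u B|: 1 for duplicate sets, 0 for disjoint sets. Used
#' as the pairwise redundancy measure between modules.
#'
#' @param setA,setB character vectors (not both empty).
#' @return value in [0, 1].
#' @examples
#' jaccard(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
#' @export
jaccard <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  u <- length(union(setA, setB))
  if (u == 0) stop("both sets empty")
  length(intersect(setA, setB)) / u
}

#' Diversity coefficients of a k-run's modules
#'
#' Per entity type, the ratio of the number of unique entities in the
#' union of the run's ATMs to the total number of entities of that type
#' in the tensor. Defined for runs with k >= 2; for k < 2 all three
#' values are NA (with a warning).
#'
#' @param atms list of [ATM-class] objects from one k-run.
#' @param tensorTotals a [SparseTensor3-class] or numeric(3) of totals
#'   (terms, genes, tfs).
#' @return named numeric(3): genes, tfs, terms.
#' @export
diversityCoefficient <- function(atms, tensorTotals) {
  if (is(tensorTotals, "SparseTensor3"))
    tensorTotals <- as.numeric(dim(tensorTotals))
  stopifnot(length(tensorTotals) == 3L)
  if (!length(atms) || atms[[1]]@kOfRun < 2L) {
    warning("diversity undefined for runs with k < 2")
    return(c(genes = NA_real_, tfs = NA_real_, terms = NA_real_))
  }
  uni <- function(mode) unique(unlist(lapply(atms, function(a)
    slot(a, mode)$entity)))
  c(genes = length(uni("genes")) / tensorTotals[2],
    tfs = length(uni("tfs")) / tensorTotals[3],
    terms = length(uni("terms")) / tensorTotals[1])
}

#' Guilt-by-association category predictions
#'
#' For every (ATM, category) pair significantly enriched at
#' \code{alpha}, proposes the ATM members that are not already
#' annotated to the category. Candidates are deduplicated across ATMs,
#' keeping the ids of all supporting ATMs.
#'
#' @param atms list of [ATM-class] objects.
#' @param enrichment data.frame from [enrichATMs()].
#' @param gsc the [GeneSetCollection-class] holding the annotations.
#' @param alpha enrichment significance level (default 0.05).
#' @return data.frame with columns entity, category, supportingATMs
#'   (comma-separated "run_k:atm_id" labels).
#' @export
gbaPredictions <- function(atms, enrichment, gsc, alpha = 0.05) {
  sig <- enrichment[enrichment$p <= alpha, , drop = FALSE]
  idx <- vapply(atms, function(a)
    paste(a@kOfRun, a@componentIndex, sep = ":"), character(1))
  rows <- lapply(seq_len(nrow(sig)), function(r) {
    aid <- paste(sig$run_k[r], sig$atm_id[r], sep = ":")
    a <- atms[[match(aid, idx)]]
    cand <- setdiff(atmMembers(a), gsc@sets[[sig$category[r]]]$members)
    if (!length(cand)) return(NULL)
    data.frame(entity = cand, category = sig$category[r], atm = aid,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(entity = character(), category = character(),
                      supportingATMs = character()))
  key <- paste(out$entity, out$category, sep = "\r")
  agg <- tapply(out$atm, key, function(x)
    paste(sort(unique(x)), collapse = ","))
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  res <- data.frame(
    entity = vapply(parts, `[`, character(1), 1),
    category = vapply(parts, `[`, character(1), 2),
    supportingATMs = as.character(agg), stringsAsFactors = FALSE)
  res <- res[order(res$category, res$entity), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Term-mapping category predictions for one ATM
#'
#' Ranks categories by the number of the ATM's significant terms found
#' among the tokens of the category's name and description (tokenized
#' with the corpus tokenizer, so both sides share one vocabulary).
#' Categories already significantly enriched for this ATM are excluded;
#' categories below \code{minOverlap} are dropped.
#'
#' @param atm an [ATM-class] object.
#' @param gsc a [GeneSetCollection-class] whose sets carry descriptions.
#' @param minOverlap minimum term overlap to report (default 1).
#' @param enrichment optional data.frame from [enrichATMs()] used to
#'   exclude already-enriched categories.
#' @param alpha significance level for the exclusion (default 0.05).
#' @param stoplist stop words for tokenizing descriptions.
#' @return data.frame with columns category, overlap, ranked by overlap
#'   descending (ties by category id).
#' @export
termMappingPredictions <- function(atm, gsc, minOverlap = 1L,
                                   enrichment = NULL, alpha = 0.05,
                                   stoplist = character()) {
  terms <- atm@terms$entity
  excl <- character()
  if (!is.null(enrichment) && nrow(enrichment)) {
    m <- enrichment$atm_id == atm@componentIndex &
      enrichment$run_k == atm@kOfRun & enrichment$p <= alpha
    excl <- enrichment$category[m]
  }
  ids <- setdiff(names(gsc@sets), excl)
  ov <- vapply(ids, function(cid) {
    s <- gsc@sets[[cid]]
    toks <- unique(tokenize(paste(s$name, s$description),
                            stoplist = stoplist))
    length(intersect(terms, toks))
  }, numeric(1))
  keep <- ov >= minOverlap
  out <- data.frame(category = ids[keep], overlap = as.integer(ov[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$overlap, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate a list of ATMs against a gene-set collection
#'
#' Runs the full evaluation battery: hypergeometric enrichment of every
#' ATM in every category; per-ATM term-ranking AUC against the pooled
#' tokens of the names and descriptions of that ATM's enriched
#' categories; per-ATM precision against an optional gold-standard set
#' with a right-tailed Welch test against size-matched random controls;
#' pairwise Jaccard redundancy of module memberships; and per-run
#' diversity coefficients.
#'
#' @param atms list of [ATM-class] objects.
#' @param gsc a [GeneSetCollection-class].
#' @param tensor the [SparseTensor3-class] the ATMs came from (for
#'   diversity totals and control pools); may be NULL to skip those.
#' @param gold optional character vector of gold-standard identifiers
#'   for precision.
#' @param alpha enrichment significance level (default 0.05).
#' @param controlRepsPerAtm matched control draws per ATM (default 200).
#' @param seed integer seed for the random controls.
#' @param stoplist stop words used when tokenizing category text.
#' @return an [EvaluationReport-class].
#' @export
evaluateATMs <- function(atms, gsc, tensor = NULL, gold = NULL,
                         alpha = 0.05, controlRepsPerAtm = 200L,
                         seed = 1L, stoplist = character()) {
  enr <- enrichATMs(atms, gsc, alpha)

  aucRows <- lapply(atms, function(a) {
    m <- enr$atm_id == a@componentIndex & enr$run_k == a@kOfRun &
      enr$p <= alpha
    cats <- enr$category[m]
    if (!length(cats) || !nrow(a@terms)) return(NULL)
    goldTerms <- unique(unlist(lapply(cats, function(cid) {
      s <- gsc@sets[[cid]]
      tokenize(paste(s$name, s$description), stoplist = stoplist)
    })))
    auc <- suppressWarnings(
      termAUC(a@terms$entity, goldTerms, scores = a@terms$score))
    data.frame(atm_id = a@componentIndex, run_k = a@kOfRun,
               nEnriched = length(cats), auc = auc)
  })
  aucDf <- do.call(rbind, aucRows)
  if (is.null(aucDf))
    aucDf <- data.frame(atm_id = integer(), run_k = integer(),
                        nEnriched = integer(), auc = numeric())

  precDf <- data.frame(atm_id = integer(), run_k = integer(),
                       precision = numeric())
  ptest <- list()
  if (!is.null(gold)) {
    precDf <- do.call(rbind, lapply(atms, function(a)
      data.frame(atm_id = a@componentIndex, run_k = a@kOfRun,
                 precision = atmPrecision(atmMembers(a), gold))))
    if (!is.null(tensor) && length(atms) >= 2) {
      lab <- axisLabels(tensor)
      ctrl <- matchedControlSets(atms, lab$genes, lab$tfs,
                                 repsPerAtm = controlRepsPerAtm,
                                 seed = seed)
      ctrlPrec <- vapply(ctrl, function(s)
        atmPrecision(c(s$genes, s$tfs), gold), numeric(1))
      ptest <- welchRightTailed(precDf$precision, ctrlPrec)
    }
  }

  redRows <- NULL
  if (length(atms) >= 2) {
    cmb <- utils::combn(length(atms), 2)
    redRows <- data.frame(
      atm1 = cmb[1, ], atm2 = cmb[2, ],
      jaccard = apply(cmb, 2, function(ix)
        jaccard(atmMembers(atms[[ix[1]]]), atmMembers(atms[[ix[2]]]))))
  } else {
    redRows <- data.frame(atm1 = integer(), atm2 = integer(),
                          jaccard = numeric())
  }

  divDf <- data.frame(run_k = integer(), genes = numeric(),
                      tfs = numeric(), terms = numeric())
  if (!is.null(tensor)) {
    ks <- unique(vapply(atms, function(a) a@kOfRun, integer(1)))
    divDf <- do.call(rbind, lapply(ks, function(kk) {
      sub <- Filter(function(a) a@kOfRun == kk, atms)
      d <- suppressWarnings(diversityCoefficient(sub, tensor))
      data.frame(run_k = kk, genes = d[["genes"]], tfs = d[["tfs"]],
                 terms = d[["terms"]])
    }))
  }

  new("EvaluationReport", enrichment = enr, auc = aucDf,
      precision = precDf, precisionTest = ptest,
      redundancy = redRows, diversity = divDf)
}
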