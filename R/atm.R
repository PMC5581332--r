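#' Normalized entropy of a score list
#'
#' Scores g_i are converted to proportions p_i = g_i / sum(g) and the
#' Shannon entropy -sum p_i log p_i is divided by log n, giving the
#' fraction of information content relative to a uniform list of the
#' same size: 1 for a uniform list, 0 for a point mass. The convention
#' 0 * log 0 = 0 applies; the ratio of logarithms makes the value
#' independent of the log base (base 2 is used internally).
#'
#' @param scores numeric vector of n >= 2 non-negative values with a
#'   positive sum.
#' @return entropy in [0, 1].
#' @examples
#' normalizedEntropy(c(4, 2, 1, 1))  # 0.875
#' @export
normalizedEntropy <- function(scores) {
  n <- length(scores)
  if (n < 2L) stop("need at least two scores")
  if (any(scores < 0)) stop("negative score")
  S <- sum(scores)
  if (S == 0) stop("degenerate list")
  p <- scores / S
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(n)
}

#' Number of significant entities in a ranked score list
#'
#' Implements the entropy-based threshold: with E the normalized
#' entropy of the list, an entity is significant when its proportion
#' p_i exceeds E / n (the uniform proportion 1/n scaled by the list's
#' information content), and at least one entity is always kept:
#' s = max(1, |p_i > E/n|). A uniform list has p_i = 1/n = E/n exactly
#' (strict inequality fails), giving s = 1. The alternative reading of
#' the threshold as 1 / (n E) is available via \code{rule = "inverse"}.
#'
#' @param scores numeric vector of n >= 2 non-negative values with a
#'   positive sum.
#' @param rule "scaled" (threshold E/n, default) or "inverse"
#'   (threshold 1/(n E)).
#' @return integer s with 1 <= s <= n.
#' @examples
#' significantCount(c(4, 2, 1, 1))  # 2
#' @export
significantCount <- function(scores, rule = c("scaled", "inverse")) {
  rule <- match.arg(rule)
  E <- normalizedEntropy(scores)
  n <- length(scores)
  p <- scores / sum(scores)
  thr <- if (rule == "scaled") E / n else {
    if (E == 0) Inf else 1 / (n * E)
  }
  max(1L, sum(p > thr))
}

.rankedMode <- function(scores, labels, bound, rule) {
  ord <- order(-scores, labels)
  n <- min(bound, length(scores))
  top <- ord[seq_len(n)]
  topScores <- scores[top]
  if (sum(topScores) == 0) {
    return(list(df = data.frame(entity = labels[order(labels)][1],
                                score = 0, stringsAsFactors = FALSE),
                degenerate = TRUE))
  }
  s <- if (n >= 2L) significantCount(topScores, rule = rule) else 1L
  keep <- top[seq_len(s)]
  list(df = data.frame(entity = labels[keep], score = scores[keep],
                       stringsAsFactors = FALSE),
       degenerate = FALSE)
}

#' Extract annotated transcriptional modules from a factor model
#'
#' For every component and every mode, takes the truncated list of the
#' \code{bound} highest-scoring entities (ties at the boundary broken
#' lexicographically on the entity label), applies the entropy-based
#' significance rule ([significantCount()]) to the truncated scores,
#' and keeps the top s entities. The default truncation bounds
#' (300 terms, 184 genes, 21 TFs) reflect the sizes observed in curated
#' pathway collections and typical abstract lengths. A component whose
#' factor column is entirely zero in some mode is emitted with a single
#' zero-score placeholder entity and that mode flagged degenerate.
#'
#' @param model a [FactorModel-class] (factor rows must be labelled;
#'   [ntf()] labels them from the tensor's axis labels).
#' @param bounds named numeric vector with elements terms, genes, tfs.
#' @param rule threshold reading passed to [significantCount()].
#' @return list of [ATM-class] objects, one per component, in lambda
#'   order.
#' @export
extractATMs <- function(model,
                        bounds = c(terms = 300, genes = 184, tfs = 21),
                        rule = c("scaled", "inverse")) {
  stopifnot(is(model, "FactorModel"))
  rule <- match.arg(rule)
  stopifnot(all(c("terms", "genes", "tfs") %in% names(bounds)))
  mats <- list(terms = model@A, genes = model@B, tfs = model@C)
  lapply(seq_len(model@rank), function(ci) {
    parts <- lapply(names(mats), function(nm) {
      M <- mats[[nm]]
      .rankedMode(M[, ci], rownames(M), bounds[[nm]], rule)
    })
    names(parts) <- names(mats)
    degen <- names(parts)[vapply(parts, `[[`, logical(1), "degenerate")]
    new("ATM",
        componentIndex = as.integer(ci),
        kOfRun = model@rank,
        lambda = model@lambda[ci],
        terms = parts$terms$df,
        genes = parts$genes$df,
        tfs = parts$tfs$df,
        degenerate = degen)
  })
}

#' Flat table of a list of ATMs
#'
#' @param atms list of [ATM-class] objects.
#' @return data.frame with columns run_k, atm_id, mode, rank, entity,
#'   score — the flat serialization format.
#' @export
atmTable <- function(atms) {
  rows <- lapply(atms, function(a) {
    do.call(rbind, lapply(c("terms", "genes", "tfs"), function(m) {
      df <- slot(a, m)
      if (!nrow(df)) return(NULL)
      data.frame(run_k = a@kOfRun, atm_id = a@componentIndex, mode = m,
                 rank = seq_len(nrow(df)), entity = df$entity,
                 score = df$score, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
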