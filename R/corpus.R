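#' Construct a CitationCorpus
#'
#' Assembles the document collection used to build the term x gene x TF
#' tensor. Identifiers are matched case-insensitively and stored
#' upper-cased; PMIDs referenced by the citation map but missing from the
#' abstract store are dropped (a message reports how many), and TF
#' identifiers without any citation are ignored.
#'
#' @param geneToPmids named list mapping entity identifier (gene or TF
#'   symbol) to a character vector of PMIDs.
#' @param tfIds character vector of identifiers designated as TFs.
#' @param abstracts named character vector, PMID -> title+abstract text.
#' @param provenance free-text source label.
#' @return a [CitationCorpus-class] object.
#' @examples
#' corp <- citationCorpus(
#'   list(Wnt1 = c("1", "2"), Lef1 = "2"),
#'   tfIds = "Lef1",
#'   abstracts = c(`1` = "wnt signalling", `2` = "wnt lef1 target"))
#' corp
#' @export
citationCorpus <- function(geneToPmids, tfIds, abstracts, provenance = "") {
  stopifnot(is.list(geneToPmids), is.character(tfIds) || length(tfIds) == 0)
  names(geneToPmids) <- toupper(names(geneToPmids))
  if (anyDuplicated(names(geneToPmids))) {
    merged <- tapply(geneToPmids, names(geneToPmids),
                     function(x) unique(unlist(x)), simplify = FALSE)
    geneToPmids <- merged[order(names(merged))]
  }
  geneToPmids <- lapply(geneToPmids, as.character)
  tfIds <- unique(toupper(tfIds))
  tfIds <- intersect(tfIds, names(geneToPmids))

  have <- names(abstracts)
  dangling <- 0L
  geneToPmids <- lapply(geneToPmids, function(p) {
    keep <- p %in% have
    dangling <<- dangling + sum(!keep)
    p[keep]
  })
  if (dangling > 0L)
    message("dropped ", dangling, " citation reference(s) without an abstract")
  empty <- lengths(geneToPmids) == 0L
  geneToPmids <- geneToPmids[!empty]
  tfIds <- intersect(tfIds, names(geneToPmids))

  new("CitationCorpus", geneToPmids = geneToPmids, tfIds = tfIds,
      abstracts = abstracts, provenance = provenance)
}

#' Remove non-specific citations from a gene -> PMID map
#'
#' Citations referring to very many genes typically describe
#' high-throughput screens with little entity-specific functional
#' content, so PMIDs referenced by more than \code{maxGenesPerPmid}
#' entities are removed from every entity's citation set. Entities left
#' with no citations are dropped. The operation is idempotent: a second
#' application changes nothing, because removing a PMID can only shrink
#' per-PMID reference counts.
#'
#' @param rawMap named list, entity identifier -> character vector of PMIDs.
#' @param maxGenesPerPmid maximum number of entities a retained citation
#'   may reference (default 10).
#' @return the filtered named list.
#' @examples
#' filterCitations(list(A = c("1", "2"), B = "2"), maxGenesPerPmid = 1)
#' @export
filterCitations <- function(rawMap, maxGenesPerPmid = 10L) {
  if (!length(rawMap)) stop("empty citation map")
  stopifnot(maxGenesPerPmid >= 1)
  pairs <- data.frame(
    gene = rep(names(rawMap), lengths(rawMap)),
    pmid = as.character(unlist(rawMap, use.names = FALSE)),
    stringsAsFactors = FALSE)
  pairs <- unique(pairs)
  nGenes <- table(pairs$pmid)
  bad <- names(nGenes)[nGenes > maxGenesPerPmid]
  out <- lapply(rawMap, function(p) setdiff(unique(as.character(p)), bad))
  out[lengths(out) > 0L]
}

#' Build gene-TF pair documents from shared citations
#'
#' For every (gene, TF) pair with gene outside the TF set that shares at
#' least one citation, constructs one document by concatenating the
#' title+abstract texts of all shared citations in ascending numeric PMID
#' order (so the text, and hence every downstream term count, is
#' deterministic). Genes sharing no citation with any TF do not appear.
#' TF-TF pairs are not formed: the gene mode of the tensor contains only
#' non-TF genes.
#'
#' @param corpus a [CitationCorpus-class] object.
#' @return data.frame with columns \code{gene}, \code{tf}, \code{text},
#'   and list-column \code{pmids}, sorted by (gene, tf).
#' @examples
#' corp <- citationCorpus(
#'   list(Wnt1 = c("1", "2"), Lef1 = "2"),
#'   tfIds = "Lef1",
#'   abstracts = c(`1` = "wnt signalling", `2` = "wnt lef1 target"))
#' buildPairDocuments(corp)
#' @export
buildPairDocuments <- function(corpus) {
  stopifnot(is(corpus, "CitationCorpus"))
  validObject(corpus)
  if (!length(corpus@tfIds)) stop("no TFs in corpus")
  genes <- setdiff(names(corpus@geneToPmids), corpus@tfIds)
  tfs <- corpus@tfIds

  # inverted index pmid -> citing genes / tfs keeps this near-linear in
  # the number of (entity, pmid) links rather than |genes| x |tfs|
  gmap <- corpus@geneToPmids[genes]
  tmap <- corpus@geneToPmids[tfs]
  glong <- data.frame(ent = rep(genes, lengths(gmap)),
                      pmid = unlist(gmap, use.names = FALSE))
  tlong <- data.frame(ent = rep(tfs, lengths(tmap)),
                      pmid = unlist(tmap, use.names = FALSE))
  hits <- merge(glong, tlong, by = "pmid", suffixes = c(".gene", ".tf"))
  if (!nrow(hits)) {
    return(data.frame(gene = character(), tf = character(),
                      text = character(),
                      pmids = I(list()), stringsAsFactors = FALSE))
  }
  key <- paste(hits$ent.gene, hits$ent.tf, sep = "\r")
  shared <- split(hits$pmid, key)
  ids <- strsplit(names(shared), "\r", fixed = TRUE)
  out <- data.frame(
    gene = vapply(ids, `[`, character(1), 1L),
    tf = vapply(ids, `[`, character(1), 2L),
    stringsAsFactors = FALSE)
  pm <- lapply(shared, function(p) {
    p <- unique(p)
    p[order(suppressWarnings(as.numeric(p)), p)]
  })
  out$text <- vapply(pm, function(p)
    paste(corpus@abstracts[p], collapse = " "), character(1))
  out$pmids <- I(unname(pm))
  ord <- order(out$gene, out$tf)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tokenize text into vocabulary terms
#'
#' Lower-cases the text, treats every character that is not alphanumeric,
#' hyphen, or underscore as whitespace, splits on whitespace, strips
#' leading/trailing hyphens from each token, then removes tokens shorter
#' than three characters and tokens in the stop list. Order and
#' multiplicity are preserved (frequencies matter downstream).
#'
#' @param text character(1).
#' @param stoplist character vector of stop words (compared lower-cased).
#' @param dropNumeric if TRUE, tokens consisting only of digits are also
#'   removed (default FALSE: numeric tokens of length >= 3 are kept).
#' @return character vector of tokens (possibly empty).
#' @examples
#' tokenize("Atoh1, a bHLH-domain factor!", stoplist = "a")
#' @export
tokenize <- function(text, stoplist = character(), dropNumeric = FALSE) {
  if (!length(text) || is.na(text) || !nzchar(text)) return(character())
  x <- tolower(text)
  x <- gsub("[^a-z0-9_-]+", " ", x)
  toks <- strsplit(trimws(x), "[ ]+")[[1]]
  toks <- gsub("^-+|-+$", "", toks)
  toks <- toks[nchar(toks) >= 3L]
  if (length(stoplist)) toks <- toks[!(toks %in% tolower(stoplist))]
  if (dropNumeric) toks <- toks[!grepl("^[0-9]+$", toks)]
  toks
}

#' Count term frequencies over pair documents
#'
#' Tokenizes every pair document and emits the non-zero term frequencies
#' as coordinate entries over a shared vocabulary. The vocabulary and the
#' gene and TF index maps are lexicographic, so index assignment is
#' deterministic.
#'
#' @param docs data.frame from [buildPairDocuments()].
#' @param stoplist,dropNumeric passed to [tokenize()].
#' @return list with elements \code{vocabulary} (ordered character;
#'   position is the term index), \code{genes}, \code{tfs} (ordered label
#'   vectors), and \code{entries}: a data.frame with integer columns
#'   \code{term}, \code{gene}, \code{tf} (1-based indices) and
#'   \code{count} (> 0).
#' @export
countTerms <- function(docs, stoplist = character(), dropNumeric = FALSE) {
  if (!is.data.frame(docs) || !nrow(docs)) stop("no pair documents")
  tokLists <- lapply(docs$text, tokenize, stoplist = stoplist,
                     dropNumeric = dropNumeric)
  vocab <- sort(unique(unlist(tokLists, use.names = FALSE)))
  if (!length(vocab)) stop("empty vocabulary")
  genes <- sort(unique(docs$gene))
  tfs <- sort(unique(docs$tf))
  gi <- match(docs$gene, genes)
  ti <- match(docs$tf, tfs)
  parts <- lapply(seq_along(tokLists), function(r) {
    toks <- tokLists[[r]]
    if (!length(toks)) return(NULL)
    tab <- table(toks)
    data.frame(term = match(names(tab), vocab),
               gene = gi[r], tf = ti[r],
               count = as.integer(tab))
  })
  entries <- do.call(rbind, parts)
  entries <- entries[order(entries$tf, entries$gene, entries$term), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  list(vocabulary = vocab, genes = genes, tfs = tfs, entries = entries)
}
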