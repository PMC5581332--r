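#' Read a gene2pubmed-style citation map
#'
#' Tab-separated with optional '#'-prefixed header; columns tax_id,
#' GeneID, PubMed_ID (only the last two are used).
#'
#' @param path file path.
#' @return named list, gene identifier -> character vector of PMIDs.
#' @export
readGene2Pubmed <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   colClasses = "character",
                   col.names = c("tax_id", "GeneID", "PubMed_ID"))
  if (!nrow(df)) stop("empty citation map")
  split(df$PubMed_ID, df$GeneID)
}

#' Read a JSON Lines abstract store
#'
#' One JSON object per line with keys pmid, title, abstract. The title
#' and abstract are concatenated into one text per citation.
#'
#' @param path file path.
#' @return named character vector, PMID -> text.
#' @export
readAbstracts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  texts <- vapply(recs, function(r)
    trimws(paste(r$title, r$abstract)), character(1))
  names(texts) <- vapply(recs, function(r) as.character(r$pmid),
                         character(1))
  texts
}

#' Read a one-identifier-per-line list (TF list or stop list)
#'
#' @param path file path.
#' @return character vector (blank lines dropped).
#' @export
readLineList <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Bundled default English stop-word list
#'
#' @return character vector of stop words.
#' @export
defaultStoplist <- function() {
  readLineList(system.file("extdata", "stoplist-english.txt",
                           package = "tensorATM", mustWork = TRUE))
}

#' Construct a GeneSetCollection
#'
#' Members are restricted to the universe; sets left empty after the
#' restriction are dropped with a message.
#'
#' @param sets named list; each element a list with name, description,
#'   members.
#' @param universe character identifier universe (default: union of all
#'   members).
#' @return a [GeneSetCollection-class].
#' @export
geneSetCollection <- function(sets,
                              universe = unique(unlist(
                                lapply(sets, `[[`, "members")))) {
  sets <- lapply(sets, function(s) {
    s$members <- intersect(unique(toupper(s$members)), universe)
    s
  })
  empty <- vapply(sets, function(s) length(s$members) == 0L, logical(1))
  if (any(empty))
    message("dropped ", sum(empty), " empty set(s) after restriction")
  new("GeneSetCollection", sets = sets[!empty],
      universe = unique(toupper(universe)))
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set id, description, then member identifiers.
#' Descriptions may be overridden from a two-column TSV (id, free text)
#' for term-mapping use.
#'
#' @param path GMT file path.
#' @param universe optional identifier universe for restriction.
#' @param descriptionsPath optional two-column TSV (id TAB text).
#' @return a [GeneSetCollection-class].
#' @export
readGMT <- function(path, universe = NULL, descriptionsPath = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) {
    if (length(f) < 3) stop("malformed GMT line: ", f[1])
    list(name = f[1], description = f[2], members = toupper(f[-(1:2)]))
  })
  names(sets) <- toupper(vapply(fields, `[`, character(1), 1))
  if (!is.null(descriptionsPath)) {
    dd <- read.delim(descriptionsPath, header = FALSE,
                     colClasses = "character",
                     col.names = c("id", "text"))
    hit <- match(toupper(dd$id), names(sets))
    for (r in which(!is.na(hit)))
      sets[[hit[r]]]$description <- dd$text[r]
  }
  if (is.null(universe))
    universe <- unique(unlist(lapply(sets, `[[`, "members")))
  geneSetCollection(sets, toupper(universe))
}

#' Write / read a sparse tensor dump
#'
#' TSV with a header line \code{#dims m n p} followed by rows
#' \code{i j k value} with 0-based indices; axis labels go to companion
#' files \code{<path>.terms}, \code{<path>.genes}, \code{<path>.tfs}
#' when present.
#'
#' @param x a [SparseTensor3-class].
#' @param path output path.
#' @return `writeTensorTSV` invisibly returns the path;
#'   `readTensorTSV` returns the tensor.
#' @export
writeTensorTSV <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#dims %d %d %d", x@dims[1], x@dims[2], x@dims[3]),
             con)
  if (length(x@vals))
    writeLines(sprintf("%d\t%d\t%d\t%.17g",
                       x@subs[, 1] - 1L, x@subs[, 2] - 1L,
                       x@subs[, 3] - 1L, x@vals), con)
  lab <- x@axisLabels
  ext <- c("terms", "genes", "tfs")
  for (e in ext)
    if (!is.null(lab[[e]]))
      writeLines(lab[[e]], paste0(path, ".", e))
  invisible(path)
}

#' @rdname writeTensorTSV
#' @export
readTensorTSV <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#dims ", first)) stop("missing #dims header")
  dims <- as.integer(strsplit(sub("^#dims ", "", first), " ")[[1]])
  body <- read.delim(path, header = FALSE, comment.char = "#",
                     col.names = c("i", "j", "k", "value"))
  lab <- lapply(c("terms", "genes", "tfs"), function(e) {
    f <- paste0(path, ".", e)
    if (file.exists(f)) readLineList(f) else NULL
  })
  sparseTensor(body$i + 1L, body$j + 1L, body$k + 1L, body$value,
               dims = dims, labels = lab)
}

#' Serialize ATMs to JSON
#'
#' @param atms list of [ATM-class] objects.
#' @param path output path (JSON).
#' @return invisibly, the path.
#' @export
writeATMsJSON <- function(atms, path) {
  obj <- lapply(atms, function(a) list(
    componentIndex = a@componentIndex, kOfRun = a@kOfRun,
    lambda = a@lambda, degenerate = a@degenerate,
    terms = a@terms, genes = a@genes, tfs = a@tfs))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Serialize a factor model
#'
#' Writes JSON metadata (rank, iterations, convergence, fit history,
#' lambda) plus one TSV per factor matrix.
#'
#' @param model a [FactorModel-class].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeFactorModel <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(rank = model@rank, iterations = model@iterations,
               converged = model@converged, seed = model@seed,
               lambda = model@lambda, fitHistory = model@fitHistory)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in c("A", "B", "C"))
    write.table(slot(model, nm),
                file.path(dir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(dir)
}
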