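#' Assemble a pipeline run configuration
#'
#' @param gene2pubmed,abstracts,tfList,stoplist,gmt input file paths
#'   (formats as in [readGene2Pubmed()], [readAbstracts()],
#'   [readLineList()], [readGMT()]).
#' @param outDir output directory.
#' @param ranks strictly increasing positive approximation ranks. The
#'   default is the 16-rank ladder 1, 2, 3, 5, 10, 15, 20, 25, 30, 50,
#'   100, 200, 300, 500, 700, 900 (2,861 components in total).
#' @param maxGenesPerPmid citation-specificity filter (default 10).
#' @param tol,eps,maxIter solver settings (see [ntf()]).
#' @param bounds ATM truncation bounds (see [extractATMs()]).
#' @param alpha enrichment significance level.
#' @param seed integer master seed.
#' @param dropNumeric drop purely numeric tokens (default FALSE).
#' @return a validated configuration list of class "RunConfig".
#' @export
runConfig <- function(gene2pubmed, abstracts, tfList, stoplist = NULL,
                      gmt = NULL, outDir = tempfile("atm-run"),
                      ranks = c(1, 2, 3, 5, 10, 15, 20, 25, 30, 50,
                                100, 200, 300, 500, 700, 900),
                      maxGenesPerPmid = 10L, tol = 1e-4, eps = 1e-9,
                      maxIter = 100L,
                      bounds = c(terms = 300, genes = 184, tfs = 21),
                      alpha = 0.05, seed = 1L, dropNumeric = FALSE) {
  ranks <- as.integer(ranks)
  stopifnot(all(ranks >= 1), !is.unsorted(ranks, strictly = TRUE),
            tol > 0, eps > 0, maxIter >= 1, alpha > 0, alpha <= 1)
  structure(list(
    gene2pubmed = gene2pubmed, abstracts = abstracts, tfList = tfList,
    stoplist = stoplist, gmt = gmt, outDir = outDir, ranks = ranks,
    maxGenesPerPmid = as.integer(maxGenesPerPmid), tol = tol, eps = eps,
    maxIter = as.integer(maxIter), bounds = bounds, alpha = alpha,
    seed = as.integer(seed), dropNumeric = isTRUE(dropNumeric)),
    class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys match the arguments of [runConfig()].
#' @return a "RunConfig" list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$bounds)) y$bounds <- unlist(y$bounds)
  do.call(runConfig, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full literature-tensor pipeline
#'
#' Executes build-corpus, build-tensor, one factorization per rank,
#' module extraction, and (when a gene-set file is configured)
#' evaluation; writes the tensor dump, per-rank ATM JSON/TSV, the
#' evaluation summary, and a manifest (input hashes, configuration,
#' per-stage record counts) to the output directory. Per-stage timing
#' is logged to stderr. A failure in any stage aborts with the stage
#' name.
#'
#' @param config a "RunConfig" from [runConfig()] / [readRunConfig()].
#' @return the manifest, invisibly written to
#'   \code{file.path(config$outDir, "manifest.json")}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  note <- function(stage)
    message(sprintf("[%s] done at %.1fs", stage,
                    proc.time()[["elapsed"]] - t0))

  stoplist <- if (!is.null(config$stoplist))
    readLineList(config$stoplist) else defaultStoplist()

  corpus <- .stage("build-corpus", {
    rawMap <- readGene2Pubmed(config$gene2pubmed)
    rawMap <- filterCitations(rawMap, config$maxGenesPerPmid)
    citationCorpus(rawMap, readLineList(config$tfList),
                   readAbstracts(config$abstracts),
                   provenance = config$gene2pubmed)
  })
  note("build-corpus")

  built <- .stage("build-tensor", {
    pairs <- buildPairDocuments(corpus)
    counts <- countTerms(pairs, stoplist = stoplist,
                         dropNumeric = config$dropNumeric)
    x <- buildTensor(counts)
    writeTensorTSV(x, file.path(config$outDir, "tensor.tsv"))
    list(pairs = pairs, tensor = x)
  })
  note("build-tensor")
  x <- built$tensor

  atms <- .stage("factorize-extract", {
    out <- list()
    for (k in config$ranks) {
      model <- ntf(x, k, tol = config$tol, maxIter = config$maxIter,
                   eps = config$eps, seed = config$seed)
      writeFactorModel(model,
                       file.path(config$outDir, sprintf("model_k%03d", k)))
      out <- c(out, extractATMs(model, bounds = config$bounds))
      message(sprintf("[factorize] k=%d: %d sweeps, fit %.4f", k,
                      model@iterations,
                      model@fitHistory[length(model@fitHistory)]))
    }
    writeATMsJSON(out, file.path(config$outDir, "atms.json"))
    write.table(atmTable(out), file.path(config$outDir, "atms.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })
  note("factorize-extract")

  report <- NULL
  if (!is.null(config$gmt)) {
    report <- .stage("evaluate", {
      gsc <- readGMT(config$gmt,
                     universe = toupper(c(axisLabels(x)$genes,
                                          axisLabels(x)$tfs)))
      rep <- evaluateATMs(atms, gsc, tensor = x, alpha = config$alpha,
                          seed = config$seed, stoplist = stoplist)
      jsonlite::write_json(
        list(enrichment = rep@enrichment, auc = rep@auc,
             diversity = rep@diversity),
        file.path(config$outDir, "evaluation.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "columns")
      rep
    })
    note("evaluate")
  }

  inputs <- Filter(Negate(is.null),
                   config[c("gene2pubmed", "abstracts", "tfList",
                            "stoplist", "gmt")])
  manifest <- list(
    config = unclass(config),
    inputHashes = as.list(tools::md5sum(unlist(inputs))),
    counts = list(
      entities = length(corpus@geneToPmids),
      tfs = length(corpus@tfIds),
      abstracts = length(corpus@abstracts),
      pairs = nrow(built$pairs),
      tensorNnz = nnzCount(x),
      tensorDims = as.integer(dim(x)),
      atms = length(atms),
      enrichmentRows = if (is.null(report)) 0L else nrow(report@enrichment)),
    rVersion = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
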