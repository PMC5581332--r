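#' Specify a planted term-gene-TF block model
#'
#' Describes a ground-truth configuration for synthetic data: blocks of
#' term, gene, and TF indices that co-occur with a given intensity, plus
#' a background noise rate. Used by [synthTensor()] and [synthCorpus()]
#' so every pipeline stage can be validated offline against a known
#' answer.
#'
#' @param nTerms,nGenes,nTfs mode extents.
#' @param blocks list of blocks, each a list with integer index vectors
#'   \code{terms}, \code{genes}, \code{tfs} and a positive
#'   \code{intensity}.
#' @param noiseRate background/noise rate in [0, 1).
#' @param seed integer seed; all randomness in the generators flows from
#'   it through per-component offsets, so parts can be regenerated
#'   independently.
#' @return a validated planted-model list.
#' @export
plantedModel <- function(nTerms, nGenes, nTfs, blocks, noiseRate = 0,
                         seed = 1L) {
  stopifnot(nTerms >= 1, nGenes >= 1, nTfs >= 1,
            is.list(blocks), length(blocks) >= 1,
            noiseRate >= 0, noiseRate < 1)
  for (b in blocks) {
    stopifnot(all(c("terms", "genes", "tfs", "intensity") %in% names(b)),
              b$intensity > 0,
              all(b$terms >= 1 & b$terms <= nTerms),
              all(b$genes >= 1 & b$genes <= nGenes),
              all(b$tfs >= 1 & b$tfs <= nTfs))
  }
  structure(list(nTerms = as.integer(nTerms), nGenes = as.integer(nGenes),
                 nTfs = as.integer(nTfs), blocks = blocks,
                 noiseRate = noiseRate, seed = as.integer(seed)),
            class = "plantedModel")
}

.defaultLabels <- function(model) {
  list(terms = sprintf("term%04d", seq_len(model$nTerms)),
       genes = sprintf("g%04d", seq_len(model$nGenes)),
       tfs = sprintf("tf%03d", seq_len(model$nTfs)))
}

#' Synthesize a sparse tensor with planted blocks
#'
#' Builds the tensor sum_b intensity_b (1_terms o 1_genes o 1_tfs) over
#' the planted blocks, perturbs each planted entry multiplicatively by
#' uniform noise of amplitude \code{noiseRate} (factor in
#' 1 +/- noiseRate), and adds background entries (values uniform on
#' (0, 1)) at a fraction \code{noiseRate} of all cells. Deterministic
#' for a given model seed.
#'
#' @param model a [plantedModel()].
#' @return list with elements \code{tensor} (a
#'   [SparseTensor3-class] with generated axis labels) and
#'   \code{truth}: per-block label sets (terms, genes, tfs).
#' @export
synthTensor <- function(model) {
  stopifnot(inherits(model, "plantedModel"))
  lab <- .defaultLabels(model)
  d <- c(model$nTerms, model$nGenes, model$nTfs)

  parts <- lapply(model$blocks, function(b) {
    g <- expand.grid(i = b$terms, j = b$genes, k = b$tfs)
    cbind(as.matrix(g), value = b$intensity)
  })
  coords <- do.call(rbind, parts)

  .withSeed(model$seed, function() {
    vals <- coords[, "value"]
    if (model$noiseRate > 0) {
      vals <- vals * (1 + model$noiseRate *
                        runif(length(vals), -1, 1))
      nBg <- floor(model$noiseRate * prod(as.double(d)))
      if (nBg > 0) {
        cells <- sample(prod(as.double(d)), nBg)
        bg <- cbind(
          i = as.integer((cells - 1) %% d[1] + 1),
          j = as.integer(((cells - 1) %/% d[1]) %% d[2] + 1),
          k = as.integer((cells - 1) %/% (as.double(d[1]) * d[2]) + 1))
        coords <- rbind(coords[, 1:3, drop = FALSE], bg)
        vals <- c(vals, runif(nBg))
      } else {
        coords <- coords[, 1:3, drop = FALSE]
      }
    } else {
      coords <- coords[, 1:3, drop = FALSE]
    }
    x <- sparseTensor(coords[, 1], coords[, 2], coords[, 3], vals,
                      dims = d, labels = lab)
    truth <- lapply(model$blocks, function(b)
      list(terms = lab$terms[b$terms], genes = lab$genes[b$genes],
           tfs = lab$tfs[b$tfs], intensity = b$intensity))
    list(tensor = x, truth = truth)
  })
}

#' Synthesize a citation corpus with planted topic blocks
#'
#' Emulates the full raw-input surface: a gene -> PMID citation map,
#' abstract texts, a TF list, and a gold-standard gene-set collection
#' whose categories are the planted blocks. Every gene-TF pair within a
#' block shares \code{abstractsPerPair} citations whose bag-of-words
#' texts draw from the block's term vocabulary (synthetic "termXXXX"
#' tokens, so no stop-word collisions); at rate \code{noiseRate},
#' abstracts are contaminated with words from the global lexicon and
#' random cross-block gene-TF citations are added. Running
#' corpus -> tensor -> ntf -> extractATMs on the output recovers the
#' blocks.
#'
#' @param model a [plantedModel()].
#' @param wordsPerAbstract words drawn per abstract (default 30).
#' @param abstractsPerPair shared citations per within-block gene-TF
#'   pair (default 2).
#' @return list with \code{corpus} (a [CitationCorpus-class]),
#'   \code{geneSets} (a [GeneSetCollection-class]; one category per
#'   block, described by the block vocabulary), and \code{truth} as in
#'   [synthTensor()].
#' @export
synthCorpus <- function(model, wordsPerAbstract = 30L,
                        abstractsPerPair = 2L) {
  stopifnot(inherits(model, "plantedModel"))
  lab <- .defaultLabels(model)
  lexicon <- lab$terms

  .withSeed(model$seed + 1L, function() {
    geneToPmids <- list()
    abstracts <- character()
    pmid <- 0L
    addCite <- function(ent, id) {
      cur <- geneToPmids[[ent]]
      geneToPmids[[ent]] <<- c(cur, id)
    }
    for (bi in seq_along(model$blocks)) {
      b <- model$blocks[[bi]]
      vocab <- lexicon[b$terms]
      for (gj in b$genes) for (tk in b$tfs) {
        for (r in seq_len(abstractsPerPair)) {
          pmid <- pmid + 1L
          id <- as.character(pmid)
          words <- sample(vocab, wordsPerAbstract, replace = TRUE)
          if (model$noiseRate > 0) {
            nNoise <- rbinom(1, wordsPerAbstract, model$noiseRate)
            if (nNoise > 0)
              words <- c(words, sample(lexicon, nNoise, replace = TRUE))
          }
          abstracts[id] <- paste(words, collapse = " ")
          addCite(lab$genes[gj], id)
          addCite(lab$tfs[tk], id)
        }
      }
    }
    if (model$noiseRate > 0) {
      nCross <- round(model$noiseRate * pmid)
      for (r in seq_len(nCross)) {
        pmid <- pmid + 1L
        id <- as.character(pmid)
        abstracts[id] <- paste(
          sample(lexicon, wordsPerAbstract, replace = TRUE),
          collapse = " ")
        addCite(sample(lab$genes, 1), id)
        addCite(sample(lab$tfs, 1), id)
      }
    }

    corpus <- citationCorpus(geneToPmids,
                             tfIds = lab$tfs,
                             abstracts = abstracts,
                             provenance = sprintf(
                               "synthetic planted model, seed %d",
                               model$seed))
    truth <- lapply(model$blocks, function(b)
      list(terms = toupper(lab$terms)[b$terms],
           genes = toupper(lab$genes)[b$genes],
           tfs = toupper(lab$tfs)[b$tfs], intensity = b$intensity))
    universe <- toupper(c(lab$genes, lab$tfs))
    sets <- lapply(seq_along(model$blocks), function(bi) {
      b <- model$blocks[[bi]]
      list(name = sprintf("block%02d", bi),
           description = paste(lexicon[b$terms], collapse = " "),
           members = toupper(c(lab$genes[b$genes], lab$tfs[b$tfs])))
    })
    names(sets) <- sprintf("BLOCK%02d", seq_along(model$blocks))
    gsc <- geneSetCollection(sets, universe)
    list(corpus = corpus, geneSets = gsc, truth = truth)
  })
}

#' Write a synthetic corpus to the on-disk input formats
#'
#' Materializes the outputs of [synthCorpus()] as the raw file formats
#' the pipeline consumes: a gene2pubmed-style TSV, a JSON Lines
#' abstract store, a TF list, a stop-word list, and a GMT file of the
#' planted categories.
#'
#' @param synth result of [synthCorpus()].
#' @param dir output directory (created if needed).
#' @param stoplist stop words to write (default: bundled English list).
#' @return invisibly, the named vector of written paths.
#' @export
writeSyntheticInputs <- function(synth, dir,
                                 stoplist = defaultStoplist()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  corp <- synth$corpus
  paths <- c(gene2pubmed = file.path(dir, "gene2pubmed.tsv"),
             abstracts = file.path(dir, "abstracts.jsonl"),
             tfs = file.path(dir, "tfs.txt"),
             stoplist = file.path(dir, "stoplist.txt"),
             gmt = file.path(dir, "genesets.gmt"))
  long <- data.frame(
    tax_id = 10090L,
    GeneID = rep(names(corp@geneToPmids), lengths(corp@geneToPmids)),
    PubMed_ID = unlist(corp@geneToPmids, use.names = FALSE))
  writeLines(c("#tax_id\tGeneID\tPubMed_ID",
               sprintf("%d\t%s\t%s", long$tax_id, long$GeneID,
                       long$PubMed_ID)),
             paths["gene2pubmed"])
  writeLines(vapply(names(corp@abstracts), function(id)
    jsonlite::toJSON(list(pmid = id, title = "",
                          abstract = corp@abstracts[[id]]),
                     auto_unbox = TRUE),
    character(1)), paths["abstracts"])
  writeLines(corp@tfIds, paths["tfs"])
  writeLines(stoplist, paths["stoplist"])
  gsc <- synth$geneSets
  writeLines(vapply(names(gsc@sets), function(cid) {
    s <- gsc@sets[[cid]]
    paste(c(cid, s$description, s$members), collapse = "\t")
  }, character(1)), paths["gmt"])
  invisible(paths)
}
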