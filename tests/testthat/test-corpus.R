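test_that("citation filtering removes promiscuous PMIDs and is idempotent", {
  # 11 genes all citing one PMID: the PMID exceeds the threshold of 10
  # and every gene loses its only citation
  wide <- setNames(rep(list("1"), 11), paste0("g", 1:11))
  expect_length(filterCitations(wide, 10), 0)

  expect_identical(filterCitations(list(g1 = "1"), 10), list(g1 = "1"))
  expect_error(filterCitations(list()), "empty citation map")
  expect_error(filterCitations(list(g1 = "1"), maxGenesPerPmid = 0))

  # 5 PMIDs, one cited by 12 genes: exactly that PMID disappears
  set.seed(3)
  raw <- lapply(1:12, function(g)
    unique(c("100", sample(as.character(101:104), 2))))
  names(raw) <- paste0("g", 1:12)
  filt <- filterCitations(raw, 10)
  left <- unique(unlist(filt))
  expect_false("100" %in% left)
  expect_setequal(left, as.character(101:104))
  # brute-force check: every remaining PMID referenced by <= 10 genes
  cnt <- table(unlist(lapply(filt, unique)))
  expect_true(all(cnt <= 10))
  # idempotence
  expect_identical(filterCitations(filt, 10), filt)
})

test_that("pair documents are the gene x TF shared-citation pairs", {
  corp <- citationCorpus(
    list(g1 = c("1", "2"), tf1 = c("2", "3")), tfIds = "tf1",
    abstracts = c(`1` = "alpha", `2` = "beta", `3` = "gamma"))
  pd <- buildPairDocuments(corp)
  expect_equal(nrow(pd), 1)
  expect_equal(pd$gene, "G1")
  expect_equal(pd$tf, "TF1")
  expect_equal(pd$pmids[[1]], "2")
  expect_equal(pd$text, "beta")

  disj <- citationCorpus(list(g1 = "1", tf1 = "2"), tfIds = "tf1",
                         abstracts = c(`1` = "alpha", `2` = "beta"))
  expect_equal(nrow(buildPairDocuments(disj)), 0)

  noTf <- citationCorpus(list(g1 = "1"), tfIds = character(),
                         abstracts = c(`1` = "alpha"))
  expect_error(buildPairDocuments(noTf), "no TFs")
})

test_that("pair documents match a brute-force double loop on a random corpus", {
  set.seed(11)
  pool <- as.character(1:12)
  ents <- c(paste0("g", 1:6), "tf1", "tf2")
  cmap <- setNames(lapply(ents, function(e) sample(pool, 6)), ents)
  abst <- setNames(paste("text for abstract", pool), pool)
  corp <- citationCorpus(cmap, tfIds = c("tf1", "tf2"), abstracts = abst)
  pd <- buildPairDocuments(corp)

  expected <- list()
  for (g in toupper(paste0("g", 1:6))) for (tf in c("TF1", "TF2")) {
    shared <- intersect(corp@geneToPmids[[g]], corp@geneToPmids[[tf]])
    if (length(shared))
      expected[[paste(g, tf)]] <- sort(as.numeric(shared))
  }
  expect_equal(nrow(pd), length(expected))
  for (r in seq_len(nrow(pd))) {
    key <- paste(pd$gene[r], pd$tf[r])
    expect_equal(as.numeric(pd$pmids[[r]]), expected[[key]])
    # text is the concatenation in ascending PMID order
    expect_equal(pd$text[r],
                 paste(abst[as.character(expected[[key]])],
                       collapse = " "))
  }
  # deterministically sorted by (gene, tf)
  expect_false(is.unsorted(paste(pd$gene, pd$tf)))
})

test_that("tokenizer applies case, punctuation, length, and stop rules", {
  expect_equal(tokenize("Atoh1, a bHLH-domain factor!", stoplist = "a"),
               c("atoh1", "bhlh-domain", "factor"))
  expect_equal(tokenize("Go to it", stoplist = "to"), character())
  expect_equal(tokenize(""), character())
  expect_equal(tokenize("under_score kept"), c("under_score", "kept"))
  expect_equal(tokenize("-edge-hyphens- trimmed-"),
               c("edge-hyphens", "trimmed"))
  expect_equal(tokenize("123 4567", dropNumeric = TRUE), character())
  expect_equal(tokenize("123 4567"), c("123", "4567"))
})

test_that("tokenizer agrees with a character-walk oracle on long text", {
  set.seed(5)
  words <- c("Wnt/beta-catenin", "p53!", "it", "co-factor", "(gene)",
             "trans_activation", "RNA-seq;", "2,861", "a", "Atoh1")
  text <- paste(sample(words, 1000, replace = TRUE), collapse = " ")
  stop <- c("gene", "rna")
  expect_identical(tokenize(text, stoplist = stop),
                   tokenizeOracle(text, stoplist = stop))
})

test_that("term counting matches a dictionary-of-counts oracle", {
  one <- data.frame(gene = "G1", tf = "TF1", text = "wnt wnt notch",
                    stringsAsFactors = FALSE)
  ct <- countTerms(one)
  expect_equal(ct$vocabulary, c("notch", "wnt"))
  expect_equal(ct$entries$count[ct$entries$term == 2], 2)  # wnt
  expect_equal(ct$entries$count[ct$entries$term == 1], 1)  # notch

  expect_error(countTerms(data.frame()), "no pair documents")
  allEmpty <- data.frame(gene = "G1", tf = "TF1", text = "a b",
                         stringsAsFactors = FALSE)
  expect_error(countTerms(allEmpty), "empty vocabulary")

  # 10 synthetic pairs vs brute-force nested count
  set.seed(9)
  vocabPool <- sprintf("term%03d", 1:15)
  docs <- data.frame(
    gene = sprintf("G%d", rep(1:5, 2)),
    tf = sprintf("TF%d", rep(1:2, each = 5)),
    text = vapply(1:10, function(i)
      paste(sample(vocabPool, 25, replace = TRUE), collapse = " "),
      character(1)),
    stringsAsFactors = FALSE)
  ct <- countTerms(docs)
  for (r in seq_len(nrow(docs))) {
    toks <- strsplit(docs$text[r], " ")[[1]]
    ref <- table(toks)
    gi <- match(docs$gene[r], ct$genes)
    ti <- match(docs$tf[r], ct$tfs)
    sub <- ct$entries[ct$entries$gene == gi & ct$entries$tf == ti, ]
    expect_equal(nrow(sub), length(ref))
    expect_equal(sub$count[match(names(ref), ct$vocabulary[sub$term])],
                 as.integer(ref))
  }
  # every counted term occurs in that pair's tokenized text
  for (r in seq_len(nrow(ct$entries))) {
    e <- ct$entries[r, ]
    doc <- docs[docs$gene == ct$genes[e$gene] & docs$tf == ct$tfs[e$tf], ]
    expect_true(ct$vocabulary[e$term] %in% strsplit(doc$text, " ")[[1]])
  }
})

test_that("corpus construction drops dangling PMIDs and normalizes case", {
  expect_message(
    corp <- citationCorpus(list(a1 = c("1", "99")), tfIds = character(),
                           abstracts = c(`1` = "x")),
    "dropped 1")
  expect_equal(corp@geneToPmids$A1, "1")
  expect_true(validObject(corp))
})
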