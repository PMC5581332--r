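test_that("hypergeometric enrichment equals exhaustive enumeration", {
  # worked example: N=10, M=4, n_s=3, x=2 -> 40/120
  uni <- sprintf("e%02d", 1:10)
  categ <- uni[1:4]
  atm <- c(uni[1:2], uni[10])
  r <- hypergeomEnrich(atm, categ, uni)
  expect_equal(r$x, 2)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_equal(r$p, hyperOracle(10, 4, 3, 2), tolerance = 1e-12)

  # certain events
  expect_equal(hypergeomEnrich(uni[5], categ, uni)$p,
               hyperOracle(10, 4, 1, 0))
  full <- hypergeomEnrich(uni, uni, uni)
  expect_equal(full$p, 1)

  # full enumeration sweep for small universes
  for (N in c(6, 9, 12)) {
    uniN <- sprintf("u%02d", 1:N)
    for (M in c(1, floor(N / 2), N - 1)) {
      for (ns in c(1, 2, floor(N / 2))) {
        for (x in 0:min(M, ns)) {
          p <- hypergeomEnrich(uniN[seq_len(ns) + (N - ns)],
                               uniN[seq_len(M)], uniN)
          # compare the tail formula directly at each x
          expect_equal(
            stats::phyper(x - 1, M, N - M, ns, lower.tail = FALSE),
            hyperOracle(N, M, ns, x), tolerance = 1e-10,
            label = sprintf("N=%d M=%d ns=%d x=%d", N, M, ns, x))
        }
      }
    }
  }
  expect_error(hypergeomEnrich(character(), categ, uni), "empty ATM")
})

test_that("term AUC hits the documented anchors and the pair oracle", {
  ranked <- c(paste0("rel", 1:5), paste0("irr", 1:15))
  expect_equal(termAUC(ranked, paste0("rel", 1:5)), 1)
  expect_equal(termAUC(rev(ranked), paste0("rel", 1:5)), 0)
  expect_equal(termAUC(c("r", "n", "r2", "n2"), c("r", "r2")), 0.75)

  set.seed(41)
  for (rep in 1:10) {
    perm <- sample(ranked)
    expect_equal(termAUC(perm, paste0("rel", 1:5)),
                 aucOracle(perm, paste0("rel", 1:5)), tolerance = 1e-12)
  }
  # tied scores contribute half
  expect_equal(termAUC(c("r", "n"), "r", scores = c(1, 1)), 0.5)
  expect_warning(auc <- termAUC(c("a", "b"), character()), "undefined")
  expect_true(is.na(auc))
})

test_that("random-permutation AUC averages one half", {
  set.seed(1009)
  terms <- sprintf("t%02d", 1:50)
  rel <- terms[1:10]
  aucs <- replicate(2000, termAUC(sample(terms), rel))
  se <- stats::sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 1e-3)
})

test_that("precision is the gold-standard overlap fraction", {
  atm <- sprintf("m%02d", 1:10)
  expect_equal(atmPrecision(atm, c(atm, "extra")), 1)
  expect_equal(atmPrecision(atm, "other"), 0)
  expect_equal(atmPrecision(atm, atm[1:5]), 0.5)
  expect_error(atmPrecision(character(), "g"), "empty ATM")
  # relabeling invariance
  expect_equal(atmPrecision(paste0("x", atm), paste0("x", atm[1:5])), 0.5)
})

test_that("Welch right-tailed test behaves as the one-sided t", {
  s1 <- c(1, 2, 3, 4); s2 <- s1
  r <- welchRightTailed(s1, s2)
  expect_equal(r$t, 0)
  expect_equal(r$p, 0.5)

  set.seed(51)
  big <- rnorm(50, 10); small <- rnorm(50, 0)
  expect_lt(welchRightTailed(big, small)$p, 1e-10)
  fwd <- welchRightTailed(big, small)
  rev <- welchRightTailed(small, big)
  expect_equal(rev$t, -fwd$t, tolerance = 1e-12)
  expect_equal(rev$p, 1 - fwd$p, tolerance = 1e-12)
  # manual Welch formula oracle
  tManual <- (mean(big) - mean(small)) /
    sqrt(var(big) / 50 + var(small) / 50)
  expect_equal(fwd$t, tManual, tolerance = 1e-12)
  expect_error(welchRightTailed(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("Welch p-values are uniform under the null", {
  set.seed(61)
  ps <- replicate(400, welchRightTailed(rnorm(10), rnorm(10))$p)
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.001)
})

test_that("random control sets are reproducible and correctly sized", {
  gp <- sprintf("g%04d", 1:500); tp <- sprintf("f%03d", 1:50)
  a <- randomControlSets(gp, tp, reps = 5, seed = 99)
  b <- randomControlSets(gp, tp, reps = 5, seed = 99)
  expect_identical(a, b)
  expect_length(a, 5)
  expect_true(all(vapply(a, function(s)
    length(s$genes) == 8 && length(s$tfs) == 2 &&
      !anyDuplicated(s$genes), logical(1))))
  expect_error(randomControlSets(gp[1:3], tp), "pool smaller")
  # 1,000 sets of 8 + 2
  big <- randomControlSets(gp, tp, reps = 1000, seed = 1)
  expect_length(big, 1000)
  expect_true(all(lengths(lapply(big, unlist)) == 10))
})

test_that("matched controls mirror each ATM's size distribution", {
  syn <- synthTensor(twoBlockModel(noise = 0))
  atms <- extractATMs(ntf(syn$tensor, 2, tol = 1e-6))
  lab <- axisLabels(syn$tensor)
  ctrl <- matchedControlSets(atms, lab$genes, lab$tfs, repsPerAtm = 7,
                             seed = 3)
  expect_length(ctrl, 7 * length(atms))
  expect_equal(length(ctrl[[1]]$genes), nrow(atms[[1]]@genes))
  expect_equal(length(ctrl[[1]]$tfs), nrow(atms[[1]]@tfs))
})

test_that("control precision matches the sampling expectation", {
  set.seed(71)
  gp <- sprintf("g%04d", 1:300); tp <- sprintf("f%03d", 1:40)
  gold <- c(sample(gp, 60), sample(tp, 8))  # 20% of each pool
  ctrl <- randomControlSets(gp, tp, reps = 400, seed = 5)
  prec <- vapply(ctrl, function(s)
    atmPrecision(c(s$genes, s$tfs), gold), numeric(1))
  se <- stats::sd(prec) / sqrt(length(prec))
  expect_lt(abs(mean(prec) - 0.2), 3 * se + 0.005)
})

test_that("Jaccard redundancy is symmetric with the documented anchors", {
  expect_equal(jaccard(letters[1:8], letters[1:8]), 1)
  expect_equal(jaccard(letters[1:4], letters[5:8]), 0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  set.seed(81)
  for (r in 1:10) {
    s1 <- sample(letters, 6); s2 <- sample(letters, 9)
    expect_equal(jaccard(s1, s2), jaccard(s2, s1))
  }
  expect_error(jaccard(character(), character()), "both sets empty")
})

test_that("diversity coefficients are per-run union ratios", {
  mkAtm <- function(genes, k) {
    a <- new("ATM")
    a@componentIndex <- 1L; a@kOfRun <- as.integer(k); a@lambda <- 1
    df <- function(e) data.frame(entity = e,
                                 score = rev(seq_along(e)) * 1.0,
                                 stringsAsFactors = FALSE)
    a@terms <- df("t1"); a@genes <- df(genes); a@tfs <- df("f1")
    a@degenerate <- character()
    a
  }
  totals <- c(200, 100, 10)
  same <- list(mkAtm("g1", 2), mkAtm("g1", 2))
  expect_equal(diversityCoefficient(same, totals)[["genes"]], 0.01)
  part <- list(mkAtm(sprintf("g%d", 1:50), 2),
               mkAtm(sprintf("g%d", 51:100), 2))
  expect_equal(diversityCoefficient(part, totals)[["genes"]], 1)
  expect_warning(d <- diversityCoefficient(list(mkAtm("g1", 1)), totals),
                 "k < 2")
  expect_true(all(is.na(d)))
  # brute-force union on a planted run
  syn <- synthTensor(twoBlockModel(noise = 0))
  atms <- extractATMs(ntf(syn$tensor, 2, tol = 1e-6))
  d <- diversityCoefficient(atms, syn$tensor)
  bruteGenes <- length(unique(c(atms[[1]]@genes$entity,
                                atms[[2]]@genes$entity)))
  expect_equal(d[["genes"]], bruteGenes / 20)
})

test_that("guilt-by-association proposes unannotated members", {
  members <- sprintf("m%03d", 1:5)
  gsc <- geneSetCollection(
    list(CAT1 = list(name = "cat one", description = "alpha beta",
                     members = members[1:2])),
    universe = toupper(members))
  a <- new("ATM")
  a@componentIndex <- 1L; a@kOfRun <- 2L; a@lambda <- 1
  a@terms <- data.frame(entity = "alpha", score = 1)
  a@genes <- data.frame(entity = toupper(members[1:4]),
                        score = c(4, 3, 2, 1))
  a@tfs <- data.frame(entity = toupper(members[5]), score = 1)
  a@degenerate <- character()
  enr <- enrichATMs(list(a), gsc)
  preds <- gbaPredictions(list(a), enr, gsc, alpha = 1)  # force inclusion
  expect_setequal(preds$entity, toupper(members[3:5]))  # 5 members, 2 known
  # fully annotated module yields nothing
  gscFull <- geneSetCollection(
    list(CAT1 = list(name = "cat", description = "x",
                     members = c(toupper(members)))),
    universe = toupper(members))
  enrF <- enrichATMs(list(a), gscFull)
  expect_equal(nrow(gbaPredictions(list(a), enrF, gscFull, alpha = 1)), 0)
})

test_that("term mapping ranks categories by description overlap", {
  a <- new("ATM")
  a@componentIndex <- 1L; a@kOfRun <- 2L; a@lambda <- 1
  a@terms <- data.frame(entity = c("axon", "guidance", "migration"),
                        score = c(3, 2, 1))
  a@genes <- data.frame(entity = "G1", score = 1)
  a@tfs <- data.frame(entity = "F1", score = 1)
  a@degenerate <- character()
  gsc <- geneSetCollection(
    list(FULL = list(name = "axon guidance migration",
                     description = "axon guidance migration",
                     members = "G1"),
         PARTIAL = list(name = "cell migration",
                        description = "migration of cells", members = "G1"),
         NONE = list(name = "metabolism", description = "sugar flux",
                     members = "G1")),
    universe = c("G1", "F1"))
  preds <- termMappingPredictions(a, gsc)
  expect_equal(preds$category[1], "FULL")
  expect_equal(preds$overlap[1], 3)
  expect_false("NONE" %in% preds$category)
  # brute-force overlap ordering
  expect_equal(preds$overlap,
               sort(c(3, 1), decreasing = TRUE))
  # already-enriched categories are excluded
  enr <- data.frame(atm_id = 1L, run_k = 2L, category = "FULL",
                    p = 0.01)
  preds2 <- termMappingPredictions(a, gsc, enrichment = enr)
  expect_false("FULL" %in% preds2$category)
})

test_that("the evaluation report ties the statistics together", {
  syn <- synthCorpus(twoBlockModel(noise = 0.1))
  pairs <- buildPairDocuments(syn$corpus)
  x <- buildTensor(countTerms(pairs, stoplist = defaultStoplist()))
  atms <- extractATMs(ntf(x, 2, tol = 1e-6))
  gold <- syn$geneSets@sets[[1]]$members
  rep <- evaluateATMs(atms, syn$geneSets, tensor = x, gold = gold,
                      controlRepsPerAtm = 50, seed = 2)
  expect_s4_class(rep, "EvaluationReport")
  expect_equal(nrow(rep@enrichment), 2 * 2)
  expect_equal(nrow(rep@auc), 2)
  # planted vocabulary tops each module; when every module term belongs
  # to the gold vocabulary the AUC is undefined (NA) by design
  expect_true(all(is.na(rep@auc$auc) | rep@auc$auc > 0.9))
  expect_equal(nrow(rep@redundancy), 1)
  expect_lt(rep@redundancy$jaccard[1], 0.2) # disjoint planted blocks
  expect_equal(nrow(rep@precision), 2)
  expect_true(is.numeric(rep@precisionTest$p))
})
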