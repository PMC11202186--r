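mkGene <- function(v, genes, ids = paste0("s", seq_len(ncol(v)))) {
  dimnames(v) <- list(genes, ids)
  v
}

test_that("GMT round trip preserves sets and EGFR flags", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("PW_A\tdesc\tEGFR\tG1\tG2",
               "PW_B\tdesc\tG3\tG4"), f)
  db <- readGmt(f)
  expect_identical(names(pathwaySets(db)), c("PW_A", "PW_B"))
  expect_identical(unname(isEgfrRelated(db)), c(TRUE, FALSE))
  expect_identical(pathwaySets(db)$PW_B, c("G3", "G4"))
  db2 <- pathwayDB(pathwaySets(db), anchor = "G3")
  expect_identical(unname(isEgfrRelated(db2)), c(FALSE, TRUE))
})

test_that("gene-level aggregation averages transcripts per gene", {
  ann <- data.frame(transcript_id = c("T1", "T2", "T3"),
                    gene_symbol = c("G1", "G2", "G2"))
  z <- mkGene(rbind(c(5, 6), c(1, 0), c(3, 2)), c("T1", "T2", "T3"))
  g <- geneLevelValues(z, ann)
  expect_equal(g["G1", ], c(s1 = 5, s2 = 6))       # identity for 1:1
  expect_equal(unname(g["G2", "s1"]), 2)           # mean of 1 and 3
  # random multi-transcript table vs direct per-gene recomputation
  withr::local_seed(51)
  ann2 <- data.frame(transcript_id = paste0("T", 1:30),
                     gene_symbol = paste0("G", sample(1:10, 30,
                                                      replace = TRUE)))
  z2 <- mkGene(matrix(rnorm(30 * 4), 30), ann2$transcript_id)
  g2 <- geneLevelValues(z2, ann2)
  for (gn in rownames(g2)) {
    rows <- ann2$transcript_id[ann2$gene_symbol == gn]
    expect_equal(g2[gn, ], colMeans(z2[rows, , drop = FALSE]))
  }
})

test_that("path scores are means over present genes, linear, drop-invariant", {
  g <- mkGene(rbind(c(1, 2), c(-1, 4), c(10, 20)), c("G1", "G2", "G3"))
  s <- pathScore(g, c("G1", "G2"))
  expect_equal(as.numeric(s), c(0, 3))              # mean of (1,-1), (2,4)
  expect_equal(as.numeric(pathScore(g, "G3")), c(10, 20))  # single gene
  expect_equal(attr(pathScore(g, c("G1", "G2", "GX")), "coverage"), 2 / 3)
  # absent genes never change the score, only the coverage log
  expect_equal(as.numeric(pathScore(g, c("G1", "G2", "GX"))),
               as.numeric(s))
  # linearity in the gene values
  expect_equal(as.numeric(pathScore(3 * g, c("G1", "G2"))),
               3 * as.numeric(s))
  expect_true(all(is.na(pathScore(g, c("GX", "GY")))))
  # 5-gene random pathway equals a direct mean
  withr::local_seed(52)
  gm <- mkGene(matrix(rnorm(40), 8), paste0("G", 1:8))
  pw <- paste0("G", c(2, 3, 5, 7, 8))
  expect_equal(as.numeric(pathScore(gm, pw)),
               as.numeric(colMeans(gm[pw, ])))
})

test_that("pathway screen is calibrated under permuted labels", {
  withr::local_seed(53)
  nPw <- 400L
  scores <- matrix(rnorm(nPw * 30), nrow = nPw,
                   dimnames = list(sprintf("PW%03d", 1:nPw),
                                   paste0("s", 1:30)))
  db <- pathwayDB(setNames(as.list(sprintf("G%03d", 1:nPw)),
                           rownames(scores)))
  res <- pathwayGroupTest(scores, rep(c("a", "b"), 15), db, alpha = 0.01)
  fracAll <- res$fractions$fraction[res$fractions$subset == "all"]
  expect_lt(fracAll, 0.01 + 3 * sqrt(0.01 * 0.99 / nPw))
  # constant pathway is excluded from the denominator
  scores2 <- rbind(scores, PWCONST = rep(1, 30))
  db2 <- pathwayDB(c(pathwaySets(db), list(PWCONST = "GX")))
  res2 <- pathwayGroupTest(scores2, rep(c("a", "b"), 15), db2)
  expect_true(is.na(res2$table$p[res2$table$pathway == "PWCONST"]))
  expect_equal(res2$fractions$total[res2$fractions$subset == "all"],
               nPw)
})

test_that("planted EGFR pathway effects enrich the EGFR subset", {
  coh <- smokeCohort()
  cm <- smokeMatrix()
  ss <- as.data.frame(cohortSamples(coh))
  eg <- !is.na(ss$egfr_status)
  p <- fitNormalization(cm, ss$sample_id[eg])
  z <- applyNormalization(cm, p)[, eg, drop = FALSE]
  gm <- geneLevelValues(z, cohortTss(coh))
  db <- pathwayDB(coh@pathways)
  expect_identical(sort(names(pathwaySets(db))[isEgfrRelated(db)]),
                   sort(S4Vectors::metadata(cohortTruth(coh))$egfr_pathways))
  scores <- pathScoreMatrix(gm, db)
  res <- pathwayGroupTest(scores, ss$egfr_status[eg], db, alpha = 0.01)
  fr <- res$fractions
  expect_gt(fr$fraction[fr$subset == "egfr"],
            fr$fraction[fr$subset == "non_egfr"])
  expect_gte(fr$fraction[fr$subset == "egfr"], 0.5)
})

test_that("EGFR gene feature set honours overlap, alpha and ordering", {
  coh <- smokeCohort()
  cm <- smokeMatrix()
  ss <- as.data.frame(cohortSamples(coh))
  eg <- !is.na(ss$egfr_status)
  p <- fitNormalization(cm, ss$sample_id[eg])
  z <- applyNormalization(cm, p)[, eg, drop = FALSE]
  gm <- geneLevelValues(z, cohortTss(coh))
  db <- pathwayDB(coh@pathways)
  fs <- egfrFeatureSet(gm, db, ss$egfr_status[eg], alpha = 0.01)
  expect_true(all(fs$p < 0.01))
  expect_false(is.unsorted(fs$p))
  allGenes <- intersect(unique(unlist(
    pathwaySets(db)[isEgfrRelated(db)])), rownames(gm))
  # retained genes all belong to the EGFR pathway gene universe
  expect_true(all(fs$gene %in% allGenes))
  expect_gte(nrow(fs), 1)
  # alpha = 1 retains every overlapping, testable gene
  fsAll <- egfrFeatureSet(gm, db, ss$egfr_status[eg], alpha = 1)
  expect_equal(nrow(fsAll), length(allGenes))
  # no overlap: empty result with a warning
  dbNone <- pathwayDB(list(PW = c("ZZZ0", "ZZZ1")), anchor = "ZZZ0")
  expect_warning(fs0 <- egfrFeatureSet(gm, dbNone,
                                       ss$egfr_status[eg]), "overlap")
  expect_equal(nrow(fs0), 0)
})

test_that("a planted 3-sd gene shift is always retained at n = 29/36", {
  withr::local_seed(54)
  labels <- rep(c("positive", "wild-type"), c(29, 36))
  gm <- rbind(
    matrix(rnorm(10 * 65), nrow = 10),                    # null genes
    cbind(matrix(rnorm(10 * 29, mean = 3), nrow = 10),    # planted shift
          matrix(rnorm(10 * 36), nrow = 10)))
  dimnames(gm) <- list(c(paste0("N", 1:10), paste0("P", 1:10)),
                       paste0("s", 1:65))
  db <- pathwayDB(list(PW_EGFR = c("EGFR", rownames(gm))))
  fs <- egfrFeatureSet(gm, db, labels, alpha = 0.01)
  expect_true(all(paste0("P", 1:10) %in% fs$gene))
})

test_that("multi-transcript genes flow through gene-level averaging", {
  coh <- simulateCohort(simConfig(
    nTss = 120L, nHealthy = 4L,
    nCancerPerStage = c(I = 1L, II = 1L, III = 1L, IV = 1L),
    nInformativeUp = 10L, nInformativeDown = 10L,
    nPathways = 4L, nEgfrPathways = 1L, genesPerPathway = 5L,
    transcriptsPerGene = 3L, seed = 19L))
  ann <- as.data.frame(cohortTss(coh))
  expect_lt(length(unique(ann$gene_symbol)), nrow(ann))
  sizes <- table(ann$gene_symbol)
  expect_true(all(sizes >= 1 & sizes <= 3))
  cm <- buildCoverageMatrix(cohortFragments(coh), coh)
  z <- applyNormalization(cm, fitNormalization(
    cm, cohortSamples(coh)$sample_id))
  gm <- geneLevelValues(z, cohortTss(coh))
  expect_equal(nrow(gm), length(unique(ann$gene_symbol)))
  g3 <- names(sizes)[sizes == 3][1]
  trs <- ann$transcript_id[ann$gene_symbol == g3]
  expect_equal(gm[g3, ], colMeans(z[trs, ]))
})

test_that("the EGFR-status classifier trains end to end on cohort genes", {
  coh <- smokeCohort()
  cm <- smokeMatrix()
  ss <- as.data.frame(cohortSamples(coh))
  eg <- which(!is.na(ss$egfr_status))
  ids <- ss$sample_id[eg]
  sp <- stratifiedSplit(ids, ss$egfr_status[eg], seed = 20L)
  p <- fitNormalization(cm, sp$train)
  z <- applyNormalization(cm, p)
  gm <- geneLevelValues(z, cohortTss(coh))
  db <- pathwayDB(coh@pathways)
  trLab <- ss$egfr_status[match(sp$train, ss$sample_id)]
  fs <- egfrFeatureSet(gm[, sp$train, drop = FALSE], db, trLab,
                       alpha = 0.05)
  expect_gte(nrow(fs), 2)
  b <- suppressWarnings(trainRf(gm[fs$gene, sp$train, drop = FALSE],
                                trLab, positive = "positive",
                                nTrees = 2500L,
                                mtry = min(5L, nrow(fs)),
                                folds = 10L, repeats = 3L, seed = 21L))
  expect_identical(b@settings$nTrees, 2500L)
  vaLab <- ss$egfr_status[match(sp$validation, ss$sample_id)]
  ev <- evaluateRoc(b, gm[, sp$validation, drop = FALSE], vaLab)
  expect_true(ev$overall$auc >= 0 && ev$overall$auc <= 1)
  expect_true(ev$overall$ciLow <= ev$overall$auc &&
              ev$overall$ciHigh >= ev$overall$auc)
})
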