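named <- function(m) {
  dimnames(m) <- list(sprintf("T%03d", seq_len(nrow(m))),
                      paste0("s", seq_len(ncol(m))))
  m
}

test_that("near-zero-variance rule matches direct ratio computations", {
  withr::local_seed(41)
  z <- named(rbind(rep(1, 100),                 # constant -> dropped
                   rnorm(100),                  # continuous -> kept
                   c(rep(0, 97), rep(1, 3))))   # ratio 32.3 > 19 -> dropped
  expect_equal(97 / 3, 32.33, tolerance = 1e-3)
  keep <- filterNearZeroVariance(z)
  expect_identical(keep, "T002")
  # caret flags the same pathological rows on this example
  nz <- caret::nearZeroVar(t(z))
  expect_setequal(rownames(z)[nz], c("T001", "T003"))
  # a discrete feature with < 10% distinct values falls to uniqueCut
  z2 <- named(matrix(rep(c(1, 2, 3), length.out = 100), nrow = 1))
  expect_identical(filterNearZeroVariance(z2), character(0))
  expect_identical(filterNearZeroVariance(z2, uniqueCut = 0.01), "T001")
})

test_that("correlation pruning keeps one of a duplicated pair", {
  withr::local_seed(42)
  base <- rnorm(50)
  z <- named(rbind(base, base, rnorm(50)))
  surv <- filterHighCorrelation(z, 0.9)
  expect_length(surv, 2)
  expect_true("T003" %in% surv)
  expect_length(intersect(c("T001", "T002"), surv), 1)
  # independent columns all survive
  zi <- named(matrix(rnorm(5 * 200), nrow = 5))
  expect_identical(filterHighCorrelation(zi, 0.9), rownames(zi))
})

test_that("three-column pruning matches an exhaustive application of the rule", {
  withr::local_seed(43)
  a <- rnorm(200)
  b <- a + rnorm(200, sd = 0.1)         # |r(a,b)| ~ 0.995
  c3 <- 0.5 * a + rnorm(200, sd = 1)    # moderate correlation with a only
  z <- named(rbind(a, b, c3))
  # oracle: re-apply the written rule by hand on the 3x3 matrix
  r <- abs(cor(t(z))); diag(r) <- 0
  worst <- which(r == max(r), arr.ind = TRUE)[1, ]
  mi <- mean(r[worst[1], ]); mj <- mean(r[worst[2], ])
  dropOracle <- rownames(z)[if (mi > mj) worst[1] else worst[2]]
  surv <- filterHighCorrelation(z, 0.9)
  expect_identical(surv, setdiff(rownames(z), dropOracle))
  # caret agrees on which member of the worst pair must fall
  expect_identical(rownames(z)[caret::findCorrelation(cor(t(z)), 0.9)],
                   dropOracle)
})

test_that("group screen is calibrated under the null and powered under shift", {
  withr::local_seed(44)
  nFeat <- 2000L
  z <- named(matrix(rnorm(nFeat * 40), nrow = nFeat))
  labels <- rep(c("a", "b"), each = 20)   # labels independent of data
  scr <- groupDifferenceScreen(z, labels, alpha = 0.01)
  frac <- mean(scr$keep)
  se <- sqrt(0.01 * 0.99 / nFeat)
  expect_lt(abs(frac - 0.01), 3 * se + 1e-9)
  # planted 3-sd shift, n = 30/30: essentially always retained
  z2 <- named(cbind(matrix(rnorm(50 * 30), nrow = 50),
                    matrix(rnorm(50 * 30, mean = 3), nrow = 50)))
  scr2 <- groupDifferenceScreen(z2, rep(c("a", "b"), each = 30))
  expect_gte(mean(scr2$keep), 0.98)
  # constant feature: p undefined, excluded
  z3 <- named(matrix(1, nrow = 1, ncol = 40))
  scr3 <- groupDifferenceScreen(z3, labels)
  expect_true(is.na(scr3$p[1]))
  expect_false(scr3$keep[1])
  expect_error(groupDifferenceScreen(z, rep(c("a", "b"), c(38, 2))),
               "at least 3")
})

test_that("monotone classification follows strict five-group ordering", {
  groupsOf <- function(n) list(labels = rep(c("healthy", "cancer"),
                                            c(n, 4 * n)),
                               stages = c(rep(NA, n),
                                          rep(c("I", "II", "III", "IV"),
                                              each = n)))
  g <- groupsOf(2)
  mk <- function(means) named(matrix(rep(means, each = 2), nrow = 1))
  up <- mk(c(1, 2, 3, 4, 5))
  none <- mk(c(1, 2, 1.5, 3, 4))
  down <- mk(c(5, 4, 3, 2, 1))
  z <- rbind(up, none, down)
  rownames(z) <- c("Tup", "Tnone", "Tdown")
  panel <- selectStageMonotone(z, g$labels, g$stages, kPerDirection = 5)
  pd <- panelDirection(panel)
  expect_identical(unname(as.character(pd["Tup"])), "cancer_up")
  expect_identical(unname(as.character(pd["Tdown"])), "healthy_up")
  expect_false("Tnone" %in% panelTranscripts(panel))
  expect_error(selectStageMonotone(z, rep("healthy", 10),
                                   rep(NA, 10)), "empty group")
})

test_that("ranking uses |stage I - healthy| with lexicographic tie-break", {
  g <- list(labels = rep(c("healthy", "cancer"), c(1, 4)),
            stages = c(NA, "I", "II", "III", "IV"))
  z <- rbind(Tb = c(0, 3, 4, 5, 6),   # score 3
             Ta = c(0, 3, 3.5, 5, 6), # score 3, tie with Tb
             Tc = c(0, 1, 2, 3, 4))   # score 1
  colnames(z) <- paste0("s", 1:5)
  panel <- selectStageMonotone(z, g$labels, g$stages, kPerDirection = 2)
  expect_identical(panelTranscripts(panel), c("Ta", "Tb"))
  full <- selectStageMonotone(z, g$labels, g$stages, kPerDirection = 3)
  expect_identical(panelTranscripts(full), c("Ta", "Tb", "Tc"))
  expect_identical(full@precut$cancer_up, c("Ta", "Tb", "Tc"))
  # determinism: identical input, identical panel
  expect_identical(panelTable(panel), panelTable(
    selectStageMonotone(z, g$labels, g$stages, kPerDirection = 2)))
})

test_that("the filter chain recovers planted features on synthetic truth", {
  coh <- smokeCohort()
  cm <- smokeMatrix()
  ss <- as.data.frame(cohortSamples(coh))
  p <- fitNormalization(cm, ss$sample_id)
  z <- applyNormalization(cm, p)
  panel <- selectFeatures(z, ss$label, ss$stage, kPerDirection = 40)
  truth <- as.data.frame(cohortTruth(coh))
  rec <- mean(panelTranscripts(panel) %in% truth$transcript_id)
  expect_gte(rec, 0.8)
  counts <- attr(panel, "filterCounts")
  expect_true(all(diff(counts) <= 0))   # each step only removes features
  # direction agreement with the planted truth
  pd <- panelDirection(panel)
  hits <- intersect(names(pd), truth$transcript_id)
  expect_true(all(as.character(pd[hits]) ==
                  truth$direction[match(hits, truth$transcript_id)]))
})

test_that("panels survive a TSV round trip", {
  z <- rbind(Tb = c(0, 3, 4, 5, 6), Ta = c(0, 2, 3, 4, 5))
  colnames(z) <- paste0("s", 1:5)
  panel <- selectStageMonotone(z, rep(c("healthy", "cancer"), c(1, 4)),
                               c(NA, "I", "II", "III", "IV"),
                               kPerDirection = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeFeaturePanel(panel, f)
  p2 <- readFeaturePanel(f)
  expect_identical(panelTable(panel), panelTable(p2))
})
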