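# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# a mid-sized cohort with clear planted structure, reused across files
smokeCohort <- function() cached("smoke", {
  simulateCohort(simConfig(
    nTss = 300L, nHealthy = 20L,
    nCancerPerStage = c(I = 5L, II = 5L, III = 5L, IV = 5L),
    nInformativeUp = 40L, nInformativeDown = 40L,
    nPathways = 20L, nEgfrPathways = 4L, genesPerPathway = 10L,
    seed = 11L))
})

smokeMatrix <- function() cached("smoke_cm", {
  coh <- smokeCohort()
  buildCoverageMatrix(cohortFragments(coh), coh)
})

# write SAM lines (already including header) to a sorted, indexed BAM
samToBam <- function(lines, dir = withr::local_tempdir(.local_envir =
                                                         parent.frame())) {
  sam <- file.path(dir, "in.sam")
  writeLines(lines, sam)
  raw <- Rsamtools::asBam(sam, file.path(dir, "raw"),
                          indexDestination = FALSE)
  dest <- file.path(dir, "reads")
  Rsamtools::sortBam(raw, dest)
  Rsamtools::indexBam(paste0(dest, ".bam"))
  paste0(dest, ".bam")
}

samHeader <- function(chromLen = 100000L, so = "coordinate")
  c(paste0("@HD\tVN:1.6\tSO:", so),
    paste0("@SQ\tSN:chrS\tLN:", chromLen))

# one proper read pair spanning [pos, pos + tlen), 0-based start given 1-based
samPair <- function(qname, pos, tlen, mapq = 60L, extraFlag = 0L,
                    readLen = 50L) {
  e2 <- pos + tlen - readLen
  seq <- strrep("A", readLen)
  cig <- paste0(readLen, "M")
  c(paste(qname, 99L + extraFlag, "chrS", pos, mapq, cig, "=", e2, tlen,
          seq, "*", sep = "\t"),
    paste(qname, 147L + extraFlag, "chrS", e2, mapq, cig, "=", pos, -tlen,
          seq, "*", sep = "\t"))
}

# independent AUC oracle: exhaustive pair counting (ties = 1/2)
pairCountAuc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# naive per-base depth of 1-based closed fragment intervals over [1, len]
naiveDepth <- function(starts, ends, len) {
  d <- numeric(len)
  for (k in seq_along(starts))
    for (b in seq(max(1, starts[k]), min(len, ends[k]))) d[b] <- d[b] + 1
  d
}
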