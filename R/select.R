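#' Two-group per-transcript screen
#'
#' Per-transcript two-sided rank-sum (default) or Welch t-test between two
#' groups on the normalized matrix; features with p below `alpha` are
#' retained. The rank-sum default is deliberate: TSS relative-coverage
#' ratios are right-skewed and a distribution-free test is robust to that.
#' No multiple-testing correction is applied; the screen reports the
#' retained count and raw p-values.
#'
#' @param z normalized matrix (features x samples).
#' @param labels two-level factor/character vector along columns.
#' @param alpha retention threshold on the raw p-value (default 0.01).
#' @param test `"wilcoxon"` (default) or `"welch"`.
#' @return a `DataFrame` with `feature`, `p`, `keep`, plus per-group means;
#'   constant features get `p = NA` and are excluded.
#' @export
groupDifferenceScreen <- function(z, labels, alpha = 0.01,
                                  test = c("wilcoxon", "welch")) {
  test <- match.arg(test)
  g <- factor(labels)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  if (any(table(g) < 3L)) stop("each group needs at least 3 samples")
  a <- z[, g == levels(g)[1], drop = FALSE]
  b <- z[, g == levels(g)[2], drop = FALSE]
  p <- vapply(seq_len(nrow(z)), function(i) {
    xi <- a[i, ]; yi <- b[i, ]
    if (length(unique(c(xi, yi))) < 2L) return(NA_real_)
    if (test == "wilcoxon")
      suppressWarnings(stats::wilcox.test(xi, yi, exact = FALSE)$p.value)
    else
      stats::t.test(xi, yi)$p.value
  }, numeric(1))
  S4Vectors::DataFrame(
    feature = rownames(z), p = p,
    mean_1 = rowMeans(a), mean_2 = rowMeans(b),
    keep = !is.na(p) & p < alpha)
}

#' Near-zero-variance filter
#'
#' Drops features whose most-common / second-most-common value frequency
#' ratio exceeds `freqCut`, or whose fraction of distinct values falls below
#' `uniqueCut`; constant features always fall.
#'
#' @param z matrix (features x samples).
#' @param freqCut frequency-ratio threshold (default 19, i.e. 95/5).
#' @param uniqueCut minimum distinct-value fraction (default 0.1).
#' @return surviving feature names, in input order.
#' @export
filterNearZeroVariance <- function(z, freqCut = 19, uniqueCut = 0.1) {
  n <- ncol(z)
  keep <- vapply(seq_len(nrow(z)), function(i) {
    tab <- sort(tabulate(factor(z[i, ])), decreasing = TRUE)
    if (length(tab) < 2L) return(FALSE)
    ratio <- tab[1] / tab[2]
    uniq <- length(tab) / n
    ratio <= freqCut && uniq >= uniqueCut
  }, logical(1))
  rownames(z)[keep]
}

#' Greedy high-correlation filter
#'
#' While any absolute pairwise Pearson correlation exceeds `cutoff`, the
#' member of the worst (largest |r|) pair with the larger mean absolute
#' correlation is dropped; ties fall to the lexicographically later feature
#' name, making the survivor set fully deterministic.
#'
#' @param z matrix (features x samples).
#' @param cutoff absolute correlation threshold (default 0.9).
#' @return surviving feature names, in input order.
#' @export
filterHighCorrelation <- function(z, cutoff = 0.9) {
  if (nrow(z) < 2L) return(rownames(z))
  r <- abs(stats::cor(t(z)))
  r[is.na(r)] <- 0
  diag(r) <- 0
  alive <- rep(TRUE, nrow(z))
  repeat {
    mx <- max(r)
    if (mx <= cutoff) break
    hit <- which(r == mx, arr.ind = TRUE)[1, ]   # deterministic: first pair
    i <- hit[["row"]]; j <- hit[["col"]]
    mi <- mean(r[i, alive]); mj <- mean(r[j, alive])
    drop <- if (mi > mj) i
            else if (mj > mi) j
            else if (rownames(z)[i] > rownames(z)[j]) i else j
    alive[drop] <- FALSE
    r[drop, ] <- 0
    r[, drop] <- 0
  }
  rownames(z)[alive]
}

#' Stage-monotone feature selection
#'
#' Classifies each feature by the ordering of its five group means (healthy,
#' stage I, II, III, IV) as strictly increasing (`cancer_up`), strictly
#' decreasing (`healthy_up`), or neither; ranks each monotone class by the
#' absolute stage-I-minus-healthy mean difference, descending, ties broken
#' by feature name; and returns the top `kPerDirection` per class. The
#' top-`kPrecut` pre-cut per class is kept as an intermediate artifact.
#'
#' @param z normalized matrix (features x samples).
#' @param labels `"healthy"` / `"cancer"` along columns.
#' @param stages stage per column (`I`..`IV` for cancer, `NA` for healthy).
#' @param kPerDirection panel size per direction class (default 100).
#' @param kPrecut pre-cut size per direction class (default 200).
#' @return a [FeaturePanel-class].
#' @export
selectStageMonotone <- function(z, labels, stages, kPerDirection = 100L,
                                kPrecut = 200L) {
  groups <- ifelse(labels == "healthy", "healthy", as.character(stages))
  lev <- c("healthy", "I", "II", "III", "IV")
  sizes <- table(factor(groups, levels = lev))
  if (any(sizes == 0L))
    stop("empty group(s): ", paste(lev[sizes == 0L], collapse = ", "),
         ". Merge or drop stages explicitly before selection.")
  means <- vapply(lev, function(gp)
    rowMeans(z[, groups == gp, drop = FALSE]), numeric(nrow(z)))
  if (!is.matrix(means))
    means <- matrix(means, nrow = nrow(z),
                    dimnames = list(rownames(z), lev))
  d <- t(apply(means, 1L, diff))
  up <- rowSums(d > 0) == 4L
  down <- rowSums(d < 0) == 4L
  score <- abs(means[, "I"] - means[, "healthy"])
  pick <- function(sel, k) {
    ids <- rownames(z)[sel]
    ids[order(-score[sel], ids)][seq_len(min(k, length(ids)))]
  }
  upIds <- pick(up, kPerDirection)
  downIds <- pick(down, kPerDirection)
  panel <- c(upIds, downIds)
  methods::new("FeaturePanel",
    transcripts = panel,
    direction = factor(rep(c("cancer_up", "healthy_up"),
                           c(length(upIds), length(downIds))),
                       levels = c("cancer_up", "healthy_up")),
    score = score[panel],
    precut = list(cancer_up = pick(up, kPrecut),
                  healthy_up = pick(down, kPrecut)),
    groupMeans = t(means[panel, , drop = FALSE]))
}

#' Full feature-reduction chain
#'
#' Applies, in order: near-zero-variance filter, greedy high-correlation
#' filter, two-group p-value screen (cancer vs healthy, p < `alpha`), and
#' stage-monotone top-k selection. The order is cheapest-first; each step
#' only ever removes features.
#'
#' @inheritParams selectStageMonotone
#' @inheritParams groupDifferenceScreen
#' @param corCutoff threshold for [filterHighCorrelation()].
#' @param freqCut,uniqueCut thresholds for [filterNearZeroVariance()].
#' @return a [FeaturePanel-class]; the per-step survivor counts are attached
#'   as `attr(panel, "filterCounts")`.
#' @export
selectFeatures <- function(z, labels, stages, alpha = 0.01,
                           corCutoff = 0.9, kPerDirection = 100L,
                           kPrecut = 200L, freqCut = 19, uniqueCut = 0.1,
                           test = c("wilcoxon", "welch")) {
  counts <- c(input = nrow(z))
  keep <- filterNearZeroVariance(z, freqCut, uniqueCut)
  counts["near_zero_variance"] <- length(keep)
  z <- z[keep, , drop = FALSE]
  keep <- filterHighCorrelation(z, corCutoff)
  counts["high_correlation"] <- length(keep)
  z <- z[keep, , drop = FALSE]
  scr <- groupDifferenceScreen(z, labels, alpha, test)
  z <- z[scr$keep, , drop = FALSE]
  counts["p_screen"] <- nrow(z)
  panel <- selectStageMonotone(z, labels, stages, kPerDirection, kPrecut)
  counts["panel"] <- length(panelTranscripts(panel))
  attr(panel, "filterCounts") <- counts
  panel
}

#' Write a feature panel as TSV
#'
#' @param panel a [FeaturePanel-class].
#' @param file output path (columns transcript_id, direction, rank_score).
#' @export
writeFeaturePanel <- function(panel, file) {
  data.table::fwrite(panelTable(panel), file, sep = "\t")
  invisible(file)
}

#' @rdname writeFeaturePanel
#' @export
readFeaturePanel <- function(file) {
  tb <- data.table::fread(file)
  methods::new("FeaturePanel",
    transcripts = tb$transcript_id,
    direction = factor(tb$direction,
                       levels = c("cancer_up", "healthy_up")),
    score = as.numeric(tb$rank_score), precut = list(),
    groupMeans = matrix(numeric(), 0, 0))
}
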