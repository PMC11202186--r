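#' Stratified 70/30 cohort split with per-stratum ceiling rounding
#'
#' Within every stratum of size n, exactly `ceiling(trainFraction * n)`
#' samples are assigned to training, uniformly at random under the seed.
#' The ceiling rule is the convention of caret's `createDataPartition` and
#' is the only rounding that reproduces the reference cohort partitions:
#' (96 cancer, 100 healthy) -> 68 + 70 = 138 training / 58 validation, and
#' (29 positive, 36 wild-type) -> 21 + 26 = 47 training / 18 validation.
#'
#' @param ids sample ids.
#' @param strata stratification label per id (e.g. class).
#' @param trainFraction fraction assigned to training (default 0.7).
#' @param seed integer seed.
#' @return `list(train =, validation =)` of disjoint, exhaustive id sets.
#' @examples
#' sp <- stratifiedSplit(paste0("s", 1:196),
#'                       rep(c("cancer", "healthy"), c(96, 100)), seed = 1)
#' lengths(sp)  # 138, 58
#' @export
stratifiedSplit <- function(ids, strata, trainFraction = 0.7, seed = 1L) {
  stopifnot(length(ids) == length(strata), !anyDuplicated(ids),
            trainFraction > 0, trainFraction < 1)
  train <- withr::with_seed(seed, {
    unlist(lapply(split(ids, strata), function(s) {
      nTr <- ceiling(trainFraction * length(s))
      if (nTr == length(s))
        warning("a stratum of size ", length(s),
                " leaves no validation samples")
      sample(s, nTr)
    }), use.names = FALSE)
  })
  list(train = ids[ids %in% train],
       validation = ids[!ids %in% train])
}

# Mann-Whitney concordance AUC (ties count 1/2); used for CV fold summaries
.concordanceAuc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# stratified fold assignment: within each class, shuffled samples are dealt
# round-robin into folds
.foldAssignment <- function(labels, folds) {
  f <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Train a random-forest classifier with repeated cross-validation
#'
#' Fits a forest on the full training data and, separately, estimates
#' prediction error by repeated stratified k-fold cross-validation with the
#' same fixed hyperparameters (model assessment only -- the final model is
#' the full-data fit). The predictor score is the forest's probability of
#' the positive class.
#'
#' @param x feature matrix (features x samples), already normalized with
#'   training-only parameters.
#' @param labels two-level class vector along columns.
#' @param positive label of the positive class (default: second level, or
#'   `"cancer"`/`"positive"` when present).
#' @param nTrees,mtry forest hyperparameters (reference settings: 1500/1 for
#'   cancer screening, 2500/5 for EGFR status).
#' @param folds,repeats cross-validation plan (default 10-fold, 3 repeats);
#'   folds are reduced with a warning when the smaller class is smaller than
#'   `folds`. `repeats = 0` skips CV.
#' @param seed integer seed controlling fold assignment and the forests.
#' @return a [ModelBundle-class].
#' @export
trainRf <- function(x, labels, positive = NULL, nTrees = 1500L, mtry = 1L,
                    folds = 10L, repeats = 3L, seed = 1L) {
  stopifnot(is.matrix(x), ncol(x) == length(labels))
  g <- factor(labels)
  if (nlevels(g) < 2L) stop("need two classes to train")
  if (is.null(positive))
    positive <- if ("cancer" %in% levels(g)) "cancer"
                else if ("positive" %in% levels(g)) "positive"
                else levels(g)[2]
  stopifnot(positive %in% levels(g))
  stopifnot(mtry >= 1L, mtry <= nrow(x), nTrees >= 1L)
  minClass <- min(table(g))
  if (repeats > 0L && minClass < folds) {
    warning("smallest class has ", minClass, " samples; reducing CV folds ",
            folds, " -> ", minClass)
    folds <- minClass
  }
  xt <- t(x)
  cv <- data.frame()
  withr::with_seed(seed, {
    if (repeats > 0L) {
      cv <- do.call(rbind, lapply(seq_len(repeats), function(r) {
        fa <- .foldAssignment(as.character(g), folds)
        auc <- vapply(seq_len(folds), function(k) {
          tr <- fa != k
          fit <- randomForest::randomForest(
            xt[tr, , drop = FALSE], g[tr], ntree = nTrees, mtry = mtry)
          sc <- stats::predict(fit, xt[!tr, , drop = FALSE],
                               type = "prob")[, positive]
          .concordanceAuc(sc, as.character(g)[!tr], positive)
        }, numeric(1))
        data.frame(repeat_ = r, fold = seq_len(folds), auc = auc)
      }))
    }
    forest <- randomForest::randomForest(xt, g, ntree = nTrees, mtry = mtry)
  })
  methods::new("ModelBundle", forest = forest, featureIds = rownames(x),
               positive = positive, trainIds = colnames(x),
               cv = cv[!is.na(cv$auc), , drop = FALSE],
               settings = list(nTrees = nTrees, mtry = mtry, folds = folds,
                               repeats = repeats, seed = seed))
}

#' Predictor scores of a fitted model on new samples
#'
#' @param bundle a [ModelBundle-class].
#' @param x feature matrix (features x samples) normalized with the same
#'   frozen training parameters.
#' @return named numeric vector of positive-class probabilities.
#' @export
predictScores <- function(bundle, x) {
  miss <- setdiff(bundle@featureIds, rownames(x))
  if (length(miss))
    stop("matrix lacks ", length(miss), " model feature(s), e.g. ",
         miss[1])
  sc <- stats::predict(bundle@forest,
                       t(x[bundle@featureIds, , drop = FALSE]),
                       type = "prob")[, bundle@positive]
  stats::setNames(as.numeric(sc), colnames(x))
}

#' ROC evaluation of a model on a held-out cohort
#'
#' Computes the ROC curve, trapezoid AUC and DeLong 95% CI of the bundle's
#' predictor scores on an evaluation cohort that must be disjoint from the
#' training ids (enforced -- evaluating on a training sample is an error,
#' not a warning). Optional subgroups (e.g. early stage I/II vs advanced
#' III/IV) restrict the cases to the subgroup while keeping all controls.
#'
#' @param bundle a [ModelBundle-class].
#' @param x feature matrix (features x samples) of the evaluation cohort.
#' @param labels two-level class vector along columns.
#' @param subgroups optional named list of case sample-id subsets.
#' @return list with one element per cohort/subgroup: `roc` (data.frame
#'   fpr/tpr), `auc`, `ciLow`, `ciHigh`, `nCases`, `nControls`.
#' @export
evaluateRoc <- function(bundle, x, labels, subgroups = NULL) {
  leaked <- intersect(colnames(x), bundle@trainIds)
  if (length(leaked))
    stop("evaluation cohort overlaps training ids (", length(leaked),
         " sample(s), e.g. ", leaked[1], ")")
  scores <- predictScores(bundle, x)
  g <- as.character(labels)
  pos <- bundle@positive
  neg <- setdiff(unique(g), pos)
  if (length(neg) != 1L) stop("labels must contain the positive class and ",
                              "exactly one other class")
  out <- list(overall = .rocOne(scores, g, pos, neg))
  for (nm in names(subgroups)) {
    caseIds <- intersect(subgroups[[nm]], names(scores)[g == pos])
    if (length(caseIds) == 0L) {
      warning("subgroup '", nm, "' has no cases in this cohort; skipped")
      next
    }
    keep <- g != pos | names(scores) %in% caseIds
    out[[nm]] <- .rocOne(scores[keep], g[keep], pos, neg)
  }
  out
}

#' ROC, AUC and DeLong CI from raw predictor scores
#'
#' Threshold-sweep ROC with trapezoid AUC (which, with ties counted 1/2,
#' equals the Mann-Whitney concordance probability) and a DeLong 95% CI.
#' [evaluateRoc()] is a convenience wrapper around this for fitted models.
#'
#' @param scores numeric predictor scores.
#' @param labels class per score.
#' @param positive positive class label.
#' @return list: `roc` (data.frame fpr/tpr), `auc`, `ciLow`, `ciHigh`,
#'   `nCases`, `nControls`.
#' @export
scoreRoc <- function(scores, labels, positive) {
  g <- as.character(labels)
  neg <- setdiff(unique(g), positive)
  if (length(neg) != 1L) stop("need the positive class plus exactly one ",
                              "other class")
  .rocOne(scores, g, positive, neg)
}

.rocOne <- function(scores, g, pos, neg) {
  r <- pROC::roc(response = g, predictor = scores, levels = c(neg, pos),
                 direction = "<", quiet = TRUE)
  ci <- tryCatch(suppressWarnings(
    as.numeric(pROC::ci.auc(r, method = "delong"))),
    error = function(e) rep(as.numeric(pROC::auc(r)), 3))
  ci[is.na(ci)] <- as.numeric(pROC::auc(r))
  list(roc = data.frame(fpr = 1 - r$specificities,
                        tpr = r$sensitivities),
       auc = as.numeric(pROC::auc(r)),
       ciLow = max(0, min(ci[1], ci[2])),
       ciHigh = min(1, max(ci[2], ci[3])),
       nCases = sum(g == pos), nControls = sum(g == neg))
}
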