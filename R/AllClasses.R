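#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowRanges
#' @importFrom GenomicRanges GRanges coverage
#' @importFrom IRanges IRanges Views viewSums
NULL

#' Simulation configuration for a synthetic cfDNA cohort
#'
#' Holds every knob of the synthetic cohort generator: cohort composition,
#' TSS geometry, sequencing depth, the nucleosome-depletion signal planted at
#' informative TSSs, and pathway structure. The seed fully determines the
#' generated cohort.
#'
#' @slot nHealthy number of healthy samples.
#' @slot nCancerPerStage named integer vector (`I`..`IV`) of cancer samples
#'   per stage; stages may be zero.
#' @slot nTss number of TSS sites on the synthetic chromosome.
#' @slot nInformativeUp,nInformativeDown numbers of planted TSSs whose central
#'   coverage increases (resp. decreases) with stage.
#' @slot backgroundDepth mean per-base fragment coverage away from TSSs
#'   (default 6, i.e. ~6X low-pass WGS).
#' @slot depletionHealthy central-window depth relative to the flanks for a
#'   non-informative (and healthy-sample) TSS; in (0, 1).
#' @slot stageEffect additive per-stage shift on the depletion fraction of
#'   planted TSSs (stage s shifts by `s * stageEffect`).
#' @slot fragLenMean,fragLenSd fragment length distribution (bp), truncated
#'   to \[80, 300\].
#' @slot noiseSd per-sample multiplicative (log-normal) depth noise.
#' @slot nPathways,nEgfrPathways,genesPerPathway synthetic pathway structure;
#'   `nEgfrPathways` sets contain the anchor gene "EGFR" and carry the
#'   planted EGFR effect.
#' @slot pathwayEffect depletion shift applied to genes of EGFR pathways in
#'   EGFR-positive samples (negative = more accessible, lower coverage).
#' @slot egfrPositiveFrac fraction of cancer samples labelled EGFR-positive.
#' @slot transcriptsPerGene 1 for one transcript per gene; 2 or 3 draws
#'   2--3 transcripts per gene to exercise transcript-to-gene averaging.
#' @slot tssSpacing distance between consecutive TSSs (bp, >= 3001 so that
#'   +/-1500 bp windows never overlap).
#' @slot seed integer seed; identical configs give byte-identical outputs.
#' @export
setClass("SimConfig", representation(
  nHealthy = "integer",
  nCancerPerStage = "integer",
  nTss = "integer",
  nInformativeUp = "integer",
  nInformativeDown = "integer",
  backgroundDepth = "numeric",
  depletionHealthy = "numeric",
  stageEffect = "numeric",
  fragLenMean = "numeric",
  fragLenSd = "numeric",
  noiseSd = "numeric",
  nPathways = "integer",
  nEgfrPathways = "integer",
  genesPerPathway = "integer",
  pathwayEffect = "numeric",
  egfrPositiveFrac = "numeric",
  transcriptsPerGene = "integer",
  tssSpacing = "integer",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  counts <- c(object@nHealthy, object@nCancerPerStage, object@nTss,
              object@nInformativeUp, object@nInformativeDown,
              object@nPathways, object@nEgfrPathways, object@genesPerPathway)
  if (any(counts < 0L)) msg <- c(msg, "all counts must be >= 0")
  if (!identical(sort(names(object@nCancerPerStage)),
                 sort(c("I", "II", "III", "IV"))))
    msg <- c(msg, "nCancerPerStage must be named I, II, III, IV")
  if (object@nInformativeUp + object@nInformativeDown > object@nTss)
    msg <- c(msg, "more informative TSSs requested than nTss")
  if (object@backgroundDepth <= 0) msg <- c(msg, "backgroundDepth must be > 0")
  if (object@depletionHealthy <= 0 || object@depletionHealthy >= 1)
    msg <- c(msg, "depletionHealthy must lie in (0, 1)")
  if (object@tssSpacing < 3001L)
    msg <- c(msg, paste0("tssSpacing ", object@tssSpacing, " < 3001 bp: ",
                         "+/-1500 bp windows would overlap; increase spacing ",
                         "or request fewer TSSs per chromosome"))
  if (object@nEgfrPathways > object@nPathways)
    msg <- c(msg, "nEgfrPathways must be <= nPathways")
  if (object@egfrPositiveFrac < 0 || object@egfrPositiveFrac > 1)
    msg <- c(msg, "egfrPositiveFrac must lie in [0, 1]")
  if (!object@transcriptsPerGene %in% 1:3)
    msg <- c(msg, "transcriptsPerGene must be 1, 2 or 3")
  if (length(msg)) msg else TRUE
})

#' A generated synthetic cfDNA cohort
#'
#' Returned by [simulateCohort()]. Fragments are kept in memory as one
#' [IRanges::IRanges] per sample (all on the single synthetic chromosome
#' "chrS"); files are written only when an output directory is supplied.
#'
#' @slot config the [SimConfig-class] that produced the cohort.
#' @slot tss TSS annotation as a width-1 [GenomicRanges::GRanges] with
#'   `transcript_id`, `gene_symbol` and `tss0` (0-based position) columns.
#' @slot samples per-sample `DataFrame` (sample_id, label, stage,
#'   egfr_status).
#' @slot fragments named `SimpleList` of `IRanges` (1-based, closed) of
#'   fragment footprints per sample.
#' @slot truth `DataFrame` of planted informative TSSs (transcript_id,
#'   direction) plus planted pathway gene memberships in `metadata()`.
#' @slot pathways named list of gene-symbol sets; EGFR-carrying sets are
#'   flagged in `metadata(truth)$egfr_pathways`.
#' @slot genomeLength length of chrS in bp.
#' @slot paths named list of files written (empty when in-memory only).
#' @export
setClass("SyntheticCohort", representation(
  config = "SimConfig",
  tss = "GRanges",
  samples = "DataFrame",
  fragments = "SimpleList",
  truth = "DataFrame",
  pathways = "list",
  genomeLength = "integer",
  paths = "list"
))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  if (!all(object@truth$transcript_id %in% object@tss$transcript_id))
    msg <- c(msg, "truth refers to transcripts absent from the annotation")
  nExp <- object@config@nHealthy + sum(object@config@nCancerPerStage)
  if (nrow(object@samples) != nExp)
    msg <- c(msg, "sample sheet size does not match the config")
  if (length(object@fragments) &&
      !identical(names(object@fragments), object@samples$sample_id))
    msg <- c(msg, "fragment list names must match sample ids")
  if (length(msg)) msg else TRUE
})

#' TSS relative-coverage matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] with transcripts as rows
#' and samples as columns, carrying two assays: `coverage` (the TSS relative
#' coverage, `NA` where masked) and `mask` (logical, `TRUE` where the flank
#' denominator was zero or the TSS was unusable). Row metadata holds the TSS
#' annotation (transcript_id, gene_symbol).
#'
#' @export
setClass("TssCoverageMatrix", contains = "RangedSummarizedExperiment")

setValidity("TssCoverageMatrix", function(object) {
  msg <- character()
  if (!all(c("coverage", "mask") %in% names(assays(object))))
    msg <- c(msg, "assays 'coverage' and 'mask' are required")
  else {
    cov <- assay(object, "coverage")
    m <- assay(object, "mask")
    if (!is.logical(m)) msg <- c(msg, "'mask' assay must be logical")
    else {
      if (any(is.na(cov) & !m)) msg <- c(msg, "NA coverage outside the mask")
      if (any(cov[!m & !is.na(cov)] < 0)) msg <- c(msg, "negative coverage")
    }
  }
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "row (transcript) and column (sample) names are required")
  if (length(msg)) msg else TRUE
})

#' Frozen training-cohort normalization parameters
#'
#' Per-transcript mean and standard deviation estimated on the training
#' cohort only, reused verbatim on validation/test cohorts. Transcripts with
#' zero variance, too few unmasked training values, or masked in more than
#' `maxMaskedFrac` of training samples are recorded in `dropped` and excluded
#' downstream.
#'
#' @slot mean,sd named numeric vectors over retained transcripts.
#' @slot nTrain number of training samples used.
#' @slot dropped named character vector: dropped transcript -> reason.
#' @slot maxMaskedFrac missingness threshold applied at fit time.
#' @export
setClass("NormalizationParams", representation(
  mean = "numeric",
  sd = "numeric",
  nTrain = "integer",
  dropped = "character",
  maxMaskedFrac = "numeric"
))

setValidity("NormalizationParams", function(object) {
  msg <- character()
  if (!identical(names(object@mean), names(object@sd)))
    msg <- c(msg, "mean and sd must be named identically")
  if (any(object@sd <= 0)) msg <- c(msg, "retained sd values must be > 0")
  if (length(msg)) msg else TRUE
})

#' Selected stage-monotone feature panel
#'
#' Ordered TSS features split into two direction classes: `cancer_up`
#' (coverage strictly increasing healthy -> stage IV) and `healthy_up`
#' (strictly decreasing). Within each class features are ranked by the
#' absolute difference between the stage-I and healthy group means,
#' descending, ties broken by transcript id.
#'
#' @slot transcripts ordered transcript ids.
#' @slot direction factor with levels `cancer_up`, `healthy_up`.
#' @slot score ranking score |mean(stage I) - mean(healthy)|.
#' @slot precut the top-`kPrecut` pre-cut per direction (list of two
#'   character vectors), kept as an intermediate artifact.
#' @slot groupMeans 5 x n matrix of group means (healthy, I--IV) for the
#'   panel transcripts.
#' @export
setClass("FeaturePanel", representation(
  transcripts = "character",
  direction = "factor",
  score = "numeric",
  precut = "list",
  groupMeans = "matrix"
))

setValidity("FeaturePanel", function(object) {
  msg <- character()
  n <- length(object@transcripts)
  if (length(object@direction) != n || length(object@score) != n)
    msg <- c(msg, "transcripts, direction and score lengths differ")
  if (!identical(levels(object@direction), c("cancer_up", "healthy_up")))
    msg <- c(msg, "direction levels must be cancer_up, healthy_up")
  if (anyDuplicated(object@transcripts))
    msg <- c(msg, "panel transcripts must be unique")
  for (d in levels(object@direction)) {
    s <- object@score[object@direction == d]
    if (length(s) > 1 && any(diff(s) > 1e-12))
      msg <- c(msg, sprintf("scores not non-increasing within %s", d))
  }
  if (length(msg)) msg else TRUE
})

#' Pathway database loaded from a GMT file
#'
#' Named gene sets with a logical flag marking "EGFR-related" pathways
#' (by default, any set containing the anchor symbol `EGFR`).
#'
#' @slot sets named list of character gene-symbol vectors.
#' @slot egfr named logical vector parallel to `sets`.
#' @slot anchor the anchor gene symbol used for flagging.
#' @export
setClass("PathwayDB", representation(
  sets = "list",
  egfr = "logical",
  anchor = "character"
))

setValidity("PathwayDB", function(object) {
  msg <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "pathway names must be unique and non-empty")
  if (any(lengths(object@sets) == 0)) msg <- c(msg, "empty gene set")
  if (!identical(names(object@egfr), names(object@sets)))
    msg <- c(msg, "egfr flags must be named like the sets")
  if (length(msg)) msg else TRUE
})

#' A fitted classifier with its frozen feature panel and CV summary
#'
#' @slot forest the fitted [randomForest::randomForest] object.
#' @slot featureIds transcript or gene ids the forest was trained on, in
#'   training order.
#' @slot positive the positive class label (scores are its class
#'   probability).
#' @slot trainIds sample ids seen in training; evaluation on any of them is
#'   refused.
#' @slot cv data.frame of per-repeat, per-fold AUCs (empty when CV was
#'   skipped).
#' @slot settings list: nTrees, mtry, folds, repeats, seed.
#' @export
setClass("ModelBundle", representation(
  forest = "ANY",
  featureIds = "character",
  positive = "character",
  trainIds = "character",
  cv = "data.frame",
  settings = "list"
))

setValidity("ModelBundle", function(object) {
  msg <- character()
  if (nrow(object@cv) && (any(object@cv$auc < 0) || any(object@cv$auc > 1)))
    msg <- c(msg, "CV AUCs must lie in [0, 1]")
  if (length(object@positive) != 1L) msg <- c(msg, "one positive class label")
  if (length(msg)) msg else TRUE
})
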