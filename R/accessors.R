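#' Construct a simulation configuration
#'
#' All arguments have defaults describing the reference synthetic cohort:
#' 60 healthy + 15 cancer samples per stage at ~6X depth, 2000 TSSs of which
#' 100 are planted coverage-up and 100 coverage-down with a 0.10 per-stage
#' depletion shift, and 40 synthetic pathways of which 6 carry an EGFR
#' effect. See [SimConfig-class] for the meaning of each field.
#'
#' @param nHealthy,nCancerPerStage cohort composition.
#' @param nTss,nInformativeUp,nInformativeDown TSS panel geometry.
#' @param backgroundDepth,depletionHealthy,stageEffect coverage signal.
#' @param fragLenMean,fragLenSd,noiseSd fragment and noise model.
#' @param nPathways,nEgfrPathways,genesPerPathway,pathwayEffect,egfrPositiveFrac
#'   pathway structure.
#' @param transcriptsPerGene,tssSpacing,seed plumbing.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nTss = 200, nHealthy = 4,
#'                  nCancerPerStage = c(I = 1, II = 1, III = 1, IV = 1))
#' @export
simConfig <- function(nHealthy = 60L,
                      nCancerPerStage = c(I = 15L, II = 15L, III = 15L, IV = 15L),
                      nTss = 2000L,
                      nInformativeUp = 100L,
                      nInformativeDown = 100L,
                      backgroundDepth = 6.0,
                      depletionHealthy = 0.5,
                      stageEffect = 0.10,
                      fragLenMean = 167,
                      fragLenSd = 10,
                      noiseSd = 0.05,
                      nPathways = 40L,
                      nEgfrPathways = 6L,
                      genesPerPathway = 15L,
                      pathwayEffect = -0.12,
                      egfrPositiveFrac = 0.45,
                      transcriptsPerGene = 1L,
                      tssSpacing = 4000L,
                      seed = 1L) {
  stg <- as.integer(nCancerPerStage)
  names(stg) <- names(nCancerPerStage)
  new("SimConfig",
      nHealthy = as.integer(nHealthy), nCancerPerStage = stg,
      nTss = as.integer(nTss),
      nInformativeUp = as.integer(nInformativeUp),
      nInformativeDown = as.integer(nInformativeDown),
      backgroundDepth = backgroundDepth,
      depletionHealthy = depletionHealthy, stageEffect = stageEffect,
      fragLenMean = fragLenMean, fragLenSd = fragLenSd, noiseSd = noiseSd,
      nPathways = as.integer(nPathways),
      nEgfrPathways = as.integer(nEgfrPathways),
      genesPerPathway = as.integer(genesPerPathway),
      pathwayEffect = pathwayEffect, egfrPositiveFrac = egfrPositiveFrac,
      transcriptsPerGene = as.integer(transcriptsPerGene),
      tssSpacing = as.integer(tssSpacing), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nHealthy, "healthy +",
      paste(object@nCancerPerStage, names(object@nCancerPerStage),
            collapse = ", "), "cancer\n")
  cat("  ", object@nTss, " TSSs (", object@nInformativeUp, " up / ",
      object@nInformativeDown, " down planted), depth ",
      object@backgroundDepth, "X, depletion ", object@depletionHealthy,
      " + stage*", object@stageEffect, "\n", sep = "")
  cat("  ", object@nPathways, " pathways (", object@nEgfrPathways,
      " EGFR, effect ", object@pathwayEffect, "), seed ", object@seed,
      "\n", sep = "")
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@samples), "samples,",
      length(object@tss), "TSSs on chrS (", object@genomeLength, "bp )\n")
  cat("  planted:", sum(object@truth$direction == "cancer_up"), "up,",
      sum(object@truth$direction == "healthy_up"), "down;",
      length(object@pathways), "pathways\n")
  if (length(object@paths)) cat("  written under:",
                                dirname(object@paths[[1]]), "\n")
})

#' @describeIn TssCoverageMatrix the relative-coverage assay (NA = masked).
#' @param x,object a `TssCoverageMatrix`.
#' @export
coverageValues <- function(x) SummarizedExperiment::assay(x, "coverage")

#' @describeIn TssCoverageMatrix the logical missingness mask.
#' @export
coverageMask <- function(x) SummarizedExperiment::assay(x, "mask")

setMethod("show", "TssCoverageMatrix", function(object) {
  callNextMethod()
  cat("masked entries:", sum(assay(object, "mask")), "of",
      length(assay(object, "mask")), "\n")
})

#' @describeIn NormalizationParams transcripts retained by the fit.
#' @param x,object a `NormalizationParams`.
#' @export
retainedTranscripts <- function(x) names(x@mean)

#' @describeIn NormalizationParams dropped transcript ids with reasons.
#' @export
droppedTranscripts <- function(x) x@dropped

setMethod("show", "NormalizationParams", function(object) {
  cat("NormalizationParams:", length(object@mean), "transcripts from",
      object@nTrain, "training samples;", length(object@dropped),
      "dropped\n")
})

#' @describeIn FeaturePanel ordered transcript ids of the panel.
#' @param x,object a `FeaturePanel`.
#' @export
panelTranscripts <- function(x) x@transcripts

#' @describeIn FeaturePanel direction class per panel feature.
#' @export
panelDirection <- function(x) stats::setNames(x@direction, x@transcripts)

#' @describeIn FeaturePanel the panel as a data.frame
#'   (transcript_id, direction, rank_score).
#' @export
panelTable <- function(x) {
  data.frame(transcript_id = x@transcripts,
             direction = as.character(x@direction),
             rank_score = unname(x@score),
             row.names = NULL, stringsAsFactors = FALSE)
}

setMethod("show", "FeaturePanel", function(object) {
  tb <- table(object@direction)
  cat("FeaturePanel:", length(object@transcripts), "features (",
      tb[["cancer_up"]], "cancer_up /", tb[["healthy_up"]], "healthy_up )\n")
})

#' @describeIn PathwayDB named list of gene sets.
#' @param x,object a `PathwayDB`.
#' @export
pathwaySets <- function(x) x@sets

#' @describeIn PathwayDB logical flag of EGFR-related sets.
#' @export
isEgfrRelated <- function(x) x@egfr

setMethod("show", "PathwayDB", function(object) {
  cat("PathwayDB:", length(object@sets), "gene sets,",
      sum(object@egfr), "containing anchor", object@anchor, "\n")
})

#' @describeIn ModelBundle per-fold cross-validation AUCs.
#' @param x,object a `ModelBundle`.
#' @export
cvSummary <- function(x) x@cv

#' @describeIn ModelBundle feature ids the forest uses.
#' @export
modelFeatures <- function(x) x@featureIds

setMethod("show", "ModelBundle", function(object) {
  cat("ModelBundle:", length(object@featureIds), "features,",
      object@settings$nTrees, "trees, mtry", object@settings$mtry,
      "; positive =", object@positive, "\n")
  if (nrow(object@cv))
    cat("  CV AUC:", sprintf("%.3f", mean(object@cv$auc)), "over",
        nrow(object@cv), "folds\n")
})
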