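#' Run the full cfDNA TSS-coverage pipeline
#'
#' Orchestrates simulate -> coverage -> normalize/select -> pathscore ->
#' train/evaluate as one configured, logged, resumable run. Each stage
#' writes its outputs under `outdir` and records their MD5 checksums in
#' `manifest.json`; on a re-run, a stage is skipped when all its outputs
#' exist with matching checksums (unless `force`). A failing stage halts the
#' run with the stage named and renames its partial outputs to `*.failed`.
#'
#' @param config a YAML file path or an equivalent nested list. Recognized
#'   sections: `outdir`, `seed`, `stages` (character vector subset of
#'   simulate, coverage, select, pathscore, train, evaluate), `simulate`
#'   (arguments of [simConfig()]), `coverage` (`tss`, `fragments_dir` for
#'   external input), `select` (`train_fraction`, `alpha`, `cor_cutoff`,
#'   `k_per_direction`), `pathscore` (`gmt`, `anchor`), `model` (`n_trees`,
#'   `mtry`, `folds`, `repeats`).
#' @param force rerun stages even when their outputs are up to date.
#' @return the run manifest (named list), invisibly written to
#'   `outdir/manifest.json`.
#' @export
runPipeline <- function(config, force = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$outdir)) stop("config needs an 'outdir'")
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  allStages <- c("simulate", "coverage", "select", "pathscore", "train",
                 "evaluate")
  stages <- cfg$stages %||% allStages
  bad <- setdiff(stages, allStages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  manifestPath <- file.path(outdir, "manifest.json")
  manifest <- if (file.exists(manifestPath))
    jsonlite::read_json(manifestPath, simplifyVector = TRUE) else
    list(package = "cfTSS",
         version = as.character(utils::packageVersion("cfTSS")),
         seed = seed, stages = list())
  state <- new.env(parent = emptyenv())
  runners <- list(simulate = .stSimulate, coverage = .stCoverage,
                  select = .stSelect, pathscore = .stPathscore,
                  train = .stTrain, evaluate = .stEvaluate)
  for (st in allStages[allStages %in% stages]) {
    outs <- .stageOutputs(st, outdir, cfg)
    if (!force && .stageUpToDate(manifest, st, outs)) {
      message("[", st, "] up to date, skipped")
      next
    }
    message("[", st, "] running")
    ok <- tryCatch({
      runners[[st]](cfg, outdir, seed, state)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      for (f in outs[file.exists(outs)]) file.rename(f, paste0(f, ".failed"))
      stop("stage '", st, "' failed: ", conditionMessage(ok))
    }
    manifest$stages[[st]] <- list(
      outputs = as.list(tools::md5sum(outs[file.exists(outs)])),
      seed = seed, time = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stageOutputs <- function(stage, outdir, cfg) {
  p <- function(...) file.path(outdir, ...)
  switch(stage,
    simulate = c(p("tss.tsv"), p("tss.bed"), p("samples.tsv"),
                 p("truth.tsv"), p("pathways.gmt")),
    coverage = c(p("matrix.tsv"), p("mask.tsv")),
    select = c(p("split.json"), p("params.json"), p("panel.tsv")),
    pathscore = c(p("path_scores.tsv"), p("pathway_tests.tsv")),
    train = p("model.rds"),
    evaluate = c(p("evaluation.json"), p("roc_points.tsv")))
}

.stageUpToDate <- function(manifest, stage, outs) {
  rec <- manifest$stages[[stage]]
  if (is.null(rec)) return(FALSE)
  if (!all(file.exists(outs))) return(FALSE)
  md5 <- tools::md5sum(outs)
  rec <- unlist(rec$outputs)
  all(names(md5) %in% names(rec)) && all(rec[names(md5)] == md5)
}

.stSimulate <- function(cfg, outdir, seed, state) {
  args <- cfg$simulate %||% list()
  nm <- names(args)
  camel <- gsub("_(\\w)", "\\U\\1", nm, perl = TRUE)
  names(args) <- camel
  if (!"seed" %in% camel) args$seed <- seed
  if ("nCancerPerStage" %in% camel) {
    v <- unlist(args$nCancerPerStage)
    if (is.null(names(v)) && length(v) == 4L)   # YAML drops vector names
      names(v) <- c("I", "II", "III", "IV")
    args$nCancerPerStage <- v
  }
  state$cohort <- simulateCohort(do.call(simConfig, args), outdir = outdir)
}

.stCoverage <- function(cfg, outdir, seed, state) {
  if (!is.null(state$cohort)) {
    frags <- cohortFragments(state$cohort)
    tss <- cohortTss(state$cohort)
    sheet <- cohortSamples(state$cohort)
  } else {
    tssPath <- cfg$coverage$tss %||% file.path(outdir, "tss.tsv")
    fragDir <- cfg$coverage$fragments_dir %||% file.path(outdir, "fragments")
    sheetPath <- file.path(outdir, "samples.tsv")
    if (!file.exists(tssPath) || !dir.exists(fragDir))
      stop("coverage inputs missing (need TSS annotation '", tssPath,
           "' and fragment dir '", fragDir,
           "'); enable the simulate stage or point 'coverage:' at them")
    tss <- readTssAnnotation(tssPath)
    files <- list.files(fragDir, pattern = "\\.(bed|bam)$",
                        full.names = TRUE)
    files <- files[!duplicated(sub("\\.(bed|bam)$", "", files))]
    frags <- stats::setNames(as.list(files),
                             sub("\\.(bed|bam)$", "", basename(files)))
    sheet <- if (file.exists(sheetPath)) data.table::fread(sheetPath)
             else NULL
  }
  cm <- buildCoverageMatrix(frags, tss, sampleData = sheet)
  writeCoverageMatrix(cm, file.path(outdir, "matrix.tsv"),
                      file.path(outdir, "mask.tsv"))
  state$cm <- cm
  state$tss <- tss
}

.pipeInputs <- function(outdir, state) {
  if (is.null(state$cm)) {
    mPath <- file.path(outdir, "matrix.tsv")
    tPath <- file.path(outdir, "tss.tsv")
    sPath <- file.path(outdir, "samples.tsv")
    if (!file.exists(mPath) || !file.exists(tPath) || !file.exists(sPath))
      stop("no coverage matrix available; enable the coverage stage first")
    state$tss <- readTssAnnotation(tPath)
    state$cm <- readCoverageMatrix(mPath, state$tss,
                                   file.path(outdir, "mask.tsv"))
    sheetDf <- data.table::fread(sPath)
    SummarizedExperiment::colData(state$cm) <- S4Vectors::DataFrame(
      sheetDf[match(colnames(state$cm), sheetDf$sample_id), ])
  }
  sheet <- as.data.frame(SummarizedExperiment::colData(state$cm))
  list(cm = state$cm, sheet = sheet, tss = state$tss)
}

.stSelect <- function(cfg, outdir, seed, state) {
  inp <- .pipeInputs(outdir, state)
  sc <- cfg$select %||% list()
  split <- stratifiedSplit(inp$sheet$sample_id, inp$sheet$label,
                           trainFraction = sc$train_fraction %||% 0.7,
                           seed = seed + 1L)
  jsonlite::write_json(split, file.path(outdir, "split.json"))
  params <- fitNormalization(inp$cm, split$train)
  writeNormalizationParams(params, file.path(outdir, "params.json"))
  zTrain <- applyNormalization(inp$cm, params)[, split$train, drop = FALSE]
  tr <- inp$sheet[match(split$train, inp$sheet$sample_id), ]
  panel <- selectFeatures(zTrain, tr$label, tr$stage,
                          alpha = sc$alpha %||% 0.01,
                          corCutoff = sc$cor_cutoff %||% 0.9,
                          kPerDirection = sc$k_per_direction %||% 100L)
  writeFeaturePanel(panel, file.path(outdir, "panel.tsv"))
  state$split <- split
  state$params <- params
  state$panel <- panel
}

# reload select-stage artifacts from disk when running stages standalone
.reloadSelect <- function(outdir, state) {
  if (is.null(state$params)) {
    pPath <- file.path(outdir, "params.json")
    if (!file.exists(pPath))
      stop("no normalization parameters; enable the select stage first")
    state$params <- readNormalizationParams(pPath)
    state$split <- jsonlite::read_json(file.path(outdir, "split.json"),
                                       simplifyVector = TRUE)
    state$panel <- readFeaturePanel(file.path(outdir, "panel.tsv"))
  }
}

.stPathscore <- function(cfg, outdir, seed, state) {
  inp <- .pipeInputs(outdir, state)
  .reloadSelect(outdir, state)
  ps <- cfg$pathscore %||% list()
  gmt <- ps$gmt %||% file.path(outdir, "pathways.gmt")
  if (!file.exists(gmt)) stop("no GMT file at ", gmt)
  db <- readGmt(gmt, anchor = ps$anchor %||% "EGFR")
  z <- applyNormalization(inp$cm, state$params)
  geneMat <- geneLevelValues(z, inp$tss)
  scores <- pathScoreMatrix(geneMat, db)
  data.table::fwrite(data.table::data.table(
    pathway = rownames(scores), scores),
    file.path(outdir, "path_scores.tsv"), sep = "\t")
  eg <- inp$sheet$egfr_status
  ok <- !is.na(eg) & eg != ""
  if (sum(ok) >= 6L && length(unique(eg[ok])) == 2L &&
      min(table(eg[ok])) >= 3L) {
    pt <- pathwayGroupTest(scores[, ok, drop = FALSE], eg[ok], db)
    tab <- as.data.frame(pt$table)
  } else {
    message("too few EGFR-labelled samples; pathway group test skipped")
    tab <- data.frame(pathway = rownames(scores), p = NA_real_,
                      egfr_related = unname(isEgfrRelated(db)),
                      significant = NA)
  }
  data.table::fwrite(tab, file.path(outdir, "pathway_tests.tsv"),
                     sep = "\t")
  state$db <- db
}

.stTrain <- function(cfg, outdir, seed, state) {
  inp <- .pipeInputs(outdir, state)
  .reloadSelect(outdir, state)
  mc <- cfg$model %||% list()
  z <- applyNormalization(inp$cm, state$params)
  tr <- inp$sheet[match(state$split$train, inp$sheet$sample_id), ]
  bundle <- trainRf(
    z[panelTranscripts(state$panel), state$split$train, drop = FALSE],
    tr$label, positive = "cancer",
    nTrees = mc$n_trees %||% 1500L, mtry = mc$mtry %||% 1L,
    folds = mc$folds %||% 10L, repeats = mc$repeats %||% 3L,
    seed = seed + 2L)
  saveRDS(bundle, file.path(outdir, "model.rds"))
  state$bundle <- bundle
}

.stEvaluate <- function(cfg, outdir, seed, state) {
  inp <- .pipeInputs(outdir, state)
  .reloadSelect(outdir, state)
  if (is.null(state$bundle)) {
    mPath <- file.path(outdir, "model.rds")
    if (!file.exists(mPath))
      stop("no trained model; enable the train stage first")
    state$bundle <- readRDS(mPath)
  }
  z <- applyNormalization(inp$cm, state$params)
  va <- inp$sheet[match(state$split$validation, inp$sheet$sample_id), ]
  sub <- list(
    early = va$sample_id[!is.na(va$stage) & va$stage %in% c("I", "II")],
    advanced = va$sample_id[!is.na(va$stage) & va$stage %in% c("III", "IV")])
  ev <- withCallingHandlers(
    evaluateRoc(state$bundle, z[, state$split$validation, drop = FALSE],
                va$label, subgroups = sub),
    warning = function(w) invokeRestart("muffleWarning"))
  cvTab <- cvSummary(state$bundle)
  jsonlite::write_json(list(
    cv_auc_mean = if (nrow(cvTab)) mean(cvTab$auc) else NULL,
    cohorts = lapply(ev, function(e)
      e[c("auc", "ciLow", "ciHigh", "nCases", "nControls")])),
    file.path(outdir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  pts <- do.call(rbind, lapply(names(ev), function(nm)
    data.frame(cohort = nm, ev[[nm]]$roc)))
  data.table::fwrite(pts, file.path(outdir, "roc_points.tsv"), sep = "\t")
  state$evaluation <- ev
}
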