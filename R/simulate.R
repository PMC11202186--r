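#' Generate a synthetic cfDNA cohort with planted structure
#'
#' Simulates per-sample cfDNA fragment footprints on one synthetic
#' chromosome ("chrS", 0-based half-open coordinates in all written files).
#' Fragment midpoints are drawn from a density that is flat at the
#' background rate everywhere except TSS +/-500 bp, where it is scaled by
#' the sample's depletion fraction for that TSS: active promoters shed
#' nucleosome-depleted regions, so cfDNA coverage dips there. Planted
#' "informative" TSSs shift their depletion by `stageEffect` per cancer
#' stage (up or down), planted EGFR-pathway genes shift by `pathwayEffect`
#' in EGFR-positive samples, and every remaining TSS shares one
#' class-independent depletion. The seed fully determines the cohort,
#' including written files.
#'
#' @param config a [SimConfig-class], see [simConfig()].
#' @param outdir optional directory; when given, writes the TSS annotation
#'   (BED6 + TSV), one fragment BED3 per sample, the sample sheet TSV, a GMT
#'   pathway file and a truth TSV (plus indexed BAMs when `writeBam`).
#' @param writeBam also write each sample as a coordinate-sorted, indexed
#'   BAM of proper read pairs (slow; intended for small cohorts).
#' @return a [SyntheticCohort-class].
#' @examples
#' coh <- simulateCohort(simConfig(nTss = 50, nHealthy = 2,
#'   nCancerPerStage = c(I = 1, II = 1, III = 1, IV = 1), seed = 7))
#' coh
#' @export
simulateCohort <- function(config, outdir = NULL, writeBam = FALSE) {
  validObject(config)
  withr::with_seed(config@seed, {
    geom <- .simGeometry(config)
    ann <- .simAnnotation(config, geom)
    planted <- .simPlanted(config, ann)
    samples <- .simSampleSheet(config)
    frags <- .simFragments(config, geom, samples, planted)
  })
  gr <- planted$gr   # carries the EGFR gene relabel
  truth <- S4Vectors::DataFrame(
    transcript_id = gr$transcript_id[c(planted$up, planted$down)],
    direction = rep(c("cancer_up", "healthy_up"),
                    c(length(planted$up), length(planted$down))))
  S4Vectors::metadata(truth) <- list(
    egfr_pathways = planted$egfrPathwayNames,
    egfr_effect_genes = planted$egfrGenes)
  coh <- new("SyntheticCohort", config = config, tss = gr,
             samples = samples, fragments = frags, truth = truth,
             pathways = planted$pathways,
             genomeLength = geom$genomeLength, paths = list())
  if (!is.null(outdir)) coh <- writeCohort(coh, outdir, writeBam = writeBam)
  coh
}

.simGeometry <- function(config) {
  firstTss <- 2000L
  tss0 <- firstTss + (seq_len(config@nTss) - 1L) * config@tssSpacing
  list(firstTss = firstTss, tss0 = tss0,
       genomeLength = tss0[length(tss0)] + 2000L)
}

.simAnnotation <- function(config, geom) {
  n <- config@nTss
  if (config@transcriptsPerGene == 1L) {
    geneOf <- seq_len(n)
  } else {
    # consecutive transcripts grouped into genes of 2..transcriptsPerGene
    sizes <- sample(2:config@transcriptsPerGene, n, replace = TRUE)
    geneOf <- rep(seq_along(sizes), sizes)[seq_len(n)]
  }
  gene <- sprintf("G%06d", geneOf)
  gr <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(start = geom$tss0 + 1L, width = 1L),
    strand = sample(c("+", "-"), n, replace = TRUE),
    transcript_id = sprintf("T%06d", seq_len(n)),
    gene_symbol = gene, tss0 = geom$tss0)
  list(gr = gr, geneOf = geneOf)
}

.simPlanted <- function(config, ann) {
  n <- config@nTss
  inf <- sample(n, config@nInformativeUp + config@nInformativeDown)
  up <- sort(inf[seq_len(config@nInformativeUp)])
  down <- sort(setdiff(inf, up))
  genes <- ann$gr$gene_symbol
  infGenes <- unique(genes[inf])
  universe <- setdiff(unique(genes), infGenes)

  pathways <- list()
  egfrGenes <- character()
  egfrNames <- character()
  if (config@nPathways > 0L && length(universe) > config@genesPerPathway) {
    egfrSym <- universe[1]          # this gene plays the EGFR anchor role
    pool <- setdiff(universe, egfrSym)
    nEgfrPool <- min(length(pool) %/% 2,
                     config@nEgfrPathways * config@genesPerPathway)
    egfrPool <- sample(pool, nEgfrPool)
    rest <- setdiff(pool, egfrPool)
    for (i in seq_len(config@nPathways)) {
      nm <- sprintf("PATHWAY_%03d", i)
      if (i <= config@nEgfrPathways) {
        pathways[[nm]] <- c(egfrSym,
                            sample(egfrPool, config@genesPerPathway - 1L))
        egfrNames <- c(egfrNames, nm)
      } else {
        pathways[[nm]] <- sample(rest,
                                 min(config@genesPerPathway, length(rest)))
      }
    }
    # relabel the anchor gene as EGFR everywhere
    genes[genes == egfrSym] <- "EGFR"
    ann$gr$gene_symbol <- genes
    pathways <- lapply(pathways, function(g) {
      g[g == egfrSym] <- "EGFR"
      g
    })
    egfrGenes <- unique(unlist(pathways[egfrNames], use.names = FALSE))
  }
  egfrTss <- which(genes %in% egfrGenes)
  list(up = up, down = down, pathways = pathways,
       egfrPathwayNames = egfrNames, egfrGenes = egfrGenes,
       egfrTss = egfrTss, gr = ann$gr)
}

.simSampleSheet <- function(config) {
  stages <- rep(names(config@nCancerPerStage), config@nCancerPerStage)
  nCancer <- length(stages)
  ids <- c(sprintf("H%03d", seq_len(config@nHealthy)),
           sprintf("C%03d", seq_len(nCancer)))
  egfr <- rep(NA_character_, config@nHealthy + nCancer)
  if (nCancer > 0L) {
    nPos <- round(config@egfrPositiveFrac * nCancer)
    st <- rep("wild-type", nCancer)
    st[sample(nCancer, nPos)] <- "positive"
    egfr[config@nHealthy + seq_len(nCancer)] <- st
  }
  S4Vectors::DataFrame(
    sample_id = ids,
    label = rep(c("healthy", "cancer"), c(config@nHealthy, nCancer)),
    stage = c(rep(NA_character_, config@nHealthy), stages),
    egfr_status = egfr)
}

# per-sample expected depletion fractions, clamped to [0, 1.5]
.simDepletion <- function(config, planted, label, stage, egfr) {
  d <- rep(config@depletionHealthy, config@nTss)
  if (identical(label, "cancer")) {
    s <- match(stage, c("I", "II", "III", "IV"))
    d[planted$up] <- d[planted$up] + s * config@stageEffect
    d[planted$down] <- d[planted$down] - s * config@stageEffect
    if (identical(egfr, "positive"))
      d[planted$egfrTss] <- d[planted$egfrTss] + config@pathwayEffect
  }
  pmin(pmax(d, 0), 1.5)
}

.truncFragLengths <- function(n, mean, sd) {
  len <- round(stats::rnorm(n, mean, sd))
  bad <- which(len < 80 | len > 300)
  while (length(bad)) {
    len[bad] <- round(stats::rnorm(length(bad), mean, sd))
    bad <- bad[len[bad] < 80 | len[bad] > 300]
  }
  len
}

.simFragments <- function(config, geom, samples, planted) {
  L <- geom$genomeLength
  baseRate <- config@backgroundDepth / config@fragLenMean
  out <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    d <- .simDepletion(config, planted, samples$label[i],
                       samples$stage[i], samples$egfr_status[i])
    lam <- baseRate * exp(stats::rnorm(1, 0, config@noiseSd))
    # background midpoints genome-wide, thinned inside central windows
    mid <- floor(stats::runif(stats::rpois(1, lam * L), 0, L))
    k <- pmin(pmax(round((mid - geom$firstTss) / config@tssSpacing), 0),
              config@nTss - 1L)
    off <- mid - (geom$firstTss + k * config@tssSpacing)
    inWin <- off >= -500L & off < 500L
    keepP <- rep(1, length(mid))
    keepP[inWin] <- pmin(d[k[inWin] + 1L], 1)
    mid <- mid[stats::runif(length(mid)) < keepP]
    # surplus midpoints where the depletion fraction exceeds 1
    over <- which(d > 1)
    if (length(over)) {
      nx <- stats::rpois(length(over), lam * 1000 * (d[over] - 1))
      extra <- rep(geom$tss0[over], nx) - 500L
      mid <- c(mid, extra + floor(stats::runif(length(extra), 0, 1000)))
    }
    len <- .truncFragLengths(length(mid), config@fragLenMean,
                             config@fragLenSd)
    start0 <- pmax(mid - len %/% 2L, 0L)
    end0 <- pmin(start0 + len, L)
    o <- order(start0, end0)
    out[[i]] <- IRanges::IRanges(start = start0[o] + 1L, end = end0[o])
  }
  names(out) <- samples$sample_id
  S4Vectors::SimpleList(out)
}

#' @describeIn simulateCohort write a cohort's files to disk. Returns the
#'   cohort with its `paths` slot filled.
#' @param cohort a [SyntheticCohort-class].
#' @export
writeCohort <- function(cohort, outdir, writeBam = FALSE) {
  dir.create(file.path(outdir, "fragments"), recursive = TRUE,
             showWarnings = FALSE)
  gr <- cohort@tss
  tssBed <- file.path(outdir, "tss.bed")
  data.table::fwrite(data.table::data.table(
    chrom = "chrS", start = gr$tss0, end = gr$tss0 + 1L,
    name = gr$transcript_id, score = 0L,
    strand = as.character(GenomicRanges::strand(gr))),
    tssBed, sep = "\t", col.names = FALSE)
  tssTsv <- file.path(outdir, "tss.tsv")
  data.table::fwrite(data.table::data.table(
    chrom = "chrS", tss_pos = gr$tss0,
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = gr$transcript_id, gene_symbol = gr$gene_symbol),
    tssTsv, sep = "\t")
  sheet <- file.path(outdir, "samples.tsv")
  data.table::fwrite(as.data.frame(cohort@samples), sheet, sep = "\t")
  truthTsv <- file.path(outdir, "truth.tsv")
  data.table::fwrite(as.data.frame(cohort@truth), truthTsv, sep = "\t")
  gmt <- file.path(outdir, "pathways.gmt")
  writeLines(vapply(names(cohort@pathways), function(nm) {
    paste(c(nm, "synthetic", cohort@pathways[[nm]]), collapse = "\t")
  }, character(1)), gmt)
  beds <- character(0)
  bams <- character(0)
  for (sid in names(cohort@fragments)) {
    fr <- cohort@fragments[[sid]]
    f <- file.path(outdir, "fragments", paste0(sid, ".bed"))
    data.table::fwrite(data.table::data.table(
      chrom = "chrS", start = IRanges::start(fr) - 1L,
      end = IRanges::end(fr)), f, sep = "\t", col.names = FALSE)
    beds[sid] <- f
    if (writeBam)
      bams[sid] <- writeFragmentsBam(
        fr, file.path(outdir, "fragments", paste0(sid, ".bam")),
        chromLength = cohort@genomeLength)
  }
  cohort@paths <- list(tss_bed = tssBed, tss_tsv = tssTsv,
                       sample_sheet = sheet, truth = truthTsv, gmt = gmt,
                       fragment_beds = beds,
                       fragment_bams = if (writeBam) bams else NULL)
  cohort
}

#' @describeIn simulateCohort TSS annotation of a cohort (GRanges).
#' @export
cohortTss <- function(cohort) cohort@tss

#' @describeIn simulateCohort sample sheet of a cohort (DataFrame).
#' @export
cohortSamples <- function(cohort) cohort@samples

#' @describeIn simulateCohort per-sample fragment IRanges list.
#' @export
cohortFragments <- function(cohort) cohort@fragments

#' @describeIn simulateCohort planted-feature truth table.
#' @export
cohortTruth <- function(cohort) cohort@truth
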