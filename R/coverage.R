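#' TSS relative coverage of one depth window
#'
#' The core accessibility statistic: mean per-base cfDNA depth over the
#' central window (TSS +/-500 bp) divided by the mean depth of the two
#' flanking 1 kb windows. Values near 1 indicate nucleosome-protected
#' (inactive) promoters; values well below 1 indicate a nucleosome-depleted,
#' accessible promoter. All three windows are half-open 1000-base intervals
#' partitioning \[tss-1500, tss+1500).
#'
#' @param central,left,right numeric per-base depth vectors, each of length
#'   1000: `[tss-500, tss+500)`, `[tss-1500, tss-500)`, `[tss+500, tss+1500)`.
#' @return a single non-negative number, or `NA` when the flank denominator
#'   is zero (a masked value, never an error).
#' @examples
#' tssRelativeCoverage(rep(2, 1000), rep(2, 1000), rep(2, 1000))  # 1
#' tssRelativeCoverage(rep(5, 1000), rep(8, 1000), rep(12, 1000)) # 0.5
#' @export
tssRelativeCoverage <- function(central, left, right) {
  stopifnot(length(central) == 1000L, length(left) == 1000L,
            length(right) == 1000L,
            all(central >= 0), all(left >= 0), all(right >= 0))
  .relcovFromSums(sum(central), sum(left), sum(right))
}

.relcovFromSums <- function(cs, ls, rs) {
  den <- (ls + rs) / 2000
  ifelse(den == 0, NA_real_, (cs / 1000) / den)
}

#' Read cfDNA fragment intervals from BAM or BED
#'
#' BAM records are filtered the way low-pass cfDNA WGS pipelines do before
#' depth calculations: mapping quality below `mapqMin` is dropped, as is any
#' record whose FLAG intersects `flagMask` (default 3840 = secondary +
#' QC-fail + duplicate + supplementary). Fragments are reconstructed from
#' the leftmost mate of each pair (TLEN > 0), i.e. the read-pair union. BED3
#' input (0-based half-open) passes through unfiltered; it is assumed
#' pre-filtered by its producer.
#'
#' @param path a coordinate-sorted, indexed `.bam`, or a `.bed`.
#' @param mapqMin minimum mapping quality kept (default 2, i.e. MAPQ < 2
#'   excluded).
#' @param flagMask SAM flag bits that disqualify a record (default 3840).
#' @return a [GenomicRanges::GRanges] of fragment footprints.
#' @export
readFragments <- function(path, mapqMin = 2L, flagMask = 3840L) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    bed <- data.table::fread(path, header = FALSE,
                             col.names = c("chrom", "start", "end")[1:3])
    return(GenomicRanges::GRanges(
      bed$chrom, IRanges::IRanges(start = bed$start + 1L, end = bed$end)))
  }
  if (ext != "bam")
    stop("unknown fragment format '.", ext, "' (expected .bam or .bed): ",
         path)
  if (!file.exists(paste0(path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", path)))
    stop("BAM is not indexed: ", path,
         " -- sort and index it first (samtools sort; samtools index)")
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$text
  so <- hdr[["@HD"]]
  if (is.null(so) || !any(grepl("SO:coordinate", so)))
    stop("BAM is not coordinate-sorted: ", path,
         " -- run samtools sort before indexing")
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "mapq", "flag", "isize"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$mapq) & b$mapq >= mapqMin &
    bitwAnd(b$flag, as.integer(flagMask)) == 0L &
    !is.na(b$isize) & b$isize > 0L & !is.na(b$pos)
  GenomicRanges::GRanges(
    as.character(b$rname[keep]),
    IRanges::IRanges(start = b$pos[keep], width = b$isize[keep]))
}

#' Write fragments as a coordinate-sorted, indexed BAM of proper pairs
#'
#' Each fragment becomes one properly-paired read pair (flags 99/147) whose
#' outer coordinates span the fragment footprint; read length is the
#' fragment length capped at 150 bp.
#'
#' @param fragments an [IRanges::IRanges] or [GenomicRanges::GRanges]
#'   (1-based closed) of fragment footprints.
#' @param path output path ending in `.bam`.
#' @param chromLength reference length written to the header.
#' @param chrom reference name (ignored for GRanges input).
#' @return the path of the sorted, indexed BAM.
#' @export
writeFragmentsBam <- function(fragments, path, chromLength,
                              chrom = "chrS") {
  if (methods::is(fragments, "GRanges")) {
    chrom <- as.character(GenomicRanges::seqnames(fragments))[1]
    fragments <- GenomicRanges::ranges(fragments)
  }
  s <- IRanges::start(fragments)
  w <- IRanges::width(fragments)
  rl <- pmin(w, 150L)
  e2 <- IRanges::end(fragments) - rl + 1L
  qn <- sprintf("frag%07d", seq_along(s))
  seqs <- strrep("A", rl)
  cig <- paste0(rl, "M")
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:", chrom, "\tLN:", chromLength),
    paste(qn, 99L, chrom, s, 60L, cig, "=", e2, w, seqs, "*", sep = "\t"),
    paste(qn, 147L, chrom, e2, 60L, cig, "=", s, -w, seqs, "*", sep = "\t"))
  sam <- tempfile(fileext = ".sam")
  writeLines(lines, sam)
  on.exit(unlink(sam))
  raw <- Rsamtools::asBam(sam, tempfile(), indexDestination = FALSE)
  dest <- sub("\\.bam$", "", path)
  Rsamtools::sortBam(raw, dest)
  unlink(raw)
  Rsamtools::indexBam(paste0(dest, ".bam"))
  paste0(dest, ".bam")
}

#' Read a TSS annotation table
#'
#' Accepts either the package's TSV layout (`chrom`, `tss_pos`, `strand`,
#' `transcript_id`, `gene_symbol`, with header) or BED6 (name column =
#' transcript id, gene symbol defaulting to the transcript id). Positions
#' are 0-based.
#'
#' @param path annotation file.
#' @return a width-1 [GenomicRanges::GRanges] with `transcript_id`,
#'   `gene_symbol` and `tss0` columns.
#' @export
readTssAnnotation <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^chrom\t", first)) {
    tb <- data.table::fread(path)
    gr <- GenomicRanges::GRanges(
      tb$chrom, IRanges::IRanges(start = tb$tss_pos + 1L, width = 1L),
      strand = tb$strand, transcript_id = tb$transcript_id,
      gene_symbol = tb$gene_symbol, tss0 = tb$tss_pos)
  } else {
    tb <- data.table::fread(path, header = FALSE)
    if (ncol(tb) < 4L) stop("TSS BED needs at least 4 columns: ", path)
    strand <- if (ncol(tb) >= 6L) tb[[6]] else "*"
    gr <- GenomicRanges::GRanges(
      tb[[1]], IRanges::IRanges(start = tb[[2]] + 1L, width = 1L),
      strand = strand, transcript_id = tb[[4]], gene_symbol = tb[[4]],
      tss0 = tb[[2]])
  }
  if (anyDuplicated(gr$transcript_id))
    stop("duplicate transcript ids in TSS annotation: ", path)
  gr
}

#' Build the TSS relative-coverage matrix for a cohort
#'
#' Computes fragment-overlap depth (each fragment's footprint counted once
#' per base) and the TSS relative coverage for every (sample, transcript)
#' pair. TSSs closer than 1500 bp to the chromosome start are unusable and
#' fully masked; zero-flank TSSs are masked per sample. The statistic is
#' strand-symmetric, so strand is carried but ignored.
#'
#' @param fragments a named list/`SimpleList` of per-sample fragments: each
#'   element an `IRanges` (single chromosome "chrS"), a `GRanges`, or a path
#'   accepted by [readFragments()].
#' @param tss TSS annotation `GRanges` (see [readTssAnnotation()]) or a
#'   [SyntheticCohort-class].
#' @param sampleData optional per-sample `DataFrame`/data.frame (rownames or
#'   `sample_id` column matching names of `fragments`) stored as `colData`.
#' @param ... passed to [readFragments()] for file inputs.
#' @return a [TssCoverageMatrix-class] (transcripts x samples).
#' @examples
#' coh <- simulateCohort(simConfig(nTss = 30, nHealthy = 2,
#'   nCancerPerStage = c(I = 1, II = 0, III = 0, IV = 1), seed = 3))
#' cm <- buildCoverageMatrix(cohortFragments(coh), cohortTss(coh))
#' cm
#' @export
buildCoverageMatrix <- function(fragments, tss, sampleData = NULL, ...) {
  if (methods::is(tss, "SyntheticCohort")) {
    if (is.null(sampleData)) sampleData <- cohortSamples(tss)
    tss <- cohortTss(tss)
  }
  stopifnot(length(tss) > 0L, !is.null(names(fragments)),
            length(fragments) > 0L)
  tss0 <- GenomicRanges::start(tss) - 1L
  chrom <- as.character(GenomicRanges::seqnames(tss))
  usable <- tss0 >= 1500L
  if (!any(usable))
    stop("no usable TSSs: all sites are < 1500 bp from the chromosome start")
  if (any(!usable))
    message(sum(!usable), " TSS record(s) < 1500 bp from the chromosome ",
            "start flagged unusable and masked")
  nT <- length(tss)
  ids <- names(fragments)
  vals <- matrix(NA_real_, nT, length(ids),
                 dimnames = list(tss$transcript_id, ids))
  mask <- matrix(TRUE, nT, length(ids),
                 dimnames = dimnames(vals))
  for (j in seq_along(ids)) {
    fr <- fragments[[j]]
    if (is.character(fr)) fr <- readFragments(fr, ...)
    if (length(fr) == 0L) stop("sample ", ids[j], " has no fragments")
    if (methods::is(fr, "IRanges")) {
      covs <- list(IRanges::coverage(fr))
      names(covs) <- unique(chrom)[1]
    } else {
      covs <- as.list(GenomicRanges::coverage(fr))
    }
    for (chr in unique(chrom[usable])) {
      idx <- which(usable & chrom == chr)
      if (!chr %in% names(covs)) next   # no fragments on chr: stays masked
      cov <- covs[[chr]]
      p <- tss0[idx]
      maxEnd <- max(p) + 1500L
      if (length(cov) < maxEnd)
        cov <- c(cov, S4Vectors::Rle(0L, maxEnd - length(cov)))
      cs <- .windowSums(cov, p - 500L, 1000L)
      ls <- .windowSums(cov, p - 1500L, 1000L)
      rs <- .windowSums(cov, p + 500L, 1000L)
      v <- .relcovFromSums(cs, ls, rs)
      vals[idx, j] <- v
      mask[idx, j] <- is.na(v)
    }
    # chromosomes absent from a sample: flanks empty => masked (already TRUE)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(coverage = vals, mask = mask),
    rowRanges = stats::setNames(tss, tss$transcript_id))
  if (!is.null(sampleData)) {
    sd <- S4Vectors::DataFrame(sampleData)
    rn <- if ("sample_id" %in% colnames(sd)) sd$sample_id else rownames(sd)
    SummarizedExperiment::colData(se) <- sd[match(ids, rn), , drop = FALSE]
    colnames(se) <- ids
  }
  out <- methods::new("TssCoverageMatrix", se)
  S4Vectors::metadata(out)$n_unusable <- sum(!usable)
  out
}

# sums of an Rle over half-open windows [start0, start0 + width) (0-based)
.windowSums <- function(cov, start0, width) {
  as.numeric(IRanges::viewSums(
    IRanges::Views(cov, IRanges::IRanges(start = start0 + 1L,
                                         width = width))))
}

#' Write / read a coverage matrix as TSV (rows = samples)
#'
#' The on-disk layout follows the sample-major convention of cfDNA feature
#' tables: one row per sample, one column per transcript, plus a parallel
#' 0/1 mask TSV.
#'
#' @param x a [TssCoverageMatrix-class].
#' @param file,maskFile output TSVs.
#' @export
writeCoverageMatrix <- function(x, file, maskFile = NULL) {
  v <- t(coverageValues(x))
  data.table::fwrite(data.table::data.table(sample_id = rownames(v), v),
                     file, sep = "\t")
  if (!is.null(maskFile)) {
    m <- t(coverageMask(x)) * 1L
    data.table::fwrite(data.table::data.table(sample_id = rownames(m), m),
                       maskFile, sep = "\t")
  }
  invisible(file)
}

#' @rdname writeCoverageMatrix
#' @param tss TSS annotation `GRanges` covering the matrix transcripts.
#' @export
readCoverageMatrix <- function(file, tss, maskFile = NULL) {
  tb <- data.table::fread(file)
  ids <- tb$sample_id
  v <- t(as.matrix(tb[, -1]))
  colnames(v) <- ids
  if (!is.null(maskFile)) {
    mt <- data.table::fread(maskFile)
    m <- t(as.matrix(mt[, -1])) == 1L
    colnames(m) <- mt$sample_id
    m <- m[rownames(v), ids, drop = FALSE]
  } else m <- is.na(v)
  keep <- match(rownames(v), tss$transcript_id)
  if (anyNA(keep))
    stop("matrix transcripts missing from the TSS annotation")
  gr <- stats::setNames(tss[keep], rownames(v))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(coverage = v, mask = m), rowRanges = gr)
  methods::new("TssCoverageMatrix", se)
}
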