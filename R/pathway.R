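#' Load a pathway database from a GMT file
#'
#' Reads tab-separated gene sets (name, description, member symbols) and
#' flags "EGFR-related" pathways: any set containing the anchor symbol. The
#' package ships no curated pathway data; any GMT (e.g. KEGG-derived
#' canonical pathways) can be supplied.
#'
#' @param path GMT file.
#' @param anchor gene symbol whose presence flags a set as EGFR-related
#'   (default `"EGFR"`).
#' @return a [PathwayDB-class].
#' @export
readGmt <- function(path, anchor = "EGFR") {
  sets <- fgsea::gmtPathways(path)
  pathwayDB(sets, anchor = anchor)
}

#' @rdname readGmt
#' @param sets a named list of character gene-symbol vectors.
#' @export
pathwayDB <- function(sets, anchor = "EGFR") {
  egfr <- vapply(sets, function(g) anchor %in% g, logical(1))
  methods::new("PathwayDB", sets = sets, egfr = egfr, anchor = anchor)
}

#' Collapse transcript-level values to gene level
#'
#' A gene's value per sample is the mean of its transcripts' normalized
#' values, so multi-transcript genes are not over-weighted when pathways are
#' scored.
#'
#' @param z normalized matrix (transcripts x samples).
#' @param annotation TSS annotation `GRanges` (or data.frame) with
#'   `transcript_id` and `gene_symbol`.
#' @return numeric matrix (genes x samples).
#' @export
geneLevelValues <- function(z, annotation) {
  ann <- as.data.frame(annotation)
  gene <- ann$gene_symbol[match(rownames(z), ann$transcript_id)]
  if (anyNA(gene)) {
    warning(sum(is.na(gene)), " transcript(s) missing from the annotation ",
            "were dropped")
    z <- z[!is.na(gene), , drop = FALSE]
    gene <- gene[!is.na(gene)]
  }
  sums <- rowsum(z, gene)
  sums / as.vector(table(gene)[rownames(sums)])
}

#' Per-sample path score of one gene set
#'
#' The path score is the mean normalized TSS coverage over the pathway's
#' genes present in the matrix; genes absent from the matrix are dropped and
#' the fraction retained is attached as `attr(, "coverage")`.
#'
#' @param geneMat matrix (genes x samples) from [geneLevelValues()].
#' @param genes character vector of pathway gene symbols.
#' @return per-sample numeric vector (`NA` when no gene is present).
#' @export
pathScore <- function(geneMat, genes) {
  present <- intersect(genes, rownames(geneMat))
  out <- if (length(present) == 0L)
    stats::setNames(rep(NA_real_, ncol(geneMat)), colnames(geneMat))
  else colMeans(geneMat[present, , drop = FALSE])
  attr(out, "coverage") <- length(present) / length(unique(genes))
  out
}

#' Path-score matrix over a pathway database
#'
#' @param geneMat matrix (genes x samples).
#' @param db a [PathwayDB-class].
#' @return matrix (pathways x samples) with per-pathway gene coverage in
#'   `attr(, "coverage")`; pathways with no measurable gene score `NA`.
#' @export
pathScoreMatrix <- function(geneMat, db) {
  sets <- pathwaySets(db)
  scores <- t(vapply(sets, function(g) {
    s <- pathScore(geneMat, g)
    attributes(s)$coverage <- NULL
    s
  }, numeric(ncol(geneMat))))
  colnames(scores) <- colnames(geneMat)
  attr(scores, "coverage") <- vapply(sets, function(g)
    length(intersect(g, rownames(geneMat))) / length(unique(g)), numeric(1))
  scores
}

#' Group comparison of path scores
#'
#' Two-sided rank-sum test per pathway between two groups (e.g.
#' EGFR-positive vs wild-type), with significant-pathway fractions reported
#' overall, for the EGFR-related subset, and for the remaining pathways.
#' Pathways with constant or missing scores are excluded from the
#' denominators.
#'
#' @param scores matrix (pathways x samples) from [pathScoreMatrix()].
#' @param labels two-level grouping along columns.
#' @param db a [PathwayDB-class] supplying the EGFR flags (or a named
#'   logical vector).
#' @param alpha significance threshold on the raw p-value (default 0.01).
#' @return list with `table` (pathway, p, egfr_related, significant) and
#'   `fractions` (subset, significant, total, fraction).
#' @export
pathwayGroupTest <- function(scores, labels, db, alpha = 0.01) {
  egfr <- if (methods::is(db, "PathwayDB")) isEgfrRelated(db) else db
  egfr <- egfr[rownames(scores)]
  scr <- groupDifferenceScreen(scores, labels, alpha)
  tab <- S4Vectors::DataFrame(pathway = rownames(scores), p = scr$p,
                              egfr_related = unname(egfr),
                              significant = scr$keep)
  testable <- !is.na(tab$p)
  frac <- function(sel) {
    tot <- sum(sel & testable)
    sig <- sum(sel & testable & tab$significant)
    c(significant = sig, total = tot,
      fraction = if (tot) sig / tot else NA_real_)
  }
  fractions <- rbind(all = frac(rep(TRUE, nrow(tab))),
                     egfr = frac(tab$egfr_related),
                     non_egfr = frac(!tab$egfr_related))
  list(table = tab,
       fractions = data.frame(subset = rownames(fractions), fractions,
                              row.names = NULL))
}

#' Gene feature set for the EGFR mutation-status model
#'
#' Restricts to genes belonging to EGFR-related pathways that are present in
#' the matrix, tests each gene between the two groups, and retains genes
#' with p below `alpha`, ordered by p then symbol (deterministic).
#'
#' @param geneMat matrix (genes x samples).
#' @param db a [PathwayDB-class].
#' @param labels two-level grouping along columns (e.g. `positive` /
#'   `wild-type`).
#' @param alpha retention threshold (default 0.01).
#' @return `DataFrame` (gene, p) of retained genes; empty (with a warning)
#'   when no pathway gene overlaps the matrix.
#' @export
egfrFeatureSet <- function(geneMat, db, labels, alpha = 0.01) {
  genes <- unique(unlist(pathwaySets(db)[isEgfrRelated(db)],
                         use.names = FALSE))
  present <- intersect(genes, rownames(geneMat))
  if (length(present) == 0L) {
    warning("no EGFR-pathway gene overlaps the matrix")
    return(S4Vectors::DataFrame(gene = character(), p = numeric()))
  }
  scr <- groupDifferenceScreen(geneMat[present, , drop = FALSE], labels,
                               alpha)
  keep <- !is.na(scr$p) & (scr$p < alpha | alpha >= 1)
  out <- S4Vectors::DataFrame(gene = scr$feature[keep], p = scr$p[keep])
  out[order(out$p, out$gene), , drop = FALSE]
}
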