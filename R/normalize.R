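#' Fit z-score normalization on the training cohort
#'
#' Per-transcript mean and standard deviation are estimated on the training
#' samples only, over unmasked entries, and frozen: the same parameters are
#' applied verbatim to validation and independent test cohorts. Transcripts
#' masked in more than `maxMaskedFrac` of training samples, with fewer than
#' two unmasked training values, or with zero variance are dropped and
#' recorded.
#'
#' @param x a [TssCoverageMatrix-class], or a numeric matrix
#'   (transcripts x samples, `NA` = masked).
#' @param trainIds sample ids (column names) of the training cohort.
#' @param maxMaskedFrac maximum tolerated training missingness per
#'   transcript (default 0.2).
#' @return a [NormalizationParams-class].
#' @export
setGeneric("fitNormalization", function(x, trainIds, maxMaskedFrac = 0.2)
  standardGeneric("fitNormalization"))

#' @rdname fitNormalization
setMethod("fitNormalization", "TssCoverageMatrix",
  function(x, trainIds, maxMaskedFrac = 0.2) {
    v <- coverageValues(x)
    v[coverageMask(x)] <- NA_real_
    fitNormalization(v, trainIds, maxMaskedFrac)
  })

#' @rdname fitNormalization
setMethod("fitNormalization", "matrix",
  function(x, trainIds, maxMaskedFrac = 0.2) {
    missingIds <- setdiff(trainIds, colnames(x))
    if (length(missingIds))
      stop("training ids absent from the matrix: ",
           paste(utils::head(missingIds, 5), collapse = ", "))
    v <- x[, trainIds, drop = FALSE]
    nMasked <- rowSums(is.na(v))
    n <- length(trainIds)
    mu <- rowMeans(v, na.rm = TRUE)
    sdv <- apply(v, 1L, stats::sd, na.rm = TRUE)
    reason <- rep(NA_character_, nrow(v))
    reason[nMasked / n > maxMaskedFrac] <- "masked_above_threshold"
    reason[is.na(reason) & (n - nMasked) < 2L] <- "too_few_values"
    reason[is.na(reason) & (is.na(sdv) | sdv == 0)] <- "zero_variance"
    keep <- is.na(reason)
    if (!any(keep)) stop("no transcripts usable for normalization")
    methods::new("NormalizationParams",
                 mean = mu[keep], sd = sdv[keep], nTrain = as.integer(n),
                 dropped = stats::setNames(reason[!keep],
                                           rownames(v)[!keep]),
                 maxMaskedFrac = maxMaskedFrac)
  })

#' Apply frozen normalization parameters
#'
#' Computes `z = (x - mean) / sd` with the training-cohort parameters; any
#' masked entry is imputed to 0 (the training feature mean) after the
#' transformation. Transcripts without fitted parameters are dropped with a
#' warning; the parameters themselves are never updated.
#'
#' @param x a [TssCoverageMatrix-class] or numeric matrix
#'   (transcripts x samples, `NA` = masked).
#' @param params a [NormalizationParams-class] from [fitNormalization()].
#' @return a plain numeric matrix (retained transcripts x samples), no `NA`.
#' @export
setGeneric("applyNormalization", function(x, params)
  standardGeneric("applyNormalization"))

#' @rdname applyNormalization
setMethod("applyNormalization", "TssCoverageMatrix", function(x, params) {
  v <- coverageValues(x)
  v[coverageMask(x)] <- NA_real_
  applyNormalization(v, params)
})

#' @rdname applyNormalization
setMethod("applyNormalization", "matrix", function(x, params) {
  keep <- intersect(rownames(x), retainedTranscripts(params))
  dropped <- setdiff(rownames(x), c(keep, names(params@dropped)))
  if (length(dropped))
    warning(length(dropped), " transcript(s) have no fitted parameters ",
            "and were dropped")
  v <- x[keep, , drop = FALSE]
  z <- (v - params@mean[keep]) / params@sd[keep]
  z[is.na(z)] <- 0
  z
})

#' Serialize normalization parameters as JSON
#'
#' @param params a [NormalizationParams-class].
#' @param file JSON path.
#' @export
writeNormalizationParams <- function(params, file) {
  jsonlite::write_json(
    list(mean = as.list(params@mean), sd = as.list(params@sd),
         n_train = params@nTrain, max_masked_frac = params@maxMaskedFrac,
         dropped = as.list(params@dropped)),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeNormalizationParams
#' @export
readNormalizationParams <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  methods::new("NormalizationParams",
               mean = unlist(j$mean), sd = unlist(j$sd),
               nTrain = as.integer(j$n_train),
               dropped = if (length(j$dropped)) unlist(j$dropped)
                         else stats::setNames(character(), character()),
               maxMaskedFrac = j$max_masked_frac %||% 0.2)
}
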