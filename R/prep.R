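#' Expression prefilter specification
#'
#' A transcript is kept when its value reaches \code{minValue} in at least a
#' \code{minSampleFraction} of samples (both comparisons non-strict). The
#' defaults used in this workflow are >= 5 TPM in 25\% of samples for linear
#' genes and >= 1 raw backspliced read in 15\% of samples for circRNAs; see
#' \code{linearFilterSpec()} and \code{circFilterSpec()}.
#'
#' @param minValue minimum value a sample must reach to count.
#' @param minSampleFraction required fraction of samples in (0, 1].
#' @return A list of class \code{FilterSpec}.
#' @export
filterSpec <- function(minValue, minSampleFraction) {
  stopifnot(is.numeric(minValue), length(minValue) == 1L, is.finite(minValue))
  if (!is.numeric(minSampleFraction) || length(minSampleFraction) != 1L ||
      minSampleFraction <= 0 || minSampleFraction > 1)
    stop("minSampleFraction must lie in (0, 1]")
  structure(list(minValue = minValue, minSampleFraction = minSampleFraction),
            class = "FilterSpec")
}

#' @rdname filterSpec
#' @export
linearFilterSpec <- function() filterSpec(5, 0.25)

#' @rdname filterSpec
#' @export
circFilterSpec <- function() filterSpec(1, 0.15)

#' Differential-expression call thresholds
#'
#' A transcript is called differentially expressed when p < \code{maxP}
#' (strict), |logFC| > \code{minAbsLogFC} (strict; the default 0 excludes
#' exactly-zero fold changes) and FDR-adjusted p <= \code{maxFDR}
#' (non-strict). Defaults: p < 0.05, |logFC| > 0, FDR <= 0.15.
#'
#' @param maxP strict p-value threshold.
#' @param minAbsLogFC strict absolute log-fold-change threshold.
#' @param maxFDR non-strict FDR threshold.
#' @return A list of class \code{DECallSpec}.
#' @export
deCallSpec <- function(maxP = 0.05, minAbsLogFC = 0, maxFDR = 0.15) {
  stopifnot(maxP >= 0, maxP <= 1, minAbsLogFC >= 0, maxFDR >= 0, maxFDR <= 1)
  structure(list(maxP = maxP, minAbsLogFC = minAbsLogFC, maxFDR = maxFDR),
            class = "DECallSpec")
}

#' Convert raw counts to TPM
#'
#' Standard transcripts-per-million: per sample, counts are divided by
#' effective transcript length (in bases) to give rates, and rates are
#' rescaled to sum to 1e6. A sample with no reads at all yields an all-zero
#' column (with a message, not an error).
#'
#' @param counts \linkS4class{ExpressionMatrix} with unit
#'   \code{"raw_counts"}.
#' @param lengths numeric vector of positive effective lengths, named by
#'   transcript id (must cover all transcripts in \code{counts}).
#' @return \linkS4class{ExpressionMatrix} with unit \code{"TPM"}; every
#'   column with nonzero counts sums to 1e6.
#' @examples
#' m <- ExpressionMatrix(matrix(c(10, 10), 2, 1,
#'        dimnames = list(c("g1", "g2"), "s1")), "raw_counts")
#' exprValues(countsToTPM(m, c(g1 = 1000, g2 = 2000)))
#' @export
countsToTPM <- function(counts, lengths) {
  stopifnot(is(counts, "ExpressionMatrix"))
  if (unitLabel(counts) != "raw_counts")
    stop("countsToTPM expects unit 'raw_counts', got '", unitLabel(counts), "'")
  ids <- transcriptIds(counts)
  missing <- setdiff(ids, names(lengths))
  if (length(missing))
    stop("lengths missing for transcript(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  len <- as.numeric(lengths[ids])
  if (any(!is.finite(len)) || any(len <= 0))
    stop("transcript lengths must be positive and finite")
  rate <- exprValues(counts) / len
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    message("all-zero sample column(s): ",
            paste(sampleIds(counts)[zero], collapse = ", "))
    tot[zero] <- 1   # keeps the column exactly zero
  }
  ExpressionMatrix(sweep(rate, 2L, tot, "/") * 1e6, "TPM")
}

#' Depth-normalize backspliced read counts
#'
#' Backspliced read counts are normalized against sequencing depth as reads
#' per million sequenced reads, putting circRNA abundance on a per-million
#' scale comparable to TPM.
#'
#' @param counts \linkS4class{ExpressionMatrix} with unit
#'   \code{"raw_counts"} (backspliced reads).
#' @param depths numeric vector of total sequenced reads per sample, named
#'   by sample id; all > 0.
#' @return \linkS4class{ExpressionMatrix} with unit
#'   \code{"normalized_backspliced_reads"}.
#' @export
normalizeBacksplice <- function(counts, depths) {
  stopifnot(is(counts, "ExpressionMatrix"))
  if (unitLabel(counts) != "raw_counts")
    stop("normalizeBacksplice expects unit 'raw_counts', got '",
         unitLabel(counts), "'")
  ids <- sampleIds(counts)
  missing <- setdiff(ids, names(depths))
  if (length(missing))
    stop("depths missing for sample(s): ", paste(missing, collapse = ", "))
  d <- as.numeric(depths[ids])
  if (any(!is.finite(d)) || any(d <= 0))
    stop("sequencing depths must be positive and finite")
  ExpressionMatrix(sweep(exprValues(counts), 2L, d / 1e6, "/"),
                   "normalized_backspliced_reads")
}

#' Prefilter transcripts by expression prevalence
#'
#' Keeps a transcript iff the fraction of samples with value >=
#' \code{spec$minValue} is >= \code{spec$minSampleFraction} (both
#' non-strict). The circRNA rule is evaluated on raw backspliced read
#' counts: pass the raw matrix and \code{onRaw = TRUE} while \code{m} holds
#' the normalized values whose ids are returned.
#'
#' @param m \linkS4class{ExpressionMatrix} whose transcript ids are
#'   reported.
#' @param spec a \code{\link{filterSpec}}.
#' @param raw optional \linkS4class{ExpressionMatrix} of raw counts, same
#'   transcripts and samples as \code{m}.
#' @param onRaw evaluate the threshold on \code{raw} instead of \code{m}.
#' @return Character vector of kept transcript ids (in matrix order).
#' @export
prefilter <- function(m, spec, raw = NULL, onRaw = FALSE) {
  stopifnot(is(m, "ExpressionMatrix"), inherits(spec, "FilterSpec"))
  v <- exprValues(m)
  if (onRaw) {
    if (is.null(raw)) stop("onRaw = TRUE requires the raw count matrix")
    stopifnot(is(raw, "ExpressionMatrix"))
    if (!identical(dim(exprValues(raw)), dim(v)) ||
        !identical(transcriptIds(raw), transcriptIds(m)) ||
        !identical(sampleIds(raw), sampleIds(m)))
      stop("raw matrix must match m in transcripts and samples")
    v <- exprValues(raw)
  }
  keep <- rowMeans(v >= spec$minValue) >= spec$minSampleFraction
  transcriptIds(m)[keep]
}

#' Call differential-expression status per transcript and comparison
#'
#' Applies the DE thresholds with their exact boundary semantics:
#' p strictly below \code{maxP}, |logFC| strictly above \code{minAbsLogFC},
#' FDR non-strictly below \code{maxFDR}. Direction is the sign of logFC.
#'
#' @param t validated DE table (see \code{\link{readDETable}}); \code{fdr}
#'   must be non-missing.
#' @param spec a \code{\link{deCallSpec}}.
#' @return \code{t} with an added \code{status} column: \code{"up"},
#'   \code{"down"} or \code{"none"}.
#' @export
callDE <- function(t, spec = deCallSpec()) {
  t <- validateDETable(t)
  stopifnot(inherits(spec, "DECallSpec"))
  if (nrow(t) == 0L) { t$status <- character(0); return(t) }
  if (anyNA(t$fdr))
    stop("callDE requires fdr for every record; table from '",
         t$source_tool[1L], "' has missing fdr")
  de <- t$p_value < spec$maxP & abs(t$log_fc) > spec$minAbsLogFC &
    t$fdr <= spec$maxFDR
  t$status <- ifelse(de, ifelse(t$log_fc > 0, "up", "down"), "none")
  t
}

#' Cross-tool consensus for differential-expression calls
#'
#' Classifies each primary (edgeR-style) DE call by whether it is supported
#' by the two orthogonal tests: CIRIquant concurs when it reports p <
#' \code{alpha} for the same transcript in the same comparison group and the
#' same direction; CircTest concurs when it reports p < \code{alpha} in the
#' same comparison group (direction not required). A transcript absent from
#' a secondary table simply does not concur.
#'
#' @param primary output of \code{\link{callDE}} (must carry \code{status}).
#' @param ciriquant,circtest validated DE tables from the respective tools.
#' @param alpha significance level for the secondary tests.
#' @return data.frame with one row per primary DE call (status != "none"):
#'   \code{transcript_id}, \code{comparison_group}, \code{status},
#'   \code{ciriquant_concurs}, \code{circtest_concurs} and
#'   \code{validation} in \{both, ciriquant_only, circtest_only, none\}.
#' @export
deConsensus <- function(primary, ciriquant, circtest, alpha = 0.05) {
  stopifnot(is.data.frame(primary), "status" %in% colnames(primary))
  ciriquant <- validateDETable(ciriquant)
  circtest <- validateDETable(circtest)
  de <- primary[primary$status != "none", , drop = FALSE]
  if (nrow(de) == 0L)
    return(data.frame(transcript_id = character(0),
                      comparison_group = character(0), status = character(0),
                      ciriquant_concurs = logical(0),
                      circtest_concurs = logical(0),
                      validation = character(0), stringsAsFactors = FALSE))
  key <- function(tab) paste(tab$transcript_id, tab$comparison_group)
  cqSig <- ciriquant[ciriquant$p_value < alpha, , drop = FALSE]
  ctSig <- circtest[circtest$p_value < alpha, , drop = FALSE]
  cqUp <- key(cqSig[cqSig$log_fc > 0, , drop = FALSE])
  cqDown <- key(cqSig[cqSig$log_fc < 0, , drop = FALSE])
  deKey <- key(de)
  cq <- ifelse(de$status == "up", deKey %in% cqUp, deKey %in% cqDown)
  ct <- deKey %in% key(ctSig)
  validation <- ifelse(cq & ct, "both",
                ifelse(cq, "ciriquant_only",
                ifelse(ct, "circtest_only", "none")))
  data.frame(transcript_id = de$transcript_id,
             comparison_group = de$comparison_group,
             status = de$status,
             ciriquant_concurs = cq, circtest_concurs = ct,
             validation = validation, stringsAsFactors = FALSE)
}
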