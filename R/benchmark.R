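#' Reconstruct modeled bulk expression
#'
#' Matrix product of the fitted cell-type-specific coefficients and the
#' per-sample cell-type proportions: \code{modeled[g, s] = sum_c B[g, c] *
#' p[c, s]}. With non-negative coefficients and proportions all modeled
#' values are >= 0. Comparing this reconstruction with the ground-truth
#' bulk matrix is the benchmark of the deconvolution fit.
#'
#' @param coefficients \linkS4class{CoefficientMatrix}.
#' @param proportions \linkS4class{ProportionMatrix} with the same cell
#'   types in the same order.
#' @param unitLabel unit label for the result (default \code{"arbitrary"};
#'   pass the unit of the bulk matrix the fit was trained on).
#' @return \linkS4class{ExpressionMatrix} of modeled bulk expression.
#' @export
reconstructBulk <- function(coefficients, proportions,
                            unitLabel = "arbitrary") {
  stopifnot(is(coefficients, "CoefficientMatrix"),
            is(proportions, "ProportionMatrix"))
  if (!identical(cellTypes(coefficients), cellTypes(proportions)))
    stop("cell types of coefficients and proportions must match in order; got (",
         paste(cellTypes(coefficients), collapse = ", "), ") vs (",
         paste(cellTypes(proportions), collapse = ", "), ")")
  ExpressionMatrix(coefValues(coefficients) %*% fractions(proportions),
                   unitLabel)
}

.pearsonTest <- function(x, y) {
  # closed-form Pearson r with the two-sided t test on n - 2 df;
  # cross-checked against stats::cor.test in the test suite
  n <- length(x)
  if (n < 3L || sd(x) == 0 || sd(y) == 0)
    return(c(r = NA_real_, p = NA_real_))
  r <- cor(x, y)
  if (abs(r) >= 1) return(c(r = r, p = .Machine$double.xmin))
  t <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = max(2 * pt(abs(t), n - 2, lower.tail = FALSE),
                   .Machine$double.xmin))
}

.assertSameShape <- function(modeled, truth) {
  stopifnot(is(modeled, "ExpressionMatrix"), is(truth, "ExpressionMatrix"))
  if (!identical(transcriptIds(modeled), transcriptIds(truth)) ||
      !identical(sampleIds(modeled), sampleIds(truth)))
    stop("modeled and truth matrices must have identical transcripts and samples, in order")
}

#' Per-transcript agreement between modeled and ground-truth bulk
#'
#' For each transcript, a simple linear regression of the ground-truth bulk
#' values on the modeled values across samples; R-squared is the squared
#' Pearson correlation and the p-value is the two-sided t test on the slope
#' with n - 2 degrees of freedom (identical under either regression
#' direction; truth-on-modeled is fixed here for determinism of slopes).
#' Diagnostics are undefined when either series is constant or n < 3; such
#' transcripts are excluded from downstream median-R2 computations and can
#' never be called cell-type specific.
#'
#' @param modeled,truth \linkS4class{ExpressionMatrix} of identical shape
#'   and ordering.
#' @return data.frame with columns \code{transcript_id}, \code{r_squared},
#'   \code{p_value}, \code{defined}.
#' @export
perTranscriptDiagnostics <- function(modeled, truth) {
  .assertSameShape(modeled, truth)
  M <- exprValues(modeled); Tm <- exprValues(truth)
  res <- t(vapply(seq_len(nrow(M)),
                  function(g) .pearsonTest(M[g, ], Tm[g, ]),
                  c(r = 0, p = 0)))
  data.frame(transcript_id = transcriptIds(modeled),
             r_squared = res[, "r"]^2,
             p_value = res[, "p"],
             defined = !is.na(res[, "r"]),
             stringsAsFactors = FALSE)
}

#' Per-sample agreement between modeled and ground-truth bulk
#'
#' Pearson correlation across transcripts between modeled and ground-truth
#' bulk expression, per sample, with the two-sided test p-value. A sample
#' whose modeled or ground-truth column is constant is flagged undefined.
#'
#' @param modeled,truth \linkS4class{ExpressionMatrix} of identical shape.
#' @return data.frame with columns \code{sample_id}, \code{pearson_r},
#'   \code{p_value}, \code{defined}.
#' @export
perSampleDiagnostics <- function(modeled, truth) {
  .assertSameShape(modeled, truth)
  M <- exprValues(modeled); Tm <- exprValues(truth)
  res <- t(vapply(seq_len(ncol(M)),
                  function(s) .pearsonTest(M[, s], Tm[, s]),
                  c(r = 0, p = 0)))
  data.frame(sample_id = sampleIds(modeled),
             pearson_r = res[, "r"],
             p_value = res[, "p"],
             defined = !is.na(res[, "r"]),
             stringsAsFactors = FALSE)
}

#' Summarize benchmark diagnostics
#'
#' Min / mean / max of the defined per-transcript R-squared values and the
#' defined per-sample Pearson correlations, plus counts, mirroring the
#' usual reporting of reconstruction benchmarks.
#'
#' @param transcriptDiag output of \code{\link{perTranscriptDiagnostics}}.
#' @param sampleDiag output of \code{\link{perSampleDiagnostics}}.
#' @param alpha significance level used to count significant transcripts.
#' @return Named list of summary statistics.
#' @export
benchmarkSummary <- function(transcriptDiag, sampleDiag, alpha = 0.05) {
  td <- transcriptDiag[transcriptDiag$defined, , drop = FALSE]
  sd_ <- sampleDiag[sampleDiag$defined, , drop = FALSE]
  list(n_transcripts = nrow(transcriptDiag),
       n_defined = nrow(td),
       n_significant = sum(td$p_value < alpha),
       r2_min = if (nrow(td)) min(td$r_squared) else NA_real_,
       r2_mean = if (nrow(td)) mean(td$r_squared) else NA_real_,
       r2_max = if (nrow(td)) max(td$r_squared) else NA_real_,
       pearson_min = if (nrow(sd_)) min(sd_$pearson_r) else NA_real_,
       pearson_mean = if (nrow(sd_)) mean(sd_$pearson_r) else NA_real_,
       pearson_max = if (nrow(sd_)) max(sd_$pearson_r) else NA_real_)
}
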