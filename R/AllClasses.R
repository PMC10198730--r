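#' @import methods
#' @importFrom stats rgamma rlnorm rnbinom rpois runif median pt cor sd setNames quantile
#' @importFrom utils read.delim write.table
NULL

.EXPR_UNITS <- c("TPM", "normalized_backspliced_reads", "raw_counts", "arbitrary")

.checkDimnames <- function(m, rowWhat, colWhat) {
  msgs <- character()
  rn <- rownames(m); cn <- colnames(m)
  if (is.null(rn) || any(is.na(rn)) || any(rn == ""))
    msgs <- c(msgs, sprintf("%s identifiers (rownames) must be present and non-empty", rowWhat))
  else if (anyDuplicated(rn))
    msgs <- c(msgs, sprintf("duplicate %s identifier(s): %s", rowWhat,
                            paste(unique(rn[duplicated(rn)]), collapse = ", ")))
  if (is.null(cn) || any(is.na(cn)) || any(cn == ""))
    msgs <- c(msgs, sprintf("%s identifiers (colnames) must be present and non-empty", colWhat))
  else if (anyDuplicated(cn))
    msgs <- c(msgs, sprintf("duplicate %s identifier(s): %s", colWhat,
                            paste(unique(cn[duplicated(cn)]), collapse = ", ")))
  msgs
}

#' ExpressionMatrix: transcripts-by-samples expression values
#'
#' Container for a bulk expression matrix: rows are transcripts (linear genes
#' or circRNAs identified by their backsplice junction), columns are samples.
#' Values must be finite and non-negative. The unit label records the scale:
#' \code{"TPM"} for linear genes, \code{"normalized_backspliced_reads"}
#' (backspliced reads per million sequenced reads) for circRNAs,
#' \code{"raw_counts"} for unnormalized counts, or \code{"arbitrary"} for
#' matrices mixing scales (e.g. a simulated matrix carrying both a linear and
#' a circRNA block, or a reconstructed bulk matrix).
#'
#' @slot values numeric matrix, transcripts x samples, non-negative.
#' @slot unitLabel single character, one of \code{"TPM"},
#'   \code{"normalized_backspliced_reads"}, \code{"raw_counts"},
#'   \code{"arbitrary"}.
#' @export
setClass("ExpressionMatrix",
         representation(values = "matrix", unitLabel = "character"))

setValidity("ExpressionMatrix", function(object) {
  m <- object@values
  msgs <- character()
  if (!is.numeric(m)) msgs <- c(msgs, "values must be a numeric matrix")
  else {
    if (any(!is.finite(m))) msgs <- c(msgs, "values must all be finite")
    else if (any(m < 0)) {
      bad <- which(m < 0, arr.ind = TRUE)[1L, ]
      msgs <- c(msgs, sprintf("negative value at transcript '%s', sample '%s'",
                              rownames(m)[bad[1L]], colnames(m)[bad[2L]]))
    }
    msgs <- c(msgs, .checkDimnames(m, "transcript", "sample"))
  }
  if (length(object@unitLabel) != 1L || !object@unitLabel %in% .EXPR_UNITS)
    msgs <- c(msgs, sprintf("unitLabel must be one of: %s",
                            paste(.EXPR_UNITS, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix (transcripts x samples) with rownames
#'   (transcript ids) and colnames (sample ids); non-negative and finite.
#' @param unitLabel unit of the values; see \linkS4class{ExpressionMatrix}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(c(1, 0.5, 0, 2), 2, 2,
#'             dimnames = list(c("circA", "circB"), c("s1", "s2")))
#' ExpressionMatrix(m, "normalized_backspliced_reads")
#' @export
ExpressionMatrix <- function(values, unitLabel) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("ExpressionMatrix", values = values, unitLabel = unitLabel)
}

#' ProportionMatrix: cell-type fractions per sample
#'
#' Cell types x samples matrix of cell-type composition fractions, as
#' estimated by a deconvolution tool such as CIBERSORT's "Impute Cell
#' Fractions" module. Every entry lies in [0, 1] and each sample's column
#' sums to 1 (within tolerance 1e-6).
#'
#' @slot fractions numeric matrix, cell types x samples.
#' @export
setClass("ProportionMatrix", representation(fractions = "matrix"))

setValidity("ProportionMatrix", function(object) {
  m <- object@fractions
  msgs <- character()
  if (!is.numeric(m)) return("fractions must be a numeric matrix")
  if (any(!is.finite(m))) msgs <- c(msgs, "fractions must all be finite")
  else {
    if (any(m < 0) || any(m > 1))
      msgs <- c(msgs, "all fractions must lie in [0, 1]")
    cs <- colSums(m)
    off <- which(abs(cs - 1) > 1e-6)
    if (length(off))
      msgs <- c(msgs, sprintf("column(s) not summing to 1 within 1e-6: %s (sum %s)",
                              paste(colnames(m)[off], collapse = ", "),
                              paste(signif(cs[off], 8), collapse = ", ")))
  }
  msgs <- c(msgs, .checkDimnames(m, "cell-type", "sample"))
  if (length(msgs)) msgs else TRUE
})

#' Construct a ProportionMatrix
#'
#' @param fractions numeric matrix, cell types x samples, with rownames
#'   (cell types) and colnames (sample ids).
#' @param renormalize if TRUE, divide each column by its sum before
#'   validation (useful for fraction tables that do not sum exactly to 1);
#'   if FALSE (default), columns must already sum to 1 within 1e-6.
#' @return A \linkS4class{ProportionMatrix}.
#' @examples
#' p <- matrix(c(0.6, 0.4), 2, 1, dimnames = list(c("T", "B"), "s1"))
#' ProportionMatrix(p)
#' @export
ProportionMatrix <- function(fractions, renormalize = FALSE) {
  fractions <- as.matrix(fractions)
  storage.mode(fractions) <- "double"
  if (renormalize) {
    cs <- colSums(fractions)
    if (any(cs <= 0)) stop("cannot renormalize: non-positive column sum")
    fractions <- sweep(fractions, 2L, cs, "/")
  }
  new("ProportionMatrix", fractions = fractions)
}

#' CoefficientMatrix: estimated cell-type-specific expression
#'
#' Transcripts x cell types matrix of non-negative NNLS coefficient
#' estimates. Zero entries produced by the active-set solver are exact
#' zeros, which is what makes exclusivity calling well defined.
#'
#' @slot coefficients numeric matrix, transcripts x cell types, >= 0.
#' @export
setClass("CoefficientMatrix", representation(coefficients = "matrix"))

setValidity("CoefficientMatrix", function(object) {
  m <- object@coefficients
  msgs <- character()
  if (!is.numeric(m)) return("coefficients must be a numeric matrix")
  if (any(!is.finite(m))) msgs <- c(msgs, "coefficients must all be finite")
  else if (any(m < 0)) msgs <- c(msgs, "coefficients must be non-negative")
  msgs <- c(msgs, .checkDimnames(m, "transcript", "cell-type"))
  if (length(msgs)) msgs else TRUE
})

#' Construct a CoefficientMatrix
#'
#' @param coefficients numeric matrix, transcripts x cell types, with
#'   rownames (transcript ids) and colnames (cell types); non-negative.
#' @return A \linkS4class{CoefficientMatrix}.
#' @export
CoefficientMatrix <- function(coefficients) {
  coefficients <- as.matrix(coefficients)
  storage.mode(coefficients) <- "double"
  new("CoefficientMatrix", coefficients = coefficients)
}

#' NNLSSolution: one solved non-negative least squares instance
#'
#' @slot beta non-negative coefficient vector (zeros are exact).
#' @slot residualNorm Euclidean norm of the residual at the optimum.
#' @slot activeSet integer indices of the coefficients pinned at zero.
#' @slot iterations number of outer (variable-introduction) iterations.
#' @export
setClass("NNLSSolution",
         representation(beta = "numeric", residualNorm = "numeric",
                        activeSet = "integer", iterations = "integer"))

#' SyntheticTruth: a simulated bulk cohort with known ground truth
#'
#' Result of \code{\link{simulateBulkMixture}}: the true cell-type-specific
#' coefficient matrix, the true per-sample proportions, per-transcript
#' single-cell-type labels (NA for transcripts expressed in all cell types),
#' the noiseless bulk mixture (exactly coefficients x proportions) and the
#' observed bulk after count noise.
#'
#' @slot coefficients \linkS4class{CoefficientMatrix} of true profiles.
#' @slot proportions \linkS4class{ProportionMatrix} of true proportions.
#' @slot specificLabels named character; the single expressing cell type for
#'   cell-type-specific transcripts, NA otherwise.
#' @slot transcriptClass named character, "linear" or "circ" per transcript.
#' @slot bulkNoiseless \linkS4class{ExpressionMatrix}, coefficients x proportions.
#' @slot bulkObserved \linkS4class{ExpressionMatrix}, noisy observation.
#' @slot config the \code{\link{simulationConfig}} list used.
#' @export
setClass("SyntheticTruth",
         representation(coefficients = "CoefficientMatrix",
                        proportions = "ProportionMatrix",
                        specificLabels = "character",
                        transcriptClass = "character",
                        bulkNoiseless = "ExpressionMatrix",
                        bulkObserved = "ExpressionMatrix",
                        config = "list"))

setValidity("SyntheticTruth", function(object) {
  ids <- rownames(object@coefficients@coefficients)
  msgs <- character()
  if (!identical(names(object@specificLabels), ids))
    msgs <- c(msgs, "specificLabels must be named by transcript id, matching coefficients")
  if (!identical(names(object@transcriptClass), ids))
    msgs <- c(msgs, "transcriptClass must be named by transcript id, matching coefficients")
  if (!all(object@transcriptClass %in% c("linear", "circ")))
    msgs <- c(msgs, "transcriptClass entries must be 'linear' or 'circ'")
  if (length(msgs)) msgs else TRUE
})
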