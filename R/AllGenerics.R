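#' @name accessors
#' @title Accessors for circDeconv classes
#' @description Small accessor generics: identifiers, values and unit labels
#'   of the matrix containers, and the components of a simulated truth.
#' @param x an object of the documented classes.
#' @return The corresponding slot content (identifiers as character vectors,
#'   values as numeric matrices).
NULL

#' @rdname accessors
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("unitLabel", function(x) standardGeneric("unitLabel"))
#' @rdname accessors
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))
#' @rdname accessors
#' @export
setGeneric("coefValues", function(x) standardGeneric("coefValues"))
#' @rdname accessors
#' @export
setGeneric("trueCoefficients", function(x) standardGeneric("trueCoefficients"))
#' @rdname accessors
#' @export
setGeneric("trueProportions", function(x) standardGeneric("trueProportions"))
#' @rdname accessors
#' @export
setGeneric("specificLabels", function(x) standardGeneric("specificLabels"))
#' @rdname accessors
#' @export
setGeneric("transcriptClass", function(x) standardGeneric("transcriptClass"))
#' @rdname accessors
#' @export
setGeneric("bulkNoiseless", function(x) standardGeneric("bulkNoiseless"))
#' @rdname accessors
#' @export
setGeneric("bulkObserved", function(x) standardGeneric("bulkObserved"))

#' @rdname accessors
#' @export
setMethod("transcriptIds", "ExpressionMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("unitLabel", "ExpressionMatrix", function(x) x@unitLabel)

#' @rdname accessors
#' @export
setMethod("cellTypes", "ProportionMatrix", function(x) rownames(x@fractions))
#' @rdname accessors
#' @export
setMethod("sampleIds", "ProportionMatrix", function(x) colnames(x@fractions))
#' @rdname accessors
#' @export
setMethod("fractions", "ProportionMatrix", function(x) x@fractions)

#' @rdname accessors
#' @export
setMethod("transcriptIds", "CoefficientMatrix", function(x) rownames(x@coefficients))
#' @rdname accessors
#' @export
setMethod("cellTypes", "CoefficientMatrix", function(x) colnames(x@coefficients))
#' @rdname accessors
#' @export
setMethod("coefValues", "CoefficientMatrix", function(x) x@coefficients)

#' @rdname accessors
#' @export
setMethod("trueCoefficients", "SyntheticTruth", function(x) x@coefficients)
#' @rdname accessors
#' @export
setMethod("trueProportions", "SyntheticTruth", function(x) x@proportions)
#' @rdname accessors
#' @export
setMethod("specificLabels", "SyntheticTruth", function(x) x@specificLabels)
#' @rdname accessors
#' @export
setMethod("transcriptClass", "SyntheticTruth", function(x) x@transcriptClass)
#' @rdname accessors
#' @export
setMethod("bulkNoiseless", "SyntheticTruth", function(x) x@bulkNoiseless)
#' @rdname accessors
#' @export
setMethod("bulkObserved", "SyntheticTruth", function(x) x@bulkObserved)
#' @rdname accessors
#' @export
setMethod("transcriptIds", "SyntheticTruth", function(x) rownames(x@coefficients@coefficients))
#' @rdname accessors
#' @export
setMethod("sampleIds", "SyntheticTruth", function(x) colnames(x@proportions@fractions))
#' @rdname accessors
#' @export
setMethod("cellTypes", "SyntheticTruth", function(x) rownames(x@proportions@fractions))

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d transcripts x %d samples [%s]\n",
              nrow(object@values), ncol(object@values), object@unitLabel))
})

setMethod("show", "ProportionMatrix", function(object) {
  cat(sprintf("ProportionMatrix: %d cell types x %d samples\n",
              nrow(object@fractions), ncol(object@fractions)))
  cat("  cell types:", paste(rownames(object@fractions), collapse = ", "), "\n")
})

setMethod("show", "CoefficientMatrix", function(object) {
  m <- object@coefficients
  cat(sprintf("CoefficientMatrix: %d transcripts x %d cell types (%.1f%% exact zeros)\n",
              nrow(m), ncol(m), 100 * mean(m == 0)))
})

setMethod("show", "NNLSSolution", function(object) {
  cat(sprintf("NNLSSolution: beta = (%s), residual norm %.6g, %d zero-constrained, %d iterations\n",
              paste(signif(object@beta, 6), collapse = ", "),
              object@residualNorm, length(object@activeSet), object@iterations))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d transcripts (%d linear, %d circ), %d cell types, %d samples\n",
              length(object@transcriptClass),
              sum(object@transcriptClass == "linear"),
              sum(object@transcriptClass == "circ"),
              nrow(object@proportions@fractions),
              ncol(object@proportions@fractions)))
  cat(sprintf("  %d cell-type-specific transcripts; noise model: %s\n",
              sum(!is.na(object@specificLabels)),
              object@config$noiseModel))
})
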