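#' Call the exclusively expressing cell type per transcript
#'
#' A transcript is exclusive to a cell type when exactly one coefficient
#' exceeds \code{zeroTol}. The default tolerance is exact 0 because the
#' active-set solver returns exact zeros; a nonzero tolerance is exposed
#' for coefficient matrices imported from other solvers.
#'
#' @param coefficients \linkS4class{CoefficientMatrix}.
#' @param zeroTol coefficients \code{> zeroTol} count as expressed.
#' @return Named character vector: the exclusive cell type, or NA when 0 or
#'   >= 2 cell types are expressed.
#' @export
callExclusive <- function(coefficients, zeroTol = 0) {
  stopifnot(is(coefficients, "CoefficientMatrix"))
  B <- coefValues(coefficients)
  cts <- cellTypes(coefficients)
  out <- apply(B, 1L, function(b) {
    pos <- which(b > zeroTol)
    if (length(pos) == 1L) cts[pos] else NA_character_
  })
  setNames(out, transcriptIds(coefficients))
}

#' Apply the significance filters to exclusivity calls
#'
#' A transcript is significantly cell-type specific when it is exclusive to
#' one cell type and passes two filters on its reconstruction diagnostics:
#' (1) p < \code{alpha} (strict) and (2) R-squared strictly greater than the
#' median R-squared over all transcripts with defined diagnostics in this
#' run. Pass only transcripts of one class (e.g. only circRNAs) so the
#' median is computed within that class. Transcripts with undefined
#' diagnostics fail both filters.
#'
#' @param exclusive named character vector from \code{\link{callExclusive}}.
#' @param diagnostics data.frame from
#'   \code{\link{perTranscriptDiagnostics}} covering every transcript in
#'   \code{exclusive}.
#' @param alpha strict p-value threshold.
#' @return data.frame with columns \code{transcript_id},
#'   \code{exclusive_cell_type}, \code{r_squared}, \code{p_value},
#'   \code{passed_p_filter}, \code{passed_r2_filter}, \code{significant}.
#' @export
applyFilters <- function(exclusive, diagnostics, alpha = 0.05) {
  stopifnot(is.character(exclusive), !is.null(names(exclusive)),
            is.data.frame(diagnostics))
  missing <- setdiff(names(exclusive), diagnostics$transcript_id)
  if (length(missing))
    stop("diagnostics missing for transcript(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  d <- diagnostics[match(names(exclusive), diagnostics$transcript_id), ]
  if (!any(d$defined))
    stop("no transcript has defined diagnostics; median R-squared is undefined")
  defR2 <- d$r_squared[d$defined]
  medR2 <- median(defR2)
  passedP <- d$defined & d$p_value < alpha
  # The median filter selects the upper half of the R-squared distribution
  # (strict >). When the distribution is degenerate -- all defined fits
  # equally good, as on noiseless data where every R-squared is 1 -- there
  # is no upper half to select and the filter is vacuous.
  if (diff(range(defR2)) < 1e-9) passedR2 <- d$defined
  else passedR2 <- d$defined & d$r_squared > medR2
  data.frame(transcript_id = names(exclusive),
             exclusive_cell_type = unname(exclusive),
             r_squared = d$r_squared,
             p_value = d$p_value,
             passed_p_filter = passedP,
             passed_r2_filter = passedR2,
             significant = !is.na(exclusive) & passedP & passedR2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cell-type ontology mapping
#'
#' Maps model-specific cell-type labels onto a shared ontology so that two
#' deconvolution models trained on different single-cell references can be
#' compared. Every model cell type maps to exactly one shared label.
#'
#' @param ... named character entries, \code{modelType = "sharedType"}, or a
#'   single named character vector.
#' @return Named character vector of class \code{CellTypeMap}.
#' @examples
#' cellTypeMap(macrophage = "myeloid", endothelial = "stromal")
#' @export
cellTypeMap <- function(...) {
  args <- list(...)
  m <- if (length(args) == 1L && is.null(names(args)) ) unlist(args) else unlist(args)
  if (is.null(names(m)) || any(!nzchar(names(m))))
    stop("every entry of a cell-type map must be named by the model cell type")
  if (anyDuplicated(names(m)))
    stop("duplicate model cell type(s): ",
         paste(unique(names(m)[duplicated(names(m))]), collapse = ", "))
  structure(as.character(setNames(as.character(m), names(m))),
            names = names(m), class = "CellTypeMap")
}

#' Default cell-type maps for the two reference single-cell ontologies
#'
#' The shared ontology is \{T, B, epithelial, mast, myeloid, stromal\}. The
#' six-cell-type reference (T, B, epithelial, mast, myeloid, stromal) maps
#' identically; the seven-cell-type reference maps macrophages to myeloid
#' and both fibroblasts and endothelial cells to stromal, the published
#' merges for comparing the two model ontologies.
#'
#' @return Named list with elements \code{lee} and \code{li}, each a
#'   \code{\link{cellTypeMap}}.
#' @export
defaultCellTypeMaps <- function() {
  shared <- c("T", "B", "epithelial", "mast", "myeloid", "stromal")
  list(lee = cellTypeMap(setNames(shared, shared)),
       li = cellTypeMap(c(T = "T", B = "B", epithelial = "epithelial",
                          mast = "mast", macrophage = "myeloid",
                          endothelial = "stromal", fibroblast = "stromal")))
}

#' Load a cell-type map from YAML
#'
#' @param path YAML file mapping model cell types to shared labels.
#' @return A \code{\link{cellTypeMap}}.
#' @export
readCellTypeMap <- function(path) {
  m <- yaml::read_yaml(path)
  cellTypeMap(unlist(m))
}

.mapTypes <- function(types, map, label) {
  used <- unique(types[!is.na(types)])
  unmapped <- setdiff(used, names(map))
  if (length(unmapped))
    stop("unmapped cell type(s) in significant calls of model ", label, ": ",
         paste(unmapped, collapse = ", "))
  out <- unname(map[types])
  out[is.na(types)] <- NA_character_
  out
}

#' Cross-model consensus of cell-type-specific calls
#'
#' A transcript is a consensus call when it is significantly cell-type
#' specific in both models and the two model cell types map to the same
#' shared ontology label. Symmetric in its two arguments.
#'
#' @param callsA,callsB data.frames from \code{\link{applyFilters}}.
#' @param mapA,mapB \code{\link{cellTypeMap}}s covering every cell type
#'   appearing in the significant calls of the respective model.
#' @return data.frame with columns \code{transcript_id}, \code{cell_type}
#'   (shared label), \code{cell_type_a}, \code{cell_type_b}.
#' @export
consensusCalls <- function(callsA, callsB, mapA, mapB) {
  stopifnot(is.data.frame(callsA), is.data.frame(callsB),
            inherits(mapA, "CellTypeMap"), inherits(mapB, "CellTypeMap"))
  sa <- callsA[callsA$significant, , drop = FALSE]
  sb <- callsB[callsB$significant, , drop = FALSE]
  sa$shared <- .mapTypes(sa$exclusive_cell_type, mapA, "A")
  sb$shared <- .mapTypes(sb$exclusive_cell_type, mapB, "B")
  m <- merge(sa[, c("transcript_id", "exclusive_cell_type", "shared")],
             sb[, c("transcript_id", "exclusive_cell_type", "shared")],
             by = "transcript_id", suffixes = c("_a", "_b"))
  m <- m[m$shared_a == m$shared_b, , drop = FALSE]
  out <- data.frame(transcript_id = m$transcript_id,
                    cell_type = m$shared_a,
                    cell_type_a = m$exclusive_cell_type_a,
                    cell_type_b = m$exclusive_cell_type_b,
                    stringsAsFactors = FALSE)
  out[order(out$transcript_id), , drop = FALSE]
}
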