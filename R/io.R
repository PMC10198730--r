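#' Read an expression matrix from a tab-separated file
#'
#' The only accepted dialect is tab-separated UTF-8 with a mandatory header:
#' first column transcript id, remaining columns one per sample. Row order
#' is preserved. Missing values are not permitted; a transcript not detected
#' in a sample must be encoded as 0 upstream.
#'
#' @param path file path.
#' @param unitLabel unit of the stored values (see
#'   \linkS4class{ExpressionMatrix}).
#' @return A validated \linkS4class{ExpressionMatrix}.
#' @seealso \code{\link{writeExpressionMatrix}}
#' @export
readExpressionMatrix <- function(path, unitLabel) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expression file must have a transcript-id column plus >= 1 sample column: ", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  if (anyNA(m)) stop("missing values are not permitted in expression matrices: ", path)
  rownames(m) <- ids
  ExpressionMatrix(m, unitLabel)
}

#' Write an expression matrix as tab-separated text
#'
#' Canonical formatting: header \code{transcript_id} plus sample ids, full
#' precision (up to 15 significant digits), no quoting. \code{read(write(m))}
#' reproduces \code{m} exactly.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(x, path) {
  stopifnot(is(x, "ExpressionMatrix"))
  .writeMatrixTsv(exprValues(x), "transcript_id", path)
}

.writeMatrixTsv <- function(m, idHeader, path) {
  # element-wise formatting: zeros stay literal "0", no column-width padding
  fm <- matrix(vapply(m, function(x)
    format(x, digits = 15, trim = TRUE, scientific = FALSE), character(1L)),
    nrow(m), ncol(m), dimnames = dimnames(m))
  df <- data.frame(id = rownames(m), fm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(idHeader, colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cell-type proportion table (CIBERSORT orientation)
#'
#' Accepts the native orientation of CIBERSORT "Impute Cell Fractions"
#' output: one row per sample (first column the sample/mixture id), one
#' column per cell type, plus optional diagnostic columns which are dropped
#' by name. The table is transposed into the internal cell types x samples
#' orientation and each sample's fractions are checked to sum to 1 within
#' 1e-6 (or renormalized when \code{renormalize = TRUE}).
#'
#' @param path file path (tab-separated with header).
#' @param renormalize divide each sample's fractions by their sum instead of
#'   requiring an exact sum of 1.
#' @param dropColumns column names treated as diagnostics and discarded.
#' @return A validated \linkS4class{ProportionMatrix}.
#' @export
readProportions <- function(path, renormalize = FALSE,
                            dropColumns = c("P-value", "Correlation", "RMSE",
                                            "Absolute score", "P.value",
                                            "Absolute.score")) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("proportion file must have a sample-id column plus >= 1 cell-type column: ", path)
  keep <- !(colnames(df) %in% dropColumns)
  keep[1L] <- TRUE
  df <- df[, keep, drop = FALSE]
  samples <- as.character(df[[1L]])
  m <- t(as.matrix(df[, -1L, drop = FALSE]))
  if (!is.numeric(m)) stop("non-numeric fractions in ", path)
  if (anyNA(m)) stop("missing fractions in ", path)
  if (any(m < 0)) stop("negative fraction(s) in ", path)
  colnames(m) <- samples
  ProportionMatrix(m, renormalize = renormalize)
}

#' Write a proportion table in CIBERSORT orientation
#'
#' Samples as rows (header \code{sample_id}), cell types as columns, so the
#' file round-trips through \code{\link{readProportions}}.
#'
#' @param x a \linkS4class{ProportionMatrix}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeProportions <- function(x, path) {
  stopifnot(is(x, "ProportionMatrix"))
  .writeMatrixTsv(t(fractions(x)), "sample_id", path)
}

.DE_GROUPS <- c("PvN", "MvN", "MvP")
.DE_TOOLS <- c("edgeR", "CIRIquant", "CircTest")

#' Read a differential-expression result table
#'
#' Tab-separated with header and columns \code{id}, \code{group},
#' \code{logFC}, \code{pvalue} and (optionally, for CIRIquant/CircTest
#' sources) \code{fdr}. Comparison groups are restricted to the three
#' tumor-progression contrasts PvN (primary vs normal), MvN (metastasis vs
#' normal) and MvP (metastasis vs primary).
#'
#' @param path file path.
#' @param sourceTool one of \code{"edgeR"}, \code{"CIRIquant"},
#'   \code{"CircTest"}; recorded in the \code{source_tool} column.
#' @return A data.frame with columns \code{transcript_id},
#'   \code{comparison_group}, \code{log_fc}, \code{p_value}, \code{fdr}
#'   (NA when absent) and \code{source_tool}. An empty table (header only)
#'   is returned as a zero-row data.frame.
#' @export
readDETable <- function(path, sourceTool) {
  sourceTool <- match.arg(sourceTool, .DE_TOOLS)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("id", "group", "logFC", "pvalue")
  if (!all(need %in% colnames(df)))
    stop("DE table must have columns id, group, logFC, pvalue: ", path)
  if (!"fdr" %in% colnames(df)) {
    if (sourceTool == "edgeR")
      stop("edgeR-style DE table requires an fdr column: ", path)
    df$fdr <- NA_real_
  }
  out <- data.frame(transcript_id = as.character(df$id),
                    comparison_group = as.character(df$group),
                    log_fc = as.numeric(df$logFC),
                    p_value = as.numeric(df$pvalue),
                    fdr = as.numeric(df$fdr),
                    source_tool = rep(sourceTool, nrow(df)),
                    stringsAsFactors = FALSE)
  validateDETable(out)
}

#' Validate a differential-expression result table
#'
#' @param t data.frame in the layout returned by \code{\link{readDETable}}.
#' @return \code{t}, invisibly validated (errors on violation).
#' @export
validateDETable <- function(t) {
  stopifnot(is.data.frame(t))
  need <- c("transcript_id", "comparison_group", "log_fc", "p_value", "fdr",
            "source_tool")
  if (!all(need %in% colnames(t)))
    stop("DE table missing column(s): ",
         paste(setdiff(need, colnames(t)), collapse = ", "))
  if (nrow(t) == 0L) return(t)
  bad <- setdiff(unique(t$comparison_group), .DE_GROUPS)
  if (length(bad))
    stop("unknown comparison group label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(.DE_GROUPS, collapse = ", "), ")")
  if (any(!is.finite(t$p_value)) || any(t$p_value < 0 | t$p_value > 1))
    stop("p_value outside [0, 1]")
  ok_fdr <- is.na(t$fdr) | (t$fdr >= 0 & t$fdr <= 1)
  if (!all(ok_fdr)) stop("fdr outside [0, 1]")
  if (any(!is.finite(t$log_fc))) stop("non-finite log_fc")
  t
}

#' Write a coefficient matrix as tab-separated text
#'
#' Exact zeros from the active-set solver are written literally as 0.
#'
#' @param x a \linkS4class{CoefficientMatrix}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeCoefficientMatrix <- function(x, path) {
  stopifnot(is(x, "CoefficientMatrix"))
  .writeMatrixTsv(coefValues(x), "transcript_id", path)
}

#' Read a coefficient matrix written by \code{\link{writeCoefficientMatrix}}
#'
#' @param path file path.
#' @return A \linkS4class{CoefficientMatrix}.
#' @export
readCoefficientMatrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  CoefficientMatrix(m)
}
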