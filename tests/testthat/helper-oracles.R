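# Brute-force NNLS oracle: enumerate all 2^k supports, solve unconstrained
# least squares on each, keep the best feasible (elementwise >= 0) solution.
# Independent of the active-set code path.
bruteForceNNLS <- function(X, y) {
  k <- ncol(X)
  best <- list(objective = sum(y^2), beta = numeric(k))   # empty support
  for (mask in seq_len(2^k - 1)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1))) > 0L)
    z <- qr.coef(qr(X[, S, drop = FALSE]), y)
    if (anyNA(z) || any(z < 0)) next
    beta <- numeric(k)
    beta[S] <- z
    obj <- sum((y - X %*% beta)^2)
    if (obj < best$objective) best <- list(objective = obj, beta = beta)
  }
  best
}

nnlsObjective <- function(X, y, beta) sum((y - X %*% beta)^2)

# small builders ------------------------------------------------------------
exprMat <- function(values, unit = "normalized_backspliced_reads",
                    transcripts = sprintf("t%d", seq_len(nrow(values))),
                    samples = sprintf("s%d", seq_len(ncol(values)))) {
  values <- as.matrix(values)
  dimnames(values) <- list(transcripts, samples)
  ExpressionMatrix(values, unit)
}

propMat <- function(fractions,
                    types = sprintf("ct%d", seq_len(nrow(fractions))),
                    samples = sprintf("s%d", seq_len(ncol(fractions)))) {
  fractions <- as.matrix(fractions)
  dimnames(fractions) <- list(types, samples)
  ProportionMatrix(fractions)
}

coefMat <- function(coefficients,
                    transcripts = sprintf("t%d", seq_len(nrow(coefficients))),
                    types = sprintf("ct%d", seq_len(ncol(coefficients)))) {
  coefficients <- as.matrix(coefficients)
  dimnames(coefficients) <- list(transcripts, types)
  CoefficientMatrix(coefficients)
}

deRow <- function(id, group, logFC, p, fdr = NA_real_, tool = "edgeR") {
  data.frame(transcript_id = id, comparison_group = group, log_fc = logFC,
             p_value = p, fdr = fdr, source_tool = tool,
             stringsAsFactors = FALSE)
}

# a minimal applyFilters()-shaped call table for consensus tests
callRow <- function(id, type, significant = TRUE) {
  data.frame(transcript_id = id, exclusive_cell_type = type,
             r_squared = 0.9, p_value = 1e-4,
             passed_p_filter = significant, passed_r2_filter = significant,
             significant = significant, stringsAsFactors = FALSE)
}
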