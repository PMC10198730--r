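#' Perturb a proportion matrix by Dirichlet resampling
#'
#' Emulates estimation error in cell-type proportions: each sample's column
#' p is replaced by a draw from Dirichlet(concentration * p). Larger
#' concentrations give smaller perturbations; the expectation is the
#' original column.
#'
#' @param proportions a \linkS4class{ProportionMatrix}.
#' @param concentration positive scalar.
#' @return A perturbed \linkS4class{ProportionMatrix}.
#' @export
perturbProportions <- function(proportions, concentration = 100) {
  stopifnot(is(proportions, "ProportionMatrix"), concentration > 0)
  P <- fractions(proportions)
  out <- apply(P, 2L, function(p) {
    g <- rgamma(length(p), shape = concentration * p)
    if (sum(g) == 0) p else g / sum(g)
  })
  dimnames(out) <- dimnames(P)
  ProportionMatrix(out)
}

#' Configuration of an end-to-end run
#'
#' Each of the two models is driven either by a simulation (one shared
#' simulated cohort; per-model proportion inputs) or by file paths. Exactly
#' one of \code{simulation} / \code{bulkPath} must be supplied.
#'
#' @param simulation a \code{\link{simulationConfig}}, or NULL for file
#'   input.
#' @param bulkPath path to a bulk expression TSV (file mode).
#' @param bulkUnit unit label of the bulk file.
#' @param proportionsPathA,proportionsPathB per-model proportion TSVs
#'   (CIBERSORT orientation); in simulation mode NULL means the true
#'   simulated proportions.
#' @param proportionPerturbation in simulation mode, Dirichlet resampling
#'   concentration applied (with distinct substreams) to each model's copy
#'   of the true proportions; NULL (default) uses the exact truth for both
#'   models.
#' @param mapA,mapB \code{\link{cellTypeMap}}s for the consensus stage;
#'   default identity maps over the cell types observed.
#' @param alpha significance level for the specificity filters.
#' @param specificityClass which transcript class the specificity stage
#'   runs on in simulation mode ("circ", "linear" or "all"); the median-R2
#'   filter is computed within this class.
#' @param outDir optional output directory; when given, every stage output
#'   is written there as TSV plus a JSON run manifest.
#' @param seed integer seed governing all randomness of the run.
#' @return Validated list of class \code{RunConfig}.
#' @export
runConfig <- function(simulation = NULL, bulkPath = NULL,
                      bulkUnit = "normalized_backspliced_reads",
                      proportionsPathA = NULL, proportionsPathB = NULL,
                      proportionPerturbation = NULL,
                      mapA = NULL, mapB = NULL, alpha = 0.05,
                      specificityClass = c("circ", "linear", "all"),
                      outDir = NULL, seed = 1L) {
  specificityClass <- match.arg(specificityClass)
  if (is.null(simulation) == is.null(bulkPath))
    stop("supply exactly one of 'simulation' or 'bulkPath'")
  if (!is.null(bulkPath) && is.null(proportionsPathA))
    stop("file mode requires proportionsPathA (model A proportions)")
  structure(list(simulation = simulation, bulkPath = bulkPath,
                 bulkUnit = bulkUnit,
                 proportionsPathA = proportionsPathA,
                 proportionsPathB = proportionsPathB,
                 proportionPerturbation = proportionPerturbation,
                 mapA = mapA, mapB = mapB, alpha = alpha,
                 specificityClass = specificityClass,
                 outDir = outDir, seed = as.integer(seed)),
            class = "RunConfig")
}

.identityMap <- function(types) cellTypeMap(setNames(types, types))

.stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full deconvolution workflow
#'
#' Stages: obtain inputs (simulate or read), fit per-transcript NNLS for
#' models A and B, reconstruct and benchmark each model, call exclusivity
#' and apply the significance filters (within the configured transcript
#' class), and form the cross-model consensus. Deterministic given
#' \code{config$seed}; all randomness (simulation, proportion perturbation)
#' is drawn from seeds derived from it.
#'
#' @param config a \code{\link{runConfig}}.
#' @return List with elements \code{truth} (NULL in file mode),
#'   \code{models} (per model: proportions, coefficients, reconstruction,
#'   transcript/sample diagnostics, benchmark summary, specificity calls)
#'   and \code{consensus}, plus a \code{summary} of stage counts. When
#'   \code{config$outDir} is set, stage outputs and a \code{manifest.json}
#'   are written there.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))

  # --- inputs -------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- config$seed
    truth <- simulateBulkMixture(sim)
    bulk <- bulkObserved(truth)
    propA <- propB <- trueProportions(truth)
    if (!is.null(config$proportionPerturbation)) {
      if (exists(".Random.seed", envir = globalenv())) {
        oldSeed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
      }
      set.seed(config$seed * 2L + 1L)
      propA <- perturbProportions(propA, config$proportionPerturbation)
      set.seed(config$seed * 2L + 2L)
      propB <- perturbProportions(propB, config$proportionPerturbation)
    }
    cls <- transcriptClass(truth)
    .stageLog("simulate", "%d transcripts x %d samples, noise=%s",
              nrow(exprValues(bulk)), ncol(exprValues(bulk)), sim$noiseModel)
  } else {
    bulk <- readExpressionMatrix(config$bulkPath, config$bulkUnit)
    propA <- readProportions(config$proportionsPathA)
    propB <- if (!is.null(config$proportionsPathB))
      readProportions(config$proportionsPathB) else propA
    cls <- setNames(rep("all", nrow(exprValues(bulk))), transcriptIds(bulk))
    .stageLog("input", "%d transcripts x %d samples from %s",
              nrow(exprValues(bulk)), ncol(exprValues(bulk)), config$bulkPath)
  }
  if (is.null(config$proportionsPathB) && is.null(config$simulation))
    .stageLog("input", "model B proportions not supplied; reusing model A")

  # --- per-model fit, benchmark, specificity ------------------------------
  specIds <- if (config$specificityClass == "all" || is.null(truth))
    transcriptIds(bulk) else names(cls)[cls == config$specificityClass]
  if (length(specIds) == 0L)
    stop("no transcripts of class '", config$specificityClass,
         "' for the specificity stage")

  fitModel <- function(label, prop) {
    coefs <- fitCellTypeExpression(bulk, prop)
    recon <- reconstructBulk(coefs, prop, unitLabel(bulk))
    td <- perTranscriptDiagnostics(recon, bulk)
    sd_ <- perSampleDiagnostics(recon, bulk)
    .stageLog("fit", "model %s: %d/%d transcripts with defined diagnostics",
              label, sum(td$defined), nrow(td))
    exclusive <- callExclusive(coefs)[specIds]
    calls <- applyFilters(exclusive,
                          td[td$transcript_id %in% specIds, , drop = FALSE],
                          alpha = config$alpha)
    .stageLog("specificity", "model %s: %d exclusive, %d significant",
              label, sum(!is.na(exclusive)), sum(calls$significant))
    list(proportions = prop, coefficients = coefs, reconstruction = recon,
         transcriptDiagnostics = td, sampleDiagnostics = sd_,
         benchmark = benchmarkSummary(td, sd_, config$alpha),
         specificity = calls)
  }
  models <- list(A = fitModel("A", propA), B = fitModel("B", propB))

  mapA <- if (is.null(config$mapA)) .identityMap(cellTypes(propA)) else config$mapA
  mapB <- if (is.null(config$mapB)) .identityMap(cellTypes(propB)) else config$mapB
  consensus <- consensusCalls(models$A$specificity, models$B$specificity,
                              mapA, mapB)
  .stageLog("consensus", "%d consensus cell-type-specific transcripts",
            nrow(consensus))

  summary <- list(
    n_transcripts = nrow(exprValues(bulk)),
    n_samples = ncol(exprValues(bulk)),
    n_specificity_class = length(specIds),
    n_exclusive_a = sum(!is.na(models$A$specificity$exclusive_cell_type)),
    n_exclusive_b = sum(!is.na(models$B$specificity$exclusive_cell_type)),
    n_significant_a = sum(models$A$specificity$significant),
    n_significant_b = sum(models$B$specificity$significant),
    n_consensus = nrow(consensus),
    seed = config$seed)

  result <- list(truth = truth, models = models, consensus = consensus,
                 summary = summary)
  if (!is.null(config$outDir)) .writeRunOutputs(result, bulk, config)
  result
}

.writeRunOutputs <- function(result, bulk, config) {
  dir <- config$outDir
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  writeExpressionMatrix(bulk, file.path(dir, "bulk.tsv"))
  for (m in names(result$models)) {
    mod <- result$models[[m]]
    writeCoefficientMatrix(mod$coefficients,
                           file.path(dir, sprintf("coefficients_%s.tsv", m)))
    writeProportions(mod$proportions,
                     file.path(dir, sprintf("proportions_%s.tsv", m)))
    write.table(mod$transcriptDiagnostics,
                file.path(dir, sprintf("transcript_diagnostics_%s.tsv", m)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(mod$sampleDiagnostics,
                file.path(dir, sprintf("sample_diagnostics_%s.tsv", m)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(mod$specificity,
                file.path(dir, sprintf("specificity_%s.tsv", m)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(result$consensus, file.path(dir, "consensus.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(result$summary,
                list(benchmark_a = result$models$A$benchmark,
                     benchmark_b = result$models$B$benchmark))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
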