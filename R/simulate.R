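.DEFAULT_CELL_TYPES <- c("T", "B", "epithelial", "mast", "myeloid", "stromal")

#' Configuration for the synthetic bulk-mixture generator
#'
#' Defaults emulate the statistical regime of a matched tumor cohort: 6
#' tumor-microenvironment cell types, 30 samples, symmetric Dirichlet
#' per-sample proportions, log-normal non-negative cell-type profiles
#' scaled so the upper quartile of per-transcript mean bulk abundance is
#' about 1.68 (the TPM scale of expressed linear genes), a circRNA block
#' about 420-fold lower (upper quartile about 0.004 normalized backspliced
#' reads), negative-binomial count noise with dispersion 0.1, and library
#' sizes of 15-25 million reads.
#'
#' @param nCellTypes number of cell types (>= 2); named from the default
#'   TME ontology when <= 6.
#' @param nSamples number of samples; a warning (not an error) is issued
#'   when below \code{nCellTypes} (underdetermined design).
#' @param nLinear,nCirc number of linear genes / circRNAs.
#' @param specificFraction fraction of transcripts (per class) expressed in
#'   exactly one cell type, in [0, 1].
#' @param dirichletAlpha positive Dirichlet concentration(s), recycled to
#'   \code{nCellTypes}.
#' @param linearScale global scale of the linear block (0.84 puts the upper
#'   quartile of mean bulk at about 1.68 for log-normal(0,1) profiles).
#' @param circAbundanceScale multiplier for the circRNA block relative to
#'   the linear scale (default 1/420, the observed gene/circRNA abundance
#'   gap on the per-million scale).
#' @param noiseModel \code{"none"}, \code{"poisson"} or
#'   \code{"negative_binomial"}.
#' @param nbDispersion negative-binomial dispersion (variance = mu +
#'   dispersion * mu^2).
#' @param librarySizeRange min/max total reads per sample.
#' @param lnormMeanlog,lnormSdlog parameters of the log-normal profile
#'   draws.
#' @param seed integer seed; the whole draw is reproducible from it.
#' @return Validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nCellTypes = 6L, nSamples = 30L,
                             nLinear = 200L, nCirc = 200L,
                             specificFraction = 0.3,
                             dirichletAlpha = 1,
                             linearScale = 0.84,
                             circAbundanceScale = 1 / 420,
                             noiseModel = c("negative_binomial", "poisson",
                                            "none"),
                             nbDispersion = 0.1,
                             librarySizeRange = c(15e6, 25e6),
                             lnormMeanlog = 0, lnormSdlog = 1,
                             seed = 1L) {
  noiseModel <- match.arg(noiseModel)
  stopifnot(nCellTypes >= 2L, nLinear >= 0L, nCirc >= 0L,
            nLinear + nCirc >= 1L, nSamples >= 2L,
            specificFraction >= 0, specificFraction <= 1,
            all(dirichletAlpha > 0), linearScale > 0,
            circAbundanceScale > 0, nbDispersion > 0,
            length(librarySizeRange) == 2L, all(librarySizeRange > 0),
            librarySizeRange[1L] <= librarySizeRange[2L])
  alpha <- rep_len(dirichletAlpha, nCellTypes)
  structure(list(nCellTypes = as.integer(nCellTypes),
                 nSamples = as.integer(nSamples),
                 nLinear = as.integer(nLinear), nCirc = as.integer(nCirc),
                 specificFraction = specificFraction,
                 dirichletAlpha = alpha,
                 linearScale = linearScale,
                 circAbundanceScale = circAbundanceScale,
                 noiseModel = noiseModel, nbDispersion = nbDispersion,
                 librarySizeRange = as.numeric(librarySizeRange),
                 lnormMeanlog = lnormMeanlog, lnormSdlog = lnormSdlog,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = length(alpha))
  sweep(g, 2L, colSums(g), "/")
}

#' Simulate a bulk cohort with known cell-type-specific ground truth
#'
#' Draws per-sample proportions from a Dirichlet, non-negative cell-type
#' profiles from a log-normal (a \code{specificFraction} of transcripts per
#' class get support in exactly one uniformly chosen cell type; the rest
#' are expressed in all cell types), forms the noiseless bulk as the exact
#' matrix product coefficients x proportions, and observes it under the
#' chosen count-noise model: counts are drawn at mean value x (library
#' size / 1e6) and divided back by that factor, so the observed matrix stays
#' on the normalized per-million scale with expectation equal to the
#' noiseless bulk. One shared proportions matrix serves both the linear and
#' circRNA blocks.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return A \linkS4class{SyntheticTruth}. Fully reproducible from
#'   \code{config$seed} (the caller's RNG state is restored on exit).
#' @export
simulateBulkMixture <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  }
  set.seed(config$seed)
  k <- config$nCellTypes
  cts <- if (k <= length(.DEFAULT_CELL_TYPES)) .DEFAULT_CELL_TYPES[seq_len(k)]
         else paste0("celltype", seq_len(k))
  samples <- sprintf("sample%02d", seq_len(config$nSamples))
  if (config$nSamples < k)
    warning("nSamples < nCellTypes: the design matrix is underdetermined")

  P <- .rdirichlet(config$nSamples, config$dirichletAlpha)
  dimnames(P) <- list(cts, samples)

  drawBlock <- function(n, prefix, scale) {
    if (n == 0L)
      return(list(B = matrix(0, 0L, k, dimnames = list(character(0), cts)),
                  labels = setNames(character(0), character(0))))
    ids <- sprintf("%s%04d", prefix, seq_len(n))
    B <- matrix(rlnorm(n * k, config$lnormMeanlog, config$lnormSdlog) * scale,
                n, k, dimnames = list(ids, cts))
    labels <- rep(NA_character_, n)
    nSpec <- round(config$specificFraction * n)
    if (nSpec > 0L) {
      specIdx <- sample.int(n, nSpec)
      specType <- sample.int(k, nSpec, replace = TRUE)
      for (i in seq_len(nSpec)) {
        keep <- B[specIdx[i], specType[i]]
        B[specIdx[i], ] <- 0
        B[specIdx[i], specType[i]] <- keep
      }
      labels[specIdx] <- cts[specType]
    }
    list(B = B, labels = setNames(labels, ids))
  }

  lin <- drawBlock(config$nLinear, "gene", config$linearScale)
  circ <- drawBlock(config$nCirc, "circ",
                    config$linearScale * config$circAbundanceScale)
  B <- rbind(lin$B, circ$B)
  labels <- c(lin$labels, circ$labels)
  cls <- setNames(rep(c("linear", "circ"), c(config$nLinear, config$nCirc)),
                  rownames(B))

  noiseless <- B %*% P
  libs <- runif(config$nSamples, config$librarySizeRange[1L],
                config$librarySizeRange[2L])
  depthFactor <- libs / 1e6
  observed <- switch(config$noiseModel,
    none = noiseless,
    poisson = {
      mu <- sweep(noiseless, 2L, depthFactor, "*")
      cnt <- matrix(rpois(length(mu), mu), nrow(mu), ncol(mu))
      sweep(cnt, 2L, depthFactor, "/")
    },
    negative_binomial = {
      mu <- sweep(noiseless, 2L, depthFactor, "*")
      cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nbDispersion),
                    nrow(mu), ncol(mu))
      sweep(cnt, 2L, depthFactor, "/")
    })
  dimnames(observed) <- dimnames(noiseless)

  unit <- if (config$nLinear == 0L) "normalized_backspliced_reads"
          else if (config$nCirc == 0L) "TPM" else "arbitrary"
  new("SyntheticTruth",
      coefficients = CoefficientMatrix(B),
      proportions = ProportionMatrix(P),
      specificLabels = labels,
      transcriptClass = cls,
      bulkNoiseless = ExpressionMatrix(noiseless, unit),
      bulkObserved = ExpressionMatrix(observed, unit),
      config = unclass(config))
}

#' Export a simulated truth as a fixture directory
#'
#' Writes \code{bulk_observed.tsv}, \code{bulk_noiseless.tsv} (expression
#' dialect), \code{proportions.tsv} (CIBERSORT orientation),
#' \code{coefficients.tsv}, \code{truth_labels.tsv} (transcript id, class,
#' specific cell type) and \code{config.yaml} so that every table
#' round-trips through the package readers.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param dir output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
exportFixture <- function(truth, dir) {
  stopifnot(is(truth, "SyntheticTruth"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create fixture directory: ", dir)
  writeExpressionMatrix(bulkObserved(truth), file.path(dir, "bulk_observed.tsv"))
  writeExpressionMatrix(bulkNoiseless(truth), file.path(dir, "bulk_noiseless.tsv"))
  writeProportions(trueProportions(truth), file.path(dir, "proportions.tsv"))
  writeCoefficientMatrix(trueCoefficients(truth), file.path(dir, "coefficients.tsv"))
  lab <- data.frame(transcript_id = names(specificLabels(truth)),
                    class = unname(transcriptClass(truth)),
                    specific_cell_type = ifelse(is.na(specificLabels(truth)),
                                                "none",
                                                unname(specificLabels(truth))),
                    stringsAsFactors = FALSE)
  write.table(lab, file.path(dir, "truth_labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  yaml::write_yaml(truth@config, file.path(dir, "config.yaml"))
  invisible(dir)
}
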