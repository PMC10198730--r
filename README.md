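# circDeconv

Cell-type deconvolution of circular RNA expression from bulk RNA-seq.

Circular RNAs (circRNAs) are invisible to poly(A)-selected single-cell
RNA-seq, so their cell type of origin inside a heterogeneous tissue — a
tumor and its microenvironment, for instance — cannot be observed directly.
circDeconv estimates it indirectly: given bulk circRNA abundance across
samples and per-sample cell-type proportions (estimated from the linear
transcriptome by a tool such as CIBERSORT), it fits, for every transcript
*g*, a non-negative least squares regression

> β̂_g = argmin_{β ≥ 0} ‖ pᵀ β − y_g ‖₂

where *p* (cell types × samples) holds the proportions and *y_g* the
transcript's bulk values. The Lawson–Hanson active-set solver is implemented
from scratch (`nnlsSolve()`); its exact zeros are what make the downstream
call — "this circRNA is expressed in exactly one cell type" — well defined.

The package covers the full workflow:

- **Deconvolution** — `fitCellTypeExpression()`: per-transcript NNLS against
  cell-type proportions (optionally stratified by sample groups).
- **Benchmarking** — `reconstructBulk()` (coefficients × proportions),
  `perTranscriptDiagnostics()` (R², slope-test p-value per transcript),
  `perSampleDiagnostics()` (Pearson r per sample), `benchmarkSummary()`.
- **Specificity calling** — `callExclusive()`, `applyFilters()` (p < 0.05
  and R² above the within-class median), `consensusCalls()` across two
  models under a cell-type ontology map (`defaultCellTypeMaps()` ships the
  six-type and seven-type TME ontologies with the macrophage→myeloid and
  endothelial/fibroblast→stromal merges).
- **Expression preparation** — `countsToTPM()`, `normalizeBacksplice()`
  (backspliced reads per million), `prefilter()` (≥5 TPM in 25% of samples
  for genes; ≥1 raw backspliced read in 15% for circRNAs), `callDE()`
  (p < 0.05, |logFC| > 0, FDR ≤ 0.15), `deConsensus()` (CIRIquant /
  CircTest cross-validation logic).
- **Backsplice junctions** — coordinate-dialect normalization with the 1-bp
  adjustments needed across circRNA databases (`normalizeJunctions()`,
  `toDialect()`, `compareJunctionSets()`).
- **Synthetic data** — `simulateBulkMixture()`: Dirichlet proportions,
  log-normal profiles with a controllable single-cell-type fraction, a
  ~420-fold circRNA abundance gap, and negative-binomial count noise, with
  the full ground truth returned for verification; `exportFixture()` writes
  it in the package's file dialects.
- **Orchestration** — `runPipeline()` / `runConfig()`, plus a thin CLI at
  `inst/scripts/circdeconv.R` with subcommands `simulate`, `deconvolve`,
  `benchmark`, `specificity`, `consensus`, `run`, `junctions-compare`,
  `normalize`, `prefilter`, `de-call`, `de-consensus`.

See the vignette (`vignettes/cell-type-deconvolution.Rmd`) for the model,
its assumptions, the generator's design and known limitations.

## Worked example

```r
library(circDeconv)

truth <- simulateBulkMixture(simulationConfig(seed = 1))
truth
#> SyntheticTruth: 400 transcripts (200 linear, 200 circ), 6 cell types, 30 samples
#>   120 cell-type-specific transcripts; noise model: negative_binomial

fit <- fitCellTypeExpression(bulkObserved(truth), trueProportions(truth))
fit
#> CoefficientMatrix: 400 transcripts x 6 cell types (48.7% exact zeros)

rec  <- reconstructBulk(fit, trueProportions(truth))
diag <- perTranscriptDiagnostics(rec, bulkObserved(truth))
str(benchmarkSummary(diag, perSampleDiagnostics(rec, bulkObserved(truth))))
#> List of 9
#>  $ n_transcripts: int 400
#>  $ n_defined    : int 327
#>  $ n_significant: int 253
#>  $ r2_min       : num 0.0185
#>  $ r2_mean      : num 0.366
#>  $ r2_max       : num 0.892
#>  $ pearson_min  : num 0.89
#>  $ pearson_mean : num 0.944
#>  $ pearson_max  : num 0.974

circIds <- names(transcriptClass(truth))[transcriptClass(truth) == "circ"]
calls <- applyFilters(callExclusive(fit)[circIds],
                      diag[diag$transcript_id %in% circIds, ])
head(calls[calls$significant, ], 3)
#>    transcript_id exclusive_cell_type r_squared     p_value passed_p_filter
#> 12      circ0012                   T 0.1682466 0.024367552            TRUE
#> 27      circ0027                   T 0.1422934 0.039885709            TRUE
#> 32      circ0032                   T 0.2357701 0.006527425            TRUE
#>    passed_r2_filter significant
#> 12             TRUE        TRUE
#> 27             TRUE        TRUE
#> 32             TRUE        TRUE
sum(calls$significant)
#> [1] 14
```

Reading the output: of 400 simulated transcripts, 327 have defined
reconstruction diagnostics and 253 of those are significant at p < 0.05; the
per-sample Pearson correlations (0.89–0.97) say the reconstructed bulk
tracks the observed bulk closely in every sample, while the per-transcript
R² spread reflects the much harder per-transcript problem at circRNA
abundance. Fourteen circRNAs end up called significantly cell-type specific
— each exclusive to one cell type with an above-median, significant fit.
With two proportion sources, `consensusCalls()` (or `runPipeline()`) would
intersect two such call sets on a shared ontology.

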