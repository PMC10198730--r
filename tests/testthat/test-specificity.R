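test_that("exclusivity is the unique positive coefficient", {
  cm <- coefMat(matrix(c(0, 0, 3.2, 0,
                         1.0, 0.5, 0, 0,
                         0, 0, 0, 0), 3, 4, byrow = TRUE),
                transcripts = c("a", "b", "c"))
  ex <- callExclusive(cm)
  expect_identical(unname(ex), c("ct3", NA, NA))

  # tolerance for imported (non-active-set) coefficients
  cm2 <- coefMat(matrix(c(1e-12, 0, 5, 0), 1, 4))
  expect_identical(unname(callExclusive(cm2)), NA_character_)
  expect_identical(unname(callExclusive(cm2, zeroTol = 1e-9)), "ct3")
})

test_that("significance filters use strict p and strict above-median R2", {
  ex <- setNames(rep("ct1", 5), paste0("t", 1:5))
  diag <- data.frame(transcript_id = paste0("t", 1:5),
                     r_squared = c(0.1, 0.2, 0.3, 0.4, 0.5),
                     p_value = c(0.01, 0.01, 0.01, 0.05, 0.01),
                     defined = TRUE)
  calls <- applyFilters(ex, diag)
  # median 0.3: equal-to-median fails the strict > filter
  expect_identical(calls$passed_r2_filter, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  # p = 0.05 fails the strict < filter
  expect_identical(calls$passed_p_filter, c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_identical(calls$significant, c(FALSE, FALSE, FALSE, FALSE, TRUE))

  # non-exclusive transcripts are never significant
  ex2 <- ex; ex2["t5"] <- NA
  expect_false(any(applyFilters(ex2, diag)$significant))

  # undefined diagnostics fail both filters
  diag2 <- diag; diag2$defined[5] <- FALSE
  expect_false(applyFilters(ex, diag2)$significant[5])

  # degenerate R2 distribution: no upper half to select, filter is vacuous
  diag3 <- diag; diag3$r_squared <- 1
  expect_identical(applyFilters(ex, diag3)$significant,
                   c(TRUE, TRUE, TRUE, FALSE, TRUE))

  diag4 <- diag; diag4$defined <- FALSE
  expect_error(applyFilters(ex, diag4), "median")
  expect_error(applyFilters(ex, diag[1:3, ]), "missing")
})

test_that("consensus merges model ontologies through the cell-type map", {
  maps <- defaultCellTypeMaps()
  a <- rbind(callRow("c1", "myeloid"), callRow("c2", "stromal"),
             callRow("c3", "T"), callRow("c4", "B"),
             callRow("c5", "epithelial", significant = FALSE))
  b <- rbind(callRow("c1", "macrophage"), callRow("c2", "endothelial"),
             callRow("c3", "B"), callRow("c4", "B"),
             callRow("c5", "epithelial"), callRow("c9", "fibroblast"))
  cons <- consensusCalls(a, b, maps$lee, maps$li)
  # macrophage -> myeloid and endothelial -> stromal merge; T vs B does not
  expect_identical(cons$transcript_id, c("c1", "c2", "c4"))
  expect_identical(cons$cell_type, c("myeloid", "stromal", "B"))
  # non-significant calls never enter consensus
  expect_false("c5" %in% cons$transcript_id)

  # symmetry and the cardinality bound
  rev <- consensusCalls(b, a, maps$li, maps$lee)
  expect_identical(rev$transcript_id, cons$transcript_id)
  expect_identical(rev$cell_type, cons$cell_type)
  expect_lte(nrow(cons), min(sum(a$significant), sum(b$significant)))

  # unmapped cell type in a significant call is an error
  bad <- rbind(callRow("c1", "astrocyte"))
  expect_error(consensusCalls(bad, b, maps$lee, maps$li), "unmapped.*astrocyte")
})

test_that("cell-type maps load from YAML and reject duplicates", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("macrophage: myeloid", "endothelial: stromal"), yml)
  m <- readCellTypeMap(yml)
  expect_identical(unname(m["macrophage"]), "myeloid")
  expect_error(cellTypeMap(c(a = "x", a = "y")), "duplicate")
})

test_that("noiseless fully-specific cohort is recovered perfectly by consensus", {
  t1 <- simulateBulkMixture(simulationConfig(nLinear = 0, nCirc = 60,
                                             specificFraction = 1,
                                             noiseModel = "none", seed = 71))
  fit <- fitCellTypeExpression(bulkObserved(t1), trueProportions(t1))
  rec <- reconstructBulk(fit, trueProportions(t1))
  diag <- perTranscriptDiagnostics(rec, bulkObserved(t1))
  calls <- applyFilters(callExclusive(fit), diag)
  cons <- consensusCalls(calls, calls,
                         .map <- cellTypeMap(setNames(cellTypes(fit),
                                                      cellTypes(fit))),
                         .map)
  truthLab <- specificLabels(t1)
  expect_identical(sort(cons$transcript_id), sort(names(truthLab)))
  expect_identical(setNames(cons$cell_type, cons$transcript_id)[names(truthLab)],
                   truthLab)
})
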