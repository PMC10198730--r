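test_that("countsToTPM matches the closed form and sums to 1e6", {
  m <- exprMat(matrix(c(10, 10), 2, 1), unit = "raw_counts",
               transcripts = c("g1", "g2"))
  tpm <- countsToTPM(m, c(g1 = 1000, g2 = 2000))
  # rates 0.01 and 0.005 -> 2/3 and 1/3 of a million
  expect_equal(unname(exprValues(tpm)[, 1]), c(2, 1) / 3 * 1e6,
               tolerance = 1e-9)

  # equal counts, equal lengths: symmetry
  m2 <- exprMat(matrix(c(7, 7), 2, 1), unit = "raw_counts")
  tpm2 <- countsToTPM(m2, c(t1 = 500, t2 = 500))
  expect_equal(unname(exprValues(tpm2)[, 1]), c(5e5, 5e5))

  # column sums are 1e6 for every sample with nonzero counts
  set.seed(5)
  m3 <- exprMat(matrix(rpois(60, 20), 10, 6), unit = "raw_counts")
  lens <- setNames(runif(10, 200, 5000), transcriptIds(m3))
  expect_equal(unname(colSums(exprValues(countsToTPM(m3, lens)))),
               rep(1e6, 6), tolerance = 1e-9)

  # all-zero sample stays zero (message, not error)
  m4 <- exprMat(matrix(c(0, 0), 2, 1), unit = "raw_counts")
  expect_message(tpm4 <- countsToTPM(m4, c(t1 = 100, t2 = 100)), "all-zero")
  expect_equal(unname(exprValues(tpm4)[, 1]), c(0, 0))

  expect_error(countsToTPM(m, c(g1 = 0, g2 = 2000)), "positive")
  expect_error(countsToTPM(exprMat(matrix(1, 1, 1)), c(t1 = 100)),
               "raw_counts")
})

test_that("backsplice normalization is reads per million of depth", {
  m <- exprMat(matrix(c(10, 0), 2, 1), unit = "raw_counts")
  norm <- normalizeBacksplice(m, c(s1 = 2e7))
  expect_equal(unname(exprValues(norm)[, 1]), c(0.5, 0))
  expect_identical(unitLabel(norm), "normalized_backspliced_reads")

  # doubling depth halves all values
  norm2 <- normalizeBacksplice(m, c(s1 = 4e7))
  expect_equal(exprValues(norm2), exprValues(norm) / 2)

  expect_error(normalizeBacksplice(m, c(s1 = 0)), "positive")
  expect_error(normalizeBacksplice(m, c(s2 = 1e7)), "missing for sample")
})

test_that("prefilter applies non-strict prevalence thresholds", {
  # circRNA rule on raw backspliced reads: 1 of 4 samples = 0.25 >= 0.15
  raw <- exprMat(matrix(c(1, 0, 0, 0), 1, 4), unit = "raw_counts",
                 transcripts = "circA")
  norm <- exprMat(matrix(c(0.05, 0, 0, 0), 1, 4), transcripts = "circA")
  expect_identical(prefilter(norm, circFilterSpec(), raw = raw, onRaw = TRUE),
                   "circA")

  # linear rule: TPM (5,5,0,0) kept at (>=5, 25%), all-4.9 dropped
  tpm <- exprMat(matrix(c(5, 5, 0, 0, rep(4.9, 4)), 2, 4, byrow = TRUE),
                 unit = "TPM", transcripts = c("gA", "gB"))
  expect_identical(prefilter(tpm, linearFilterSpec()), "gA")

  # exact boundary fractions pass (non-strict >=)
  tpm2 <- exprMat(matrix(c(5, 0, 0, 0), 1, 4), unit = "TPM",
                  transcripts = "gC")
  expect_identical(prefilter(tpm2, filterSpec(5, 0.25)), "gC")

  expect_error(prefilter(norm, circFilterSpec(), onRaw = TRUE), "raw count")
  expect_error(prefilter(norm, circFilterSpec(),
                         raw = exprMat(matrix(1, 1, 2), unit = "raw_counts"),
                         onRaw = TRUE), "match")
})

test_that("prefilter is monotone in both thresholds", {
  set.seed(9)
  m <- exprMat(matrix(rlnorm(200, 0, 2), 20, 10), unit = "TPM")
  kept <- prefilter(m, filterSpec(2, 0.4))
  for (spec in list(filterSpec(1, 0.4), filterSpec(2, 0.2),
                    filterSpec(0.5, 0.1)))
    expect_true(all(kept %in% prefilter(m, spec)))
})

test_that("DE calls honor exact boundary semantics", {
  t <- rbind(deRow("a", "MvP", 0.5, 0.04, 0.10),   # all pass -> up
             deRow("b", "MvP", 0.5, 0.04, 0.151),  # fdr boundary is <= 0.15
             deRow("c", "MvP", 0.0, 0.04, 0.10),   # strict |logFC| > 0
             deRow("d", "MvP", 0.5, 0.05, 0.10),   # strict p < 0.05
             deRow("e", "MvP", -0.5, 0.04, 0.15),  # fdr exactly 0.15 passes
             deRow("f", "PvN", 2.0, 0.001, 0.01))
  called <- callDE(t)
  expect_identical(called$status, c("up", "none", "none", "none", "down", "up"))
})

test_that("cross-tool DE consensus follows direction and group rules", {
  primary <- callDE(rbind(deRow("circ1", "MvP", 1.0, 0.01, 0.05),
                          deRow("circ2", "MvP", 1.0, 0.01, 0.05),
                          deRow("circ3", "MvP", 1.0, 0.01, 0.05),
                          deRow("circ4", "MvP", -1.0, 0.01, 0.05)))
  cq <- rbind(deRow("circ1", "MvP", 0.8, 0.01, tool = "CIRIquant"),   # concurs
              deRow("circ2", "MvP", -0.8, 0.01, tool = "CIRIquant"),  # wrong direction
              deRow("circ4", "MvN", -0.8, 0.01, tool = "CIRIquant"))  # wrong group
  ct <- rbind(deRow("circ2", "MvP", 0, 0.01, tool = "CircTest"),      # concurs (no direction)
              deRow("circ1", "MvP", 0, 0.2, tool = "CircTest"))       # not significant
  res <- deConsensus(primary, cq, ct)
  expect_identical(setNames(res$validation, res$transcript_id),
                   c(circ1 = "ciriquant_only", circ2 = "circtest_only",
                     circ3 = "none", circ4 = "none"))

  # both tests concurring
  cq2 <- deRow("circ2", "MvP", 0.8, 0.01, tool = "CIRIquant")
  expect_identical(deConsensus(primary, cq2, ct)$validation[2], "both")
})
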