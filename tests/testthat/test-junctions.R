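library(GenomicRanges)

test_that("dialect conversion applies the 1-bp adjustments", {
  oneBased <- junctionDialect("db", 1, TRUE)
  bed <- junctionDialect("bed", 0, FALSE)

  gr <- normalizeJunctions(data.frame(chrom = "chr1", start = 100, end = 200),
                           oneBased)
  # canonical 0-based half-open (99, 200) == GRanges [100, 200]
  expect_equal(start(gr), 100)
  expect_equal(end(gr), 200)
  expect_equal(toDialect(gr, bed)$start, 99)
  expect_equal(toDialect(gr, bed)$end, 200)

  # already-canonical input is the identity
  gr2 <- normalizeJunctions(data.frame(chrom = "chr1", start = 99, end = 200),
                            bed)
  expect_equal(c(start(gr2), end(gr2)), c(start(gr), end(gr)))

  # empty interval is rejected
  expect_error(normalizeJunctions(data.frame(chrom = "chr1", start = 5, end = 5),
                                  bed), "empty or inverted")
})

test_that("normalization is idempotent and dialect round-trips are the identity", {
  reg <- defaultDialectRegistry()
  bed <- reg$bed
  set.seed(3)
  raw <- data.frame(chrom = sample(c("chr1", "chr2", "chrX"), 25, TRUE),
                    start = sample.int(1e6, 25),
                    strand = sample(c("+", "-", "."), 25, TRUE))
  raw$end <- raw$start + sample.int(5000, 25)
  gr <- normalizeJunctions(raw, bed)

  # normalize(normalize(j)) = normalize(j): re-reading canonical coords as bed
  gr2 <- normalizeJunctions(toDialect(gr, bed), bed)
  expect_identical(as.data.frame(gr2), as.data.frame(gr))

  # out to any registered dialect and back is the identity
  for (d in reg) {
    back <- normalizeJunctions(toDialect(gr, d), d)
    expect_identical(as.data.frame(back), as.data.frame(gr))
  }
})

test_that("junction set comparison counts overlap after normalization", {
  bed <- junctionDialect("bed", 0, FALSE)
  a <- normalizeJunctions(data.frame(chrom = c("chr1", "chr1", "chr2"),
                                     start = c(99, 500, 10),
                                     end = c(200, 600, 50)), bed)
  b <- normalizeJunctions(data.frame(chrom = c("chr1", "chr3"),
                                     start = c(99, 7),
                                     end = c(200, 70)), bed)
  r <- compareJunctionSets(a, b)
  expect_equal(r[c("a_only", "b_only", "shared")],
               list(a_only = 2, b_only = 1, shared = 1))
  expect_equal(r$n_a, r$a_only + r$shared)
  expect_equal(r$n_b, r$b_only + r$shared)

  # symmetric in the shared count
  expect_equal(compareJunctionSets(b, a)$shared, r$shared)

  # the same junction annotated under two dialects compares as shared
  oneBased <- junctionDialect("db", 1, TRUE)
  a2 <- normalizeJunctions(data.frame(chrom = "chr1", start = 100, end = 200),
                           oneBased)
  b2 <- normalizeJunctions(data.frame(chrom = "chr1", start = 99, end = 200),
                           bed)
  expect_equal(compareJunctionSets(a2, b2)$shared, 1)
})

test_that("strand participates in identity only when requested", {
  bed <- junctionDialect("bed", 0, FALSE)
  a <- normalizeJunctions(data.frame(chrom = "chr1", start = 99, end = 200,
                                     strand = "+"), bed)
  b <- normalizeJunctions(data.frame(chrom = "chr1", start = 99, end = 200,
                                     strand = "-"), bed)
  expect_equal(compareJunctionSets(a, b, matchStrand = TRUE)$shared, 0)
  expect_equal(compareJunctionSets(a, b, matchStrand = FALSE)$shared, 1)
})

test_that("unnormalized inputs are refused", {
  gr <- GRanges("chr1", IRanges::IRanges(100, 200))
  expect_error(compareJunctionSets(gr, gr), "not normalized")
})

test_that("junction files read under a stated dialect; registry extends via YAML", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t200\tj1\t0\t+", "chr2\t10\t50\tj2\t0\t-"), path)
  gr <- readJunctions(path, "bed")
  expect_equal(length(gr), 2L)
  expect_equal(start(gr)[1], 100)

  out <- withr::local_tempfile(fileext = ".bed")
  writeJunctionsBed(gr, out)
  expect_identical(as.data.frame(readJunctions(out, "bed")),
                   as.data.frame(gr))

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("mydb:", "  start_basis: 1", "  end_inclusive: true"), yml)
  reg <- readDialectRegistry(yml)
  expect_true("mydb" %in% names(reg))
  expect_equal(reg$mydb$startBasis, 1L)
  expect_error(readJunctions(path, "nosuch"), "unknown dialect")
})
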