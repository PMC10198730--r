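#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors metadata metadata<- mcols mcols<-
NULL

#' Describe a junction coordinate dialect
#'
#' circRNA databases annotate backsplice-junction boundaries under different
#' coordinate conventions; comparing junction sets across resources requires
#' 1-bp adjustments determined by each source's convention. A dialect is
#' described by its start basis (0 or 1) and whether the end coordinate is
#' inclusive (points at the last base) or exclusive (one past it).
#'
#' @param name dialect name (unique within a registry).
#' @param startBasis 0 or 1.
#' @param endInclusive logical.
#' @return A list of class \code{JunctionDialect}.
#' @examples
#' junctionDialect("bed", 0, FALSE)
#' @export
junctionDialect <- function(name, startBasis, endInclusive) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!startBasis %in% c(0L, 1L)) stop("startBasis must be 0 or 1")
  stopifnot(is.logical(endInclusive), length(endInclusive) == 1L)
  structure(list(name = name, startBasis = as.integer(startBasis),
                 endInclusive = endInclusive),
            class = "JunctionDialect")
}

#' Built-in junction dialect registry
#'
#' Conventions for common circRNA coordinate sources. BED files (including
#' chimeric-alignment BED extracted by STAR and consumed by CIRCexplorer2)
#' are 0-based half-open. Database dumps in "genomic coordinate" style
#' (circBase, circAtlas, CIRI) are listed as 1-based end-inclusive; these
#' entries are documented defaults, not authoritative — override any of
#' them via \code{\link{readDialectRegistry}}.
#'
#' @return Named list of \code{\link{junctionDialect}} objects.
#' @export
defaultDialectRegistry <- function() {
  ds <- list(
    junctionDialect("bed", 0L, FALSE),
    junctionDialect("circexplorer2", 0L, FALSE),
    junctionDialect("circatlas", 1L, TRUE),
    junctionDialect("circbase", 1L, TRUE),
    junctionDialect("ciri", 1L, TRUE),
    junctionDialect("one_based_inclusive", 1L, TRUE))
  setNames(ds, vapply(ds, `[[`, "", "name"))
}

#' Load a junction dialect registry from YAML
#'
#' The file maps dialect names to \code{start_basis} (0/1) and
#' \code{end_inclusive} (true/false). Entries extend/override the built-in
#' registry.
#'
#' @param path YAML file path.
#' @param base registry to extend (default \code{defaultDialectRegistry()}).
#' @return Named list of \code{\link{junctionDialect}} objects.
#' @export
readDialectRegistry <- function(path, base = defaultDialectRegistry()) {
  spec <- yaml::read_yaml(path)
  for (nm in names(spec)) {
    e <- spec[[nm]]
    if (is.null(e$start_basis) || is.null(e$end_inclusive))
      stop("dialect '", nm, "' must define start_basis and end_inclusive")
    base[[nm]] <- junctionDialect(nm, e$start_basis, isTRUE(e$end_inclusive))
  }
  base
}

#' Normalize raw backsplice junctions into the canonical convention
#'
#' Converts raw coordinates given under a stated dialect into the canonical
#' internal convention (BED-style 0-based half-open, held in a GRanges
#' which represents the same interval 1-based closed). Junction identity is
#' the backsplice coordinate pair only; isoform structure is ignored.
#'
#' @param x data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   and optionally \code{strand} (one of +, -, .); or a GRanges whose
#'   coordinates are to be reinterpreted under \code{dialect}.
#' @param dialect a \code{\link{junctionDialect}}.
#' @return A GRanges of normalized junctions, flagged as normalized in its
#'   metadata; strand preserved (\code{.} becomes \code{*}).
#' @examples
#' d <- junctionDialect("db", 1, TRUE)
#' normalizeJunctions(data.frame(chrom = "chr1", start = 100, end = 200), d)
#' @export
normalizeJunctions <- function(x, dialect) {
  stopifnot(inherits(dialect, "JunctionDialect"))
  if (is(x, "GRanges"))
    x <- data.frame(chrom = as.character(seqnames(x)),
                    start = start(x), end = end(x),
                    strand = as.character(strand(x)),
                    stringsAsFactors = FALSE)
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% colnames(x)))
  if (any(!nzchar(as.character(x$chrom)))) stop("empty chrom name")
  s0 <- as.numeric(x$start) - dialect$startBasis
  e0 <- as.numeric(x$end) - dialect$startBasis + as.integer(dialect$endInclusive)
  if (any(s0 < 0)) stop("negative start after conversion from dialect '",
                        dialect$name, "'")
  bad <- which(e0 <= s0)
  if (length(bad))
    stop("empty or inverted interval after conversion from dialect '",
         dialect$name, "' at row(s): ", paste(bad, collapse = ", "))
  strand <- if ("strand" %in% colnames(x)) as.character(x$strand) else rep(".", nrow(x))
  strand[strand == "."] <- "*"
  gr <- GRanges(x$chrom, IRanges(start = s0 + 1, end = e0), strand = strand)
  metadata(gr)$normalized <- TRUE
  gr
}

#' Express normalized junctions in an output dialect
#'
#' Inverse of \code{\link{normalizeJunctions}}: converting out to any
#' dialect and normalizing back is the identity.
#'
#' @param gr GRanges of normalized junctions.
#' @param dialect a \code{\link{junctionDialect}}.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{strand} under the dialect's convention.
#' @export
toDialect <- function(gr, dialect) {
  stopifnot(is(gr, "GRanges"), inherits(dialect, "JunctionDialect"))
  s0 <- start(gr) - 1L   # canonical 0-based half-open
  e0 <- end(gr)
  st <- as.character(strand(gr))
  st[st == "*"] <- "."
  data.frame(chrom = as.character(seqnames(gr)),
             start = s0 + dialect$startBasis,
             end = e0 + dialect$startBasis - as.integer(dialect$endInclusive),
             strand = st, stringsAsFactors = FALSE)
}

#' Read a junction table (BED-like) and normalize it
#'
#' Reads a headerless tab-separated table with columns chrom, start, end and
#' (when present, BED layout) strand in column 6, then normalizes under the
#' given dialect. BED files use \code{dialect = "bed"}.
#'
#' @param path file path.
#' @param dialect a \code{\link{junctionDialect}} or the name of one in
#'   \code{registry}.
#' @param registry dialect registry for name lookup.
#' @return Normalized GRanges (see \code{\link{normalizeJunctions}}).
#' @export
readJunctions <- function(path, dialect = "bed",
                          registry = defaultDialectRegistry()) {
  if (is.character(dialect)) {
    if (!dialect %in% names(registry))
      stop("unknown dialect '", dialect, "'; registered: ",
           paste(names(registry), collapse = ", "))
    dialect <- registry[[dialect]]
  }
  df <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("junction file needs >= 3 columns: ", path)
  raw <- data.frame(chrom = as.character(df[[1L]]),
                    start = as.numeric(df[[2L]]),
                    end = as.numeric(df[[3L]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 6L) raw$strand <- as.character(df[[6L]])
  normalizeJunctions(raw, dialect)
}

#' Write normalized junctions as BED
#'
#' @param gr normalized GRanges.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeJunctionsBed <- function(gr, path) {
  df <- toDialect(gr, junctionDialect("bed", 0L, FALSE))
  out <- data.frame(df$chrom, df$start, df$end, ".", 0L, df$strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

.junctionKeys <- function(gr, matchStrand) {
  k <- paste0(as.character(seqnames(gr)), ":", start(gr) - 1L, "-", end(gr))
  if (matchStrand) k <- paste0(k, ":", as.character(strand(gr)))
  k
}

.assertNormalized <- function(gr, label) {
  if (!is(gr, "GRanges") || !isTRUE(metadata(gr)$normalized))
    stop("junction set '", label, "' is not normalized; run normalizeJunctions() first")
}

#' Compare two backsplice-junction sets
#'
#' Junctions are compared as sets of unique backsplice coordinate pairs
#' (chrom, start, end) after normalization to the canonical convention —
#' exact equality, optionally also on strand. Strand matching defaults to
#' off. Counts satisfy \code{|a| = a_only + shared} and
#' \code{|b| = b_only + shared} on the deduplicated sets.
#'
#' @param a,b normalized GRanges (from \code{\link{normalizeJunctions}} or
#'   \code{\link{readJunctions}}).
#' @param matchStrand include strand in junction identity.
#' @return List with counts \code{a_only}, \code{b_only}, \code{shared},
#'   \code{n_a}, \code{n_b} (unique junction counts) and \code{sharedJunctions}
#'   (GRanges of the shared junctions).
#' @export
compareJunctionSets <- function(a, b, matchStrand = FALSE) {
  .assertNormalized(a, "a")
  .assertNormalized(b, "b")
  ka <- unique(.junctionKeys(a, matchStrand))
  kb <- unique(.junctionKeys(b, matchStrand))
  sharedKeys <- intersect(ka, kb)
  keysA <- .junctionKeys(a, matchStrand)
  sharedGr <- a[!duplicated(keysA) & keysA %in% sharedKeys]
  metadata(sharedGr)$normalized <- TRUE
  list(a_only = length(ka) - length(sharedKeys),
       b_only = length(kb) - length(sharedKeys),
       shared = length(sharedKeys),
       n_a = length(ka), n_b = length(kb),
       sharedJunctions = sharedGr)
}
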