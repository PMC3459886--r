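#' Construct a CoverageTrack
#'
#' @param ranges a \code{GRanges} of covered bases (any representation;
#'   reduced internally to sorted, disjoint, maximally merged intervals).
#' @param sampleId sample identifier.
#' @return a \linkS4class{CoverageTrack}.
#' @export
CoverageTrack <- function(ranges = GRanges(), sampleId = "sample") {
    new("CoverageTrack", ranges = GenomicRanges::reduce(sort(ranges)),
        sampleId = as.character(sampleId))
}

#' @describeIn CoverageTrack-class total number of covered bases.
#' @param x a \code{CoverageTrack}.
#' @export
totalCovered <- function(x) {
    stopifnot(is(x, "CoverageTrack"))
    sum(as.numeric(width(x@ranges)))
}

setMethod("show", "CoverageTrack", function(object) {
    cat("CoverageTrack '", object@sampleId, "': ",
        length(object@ranges), " intervals, ",
        format(totalCovered(object), big.mark = ","), " covered bases\n",
        sep = "")
})

#' Read per-sample coverage
#'
#' Reads the positions covered by at least one read, either from a
#' three-column per-base depth dump (\code{chrom<TAB>pos<TAB>depth}, pos
#' 1-based, as produced by \command{samtools depth}) or from a BED file of
#' covered intervals (0-based, half-open). Positions with depth 0 are not
#' covered; adjacent covered positions are merged.
#'
#' @param path input file.
#' @param format \code{"depth_tsv"} or \code{"bed"}.
#' @param sampleId sample identifier for the returned track.
#' @return a \linkS4class{CoverageTrack}.
#' @examples
#' f <- tempfile()
#' writeLines(c("chr1\t5\t3", "chr1\t6\t1", "chr1\t7\t2"), f)
#' readCoverage(f, "depth_tsv")
#' @export
readCoverage <- function(path, format = c("depth_tsv", "bed"),
                         sampleId = basename(path)) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("coverage file not found: ", path)
    if (format == "bed") {
        gr <- rtracklayer::import(path, format = "BED")
        return(CoverageTrack(gr, sampleId))
    }
    lines <- readLines(path)
    keepLine <- nzchar(lines)
    lineNo <- which(keepLine)
    lines <- lines[keepLine]
    if (!length(lines)) return(CoverageTrack(GRanges(), sampleId))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 3L))
        stop("malformed depth row (fewer than 3 fields) at line ",
             lineNo[which(nf < 3L)[1L]])
    chrom <- vapply(parts, `[[`, character(1), 1L)
    pos <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2L)))
    depth <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
    bad <- which(is.na(pos) | is.na(depth) | pos < 1L)
    if (length(bad))
        stop("malformed depth row (non-numeric or invalid pos/depth) at line ",
             lineNo[bad[1L]])
    keep <- depth >= 1
    gr <- GRanges(chrom[keep], IRanges::IRanges(start = pos[keep], width = 1L))
    CoverageTrack(gr, sampleId)
}

#' Construct a CommonCoverage
#'
#' @param bases non-negative number of bases covered in both samples.
#' @param pairId identifier of the comparison.
#' @return a \linkS4class{CommonCoverage}.
#' @export
CommonCoverage <- function(bases, pairId = "pair") {
    new("CommonCoverage", pairId = as.character(pairId),
        bases = as.numeric(bases))
}

#' @rdname CommonCoverage-class
#' @export
setMethod("coveredBases", "CommonCoverage", function(x) x@bases)

setMethod("show", "CommonCoverage", function(object) {
    cat("CommonCoverage '", object@pairId, "': ",
        format(object@bases, big.mark = ","), " bases\n", sep = "")
})

#' Common coverage of two samples
#'
#' Counts the reference bases covered (depth >= 1) in both samples of a
#' comparison, optionally restricted to a target region set (e.g. the
#' capture design). This is the normalizer that makes call counts from
#' comparisons with different searchable space commensurable.
#'
#' @param a,b \linkS4class{CoverageTrack}s of the two samples.
#' @param restrict optional \code{GRanges}; when supplied, only bases inside
#'   these intervals are counted.
#' @param pairId identifier for the resulting comparison.
#' @return a \linkS4class{CommonCoverage}.
#' @examples
#' a <- CoverageTrack(GenomicRanges::GRanges("chr1:1-100"))
#' b <- CoverageTrack(GenomicRanges::GRanges("chr1:51-150"))
#' coveredBases(commonCoverage(a, b))  # 50
#' @export
commonCoverage <- function(a, b, restrict = NULL, pairId = "pair") {
    stopifnot(is(a, "CoverageTrack"), is(b, "CoverageTrack"))
    common <- GenomicRanges::intersect(a@ranges, b@ranges,
                                       ignore.strand = TRUE)
    if (!is.null(restrict)) {
        stopifnot(is(restrict, "GRanges"))
        common <- GenomicRanges::intersect(
            common, GenomicRanges::reduce(restrict), ignore.strand = TRUE)
    }
    CommonCoverage(sum(as.numeric(width(common))), pairId)
}
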