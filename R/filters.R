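#' Call-set filters
#'
#' Generic post-filters applied to call sets before confidence assignment.
#' All three filters are idempotent and commute with one another; each
#' appends its in/out counts to the provenance log.
#'
#' \describe{
#'   \item{filterNormalCoverage}{keeps tumor-vs-normal calls whose locus
#'     has non-zero coverage in the normal sample, removing calls that only
#'     look somatic because the normal locus was never sequenced.}
#'   \item{filterBlacklist}{removes calls falling inside blacklist regions
#'     (e.g. repetitive sequence from a RepeatMasker track). Regions come
#'     as a \code{GRanges} or a BED file path; BED intervals are 0-based
#'     half-open, so a 1-based call position p lies in [start, end) iff
#'     start <= p-1 < end (the conversion is handled by the BED importer).}
#'   \item{filterMinProperty}{keeps calls whose named quality property is
#'     at or above a threshold, e.g. a somatic score of 30 or more.}
#' }
#'
#' @param calls a \linkS4class{CallSet}.
#' @param normalCov \linkS4class{CoverageTrack} of the normal sample.
#' @return a filtered \linkS4class{CallSet}.
#' @rdname filters
#' @export
filterNormalCoverage <- function(calls, normalCov) {
    stopifnot(is(calls, "CallSet"), is(normalCov, "CoverageTrack"))
    if (comparison(calls) != "tumor_normal")
        stop("normal-coverage filtering applies to tumor_normal call sets")
    n0 <- length(calls)
    hit <- IRanges::overlapsAny(calls@ranges, normalCov@ranges,
                                ignore.strand = TRUE)
    calls <- calls[hit]
    .logStep(calls, "filter_normal_coverage: removed %d of %d calls",
             n0 - length(calls), n0)
}

#' @param regions blacklist intervals: a \code{GRanges} or a BED file path.
#' @rdname filters
#' @export
filterBlacklist <- function(calls, regions) {
    stopifnot(is(calls, "CallSet"))
    if (is.character(regions))
        regions <- rtracklayer::import(regions, format = "BED")
    stopifnot(is(regions, "GRanges"))
    n0 <- length(calls)
    hit <- IRanges::overlapsAny(calls@ranges, regions, ignore.strand = TRUE)
    calls <- calls[!hit]
    .logStep(calls, "filter_blacklist: removed %d of %d calls",
             n0 - length(calls), n0)
}

#' @param property name of a configured quality property.
#' @param threshold minimum value; calls with
#'   \code{property >= threshold} are kept.
#' @rdname filters
#' @export
filterMinProperty <- function(calls, property, threshold) {
    stopifnot(is(calls, "CallSet"))
    if (!(property %in% calls@properties))
        stop("unknown quality property '", property, "' (available: ",
             paste(calls@properties, collapse = ", "), ")")
    n0 <- length(calls)
    keep <- mcols(calls@ranges)[[property]] >= threshold
    calls <- calls[keep]
    .logStep(calls, "filter_min_property(%s >= %s): removed %d of %d calls",
             property, format(threshold), n0 - length(calls), n0)
}

#' Consensus of call sets across pairings or replicates
#'
#' Intersects call sets on the (chrom, pos, alt) key, returning the calls
#' present in every input set. Quality values are taken from the first
#' listed set (document order = priority). Used both for replicate
#' consensus (duplicates/triplicates) and for requiring a mutation in all
#' tumor-normal pairings.
#'
#' @param callsets non-empty list of \linkS4class{CallSet}s sharing caller
#'   and comparison type.
#' @return a \linkS4class{CallSet} (subset of the first input).
#' @export
intersectPairings <- function(callsets) {
    if (!is.list(callsets) || !length(callsets))
        stop("'callsets' must be a non-empty list of CallSet objects")
    stopifnot(all(vapply(callsets, is, logical(1), "CallSet")))
    callers <- unique(vapply(callsets, caller, character(1)))
    comps <- unique(vapply(callsets, comparison, character(1)))
    if (length(callers) > 1L || length(comps) > 1L)
        stop("all call sets must share caller and comparison type")
    keys <- lapply(callsets, .callKeys)
    shared <- Reduce(intersect, keys)
    out <- callsets[[1L]][keys[[1L]] %in% shared]
    .logStep(out, "intersect_pairings: %d shared of input sizes [%s]",
             length(out),
             paste(vapply(callsets, length, integer(1)), collapse = ", "))
}
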