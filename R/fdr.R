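#' Build the empirical FDR(Q) function
#'
#' Constructs the empirical mapping from a quality score \code{q} to a
#' false discovery rate, using the same-vs-same comparison as the null:
#' the number of same-vs-same calls with a score of \code{q} or better,
#' divided by the number of tumor-comparison calls with a score of \code{q}
#' or better, each count normalized by the common coverage of its
#' comparison, and the ratio clamped to [0, 1]. When no tumor call scores
#' \code{q} or better the value is 0 if no null call does either, else 1.
#'
#' By default the raw ratio is reported, without monotone (q-value-style)
#' smoothing; set \code{smooth = TRUE} to make evaluations non-increasing
#' in \code{q}.
#'
#' @param ssQ Q scores of the same-vs-same (null) calls.
#' @param tnQ Q scores of the tumor-vs-normal calls; must be non-empty.
#' @param cSS,cTN \linkS4class{CommonCoverage} (or bare base counts) of the
#'   same-vs-same and tumor comparisons.
#' @param smooth enforce monotone non-increasing evaluations.
#' @return an \linkS4class{FDRFunction}.
#' @examples
#' fn <- buildFdrFunction(c(0.9, 0.5), c(0.95, 0.9, 0.5, 0.2), 1e6, 1e6)
#' evaluateFdr(fn, c(0.95, 0.9))  # 0.0, 0.5
#' @export
buildFdrFunction <- function(ssQ, tnQ, cSS, cTN, smooth = FALSE) {
    if (!length(tnQ)) stop("'tnQ' must be non-empty")
    stopifnot(all(is.finite(ssQ)), all(is.finite(tnQ)))
    new("FDRFunction", ssQ = sort(as.numeric(ssQ)),
        tnQ = sort(as.numeric(tnQ)),
        cSS = .baseCount(cSS, "cSS"), cTN = .baseCount(cTN, "cTN"),
        smooth = isTRUE(smooth))
}

#' @describeIn buildFdrFunction evaluate the function at scores \code{q}
#'   (vectorized); returns values in [0, 1].
#' @param fn an \linkS4class{FDRFunction}.
#' @param q numeric vector of quality scores.
#' @export
evaluateFdr <- function(fn, q) {
    stopifnot(is(fn, "FDRFunction"), all(is.finite(q)))
    nSS <- .countGE(q, fn@ssQ)
    nTN <- .countGE(q, fn@tnQ)
    out <- .ifdrRatio(nSS, nTN, fn@cSS, fn@cTN)
    if (fn@smooth && length(out) > 1L) {
        # running maximum from high q downward, computed in q order
        o <- order(q, decreasing = TRUE)
        out[o] <- cummax(out[o])
    }
    out
}

#' Annotate calls with per-mutation FDRs
#'
#' Evaluates an \linkS4class{FDRFunction} at each call's Q score and
#' returns the set sorted by FDR ascending (ties broken by chromosome,
#' then position), the order in which mutations are prioritized for
#' follow-up.
#'
#' @param fn an \linkS4class{FDRFunction}.
#' @param calls a \linkS4class{CallSet} whose metadata carries a numeric
#'   \code{Q} column (see \code{\link{scoreQuality}}), or a data.frame with
#'   columns \code{chrom, pos, ref, alt, Q}.
#' @return the input with an \code{FDR} column added, sorted by FDR.
#' @export
assignFdr <- function(fn, calls) {
    if (is(calls, "CallSet")) {
        mc <- mcols(calls@ranges)
        if (!("Q" %in% colnames(mc)))
            stop("calls carry no 'Q' column; score them first")
        fdr <- evaluateFdr(fn, mc$Q)
        mcols(calls@ranges)$FDR <- fdr
        o <- order(fdr, as.character(seqnames(calls@ranges)),
                   start(calls@ranges))
        calls <- calls[o]
        .logStep(calls, "assign_fdr: %d calls annotated", length(calls))
    } else {
        calls <- as.data.frame(calls)
        if (!("Q" %in% colnames(calls)))
            stop("calls carry no 'Q' column; score them first")
        calls$FDR <- evaluateFdr(fn, calls$Q)
        calls[order(calls$FDR, calls$chrom, calls$pos), , drop = FALSE]
    }
}

#' Reuse a same-vs-same reference for a new tumor comparison
#'
#' The same-vs-same profiling needs to be done only once per platform and
#' caller: this swaps in the Q scores of a new tumor comparison while
#' keeping the null side (and its coverage) of an existing
#' \linkS4class{FDRFunction}. The new scores must come from the same
#' \linkS4class{QualityModel} so that Q values are comparable.
#'
#' @param fn an existing \linkS4class{FDRFunction}.
#' @param newTnQ Q scores of the new tumor comparison.
#' @param cTN common coverage of the new tumor comparison; defaults to the
#'   previous one.
#' @return a new \linkS4class{FDRFunction}.
#' @export
reuseReference <- function(fn, newTnQ, cTN = NULL) {
    stopifnot(is(fn, "FDRFunction"))
    if (is.null(cTN)) cTN <- fn@cTN
    buildFdrFunction(fn@ssQ, newTnQ, fn@cSS, cTN, smooth = fn@smooth)
}

setMethod("show", "FDRFunction", function(object) {
    cat("FDRFunction: ", length(object@ssQ), " same-vs-same / ",
        length(object@tnQ), " tumor calls\n", sep = "")
    cat("  common coverage ss/tn: ",
        format(object@cSS, big.mark = ","), " / ",
        format(object@cTN, big.mark = ","), " bases",
        if (object@smooth) " | monotone-smoothed" else "", "\n", sep = "")
})
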