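#' Construct a CallSet from per-call fields
#'
#' Low-level constructor used by the VCF reader and the synthetic
#' generator. Calls are stored on a \code{GRanges}; the quality properties
#' become numeric metadata columns.
#'
#' @param chrom,pos,ref,alt per-call vectors (pos is 1-based).
#' @param qualities data.frame/DataFrame of quality properties, one row per
#'   call, or NULL when \code{properties} is empty.
#' @param caller caller identifier.
#' @param comparison \code{"tumor_normal"} or \code{"same_same"}.
#' @param pairId identifier of the sample pairing.
#' @param properties ordered property names; defaults to the columns of
#'   \code{qualities}.
#' @param provenance initial provenance log.
#'
#' @return a \linkS4class{CallSet}.
#' @examples
#' cs <- CallSet(chrom = "chr1", pos = c(10L, 20L), ref = c("A", "C"),
#'               alt = c("G", "T"),
#'               qualities = data.frame(q = c(30, 40), dp = c(10, 12)),
#'               caller = "toy", comparison = "tumor_normal", pairId = "p1")
#' @export
CallSet <- function(chrom, pos, ref, alt, qualities = NULL,
                    caller = "unknown", comparison = "tumor_normal",
                    pairId = "pair1", properties = NULL,
                    provenance = character()) {
    n <- length(pos)
    gr <- GRanges(rep_len(as.character(chrom), n),
                  IRanges::IRanges(start = as.integer(pos), width = 1L))
    mc <- DataFrame(ref = as.character(ref), alt = as.character(alt))
    if (!is.null(qualities)) {
        qualities <- as.data.frame(qualities)
        for (cn in colnames(qualities)) mc[[cn]] <- as.numeric(qualities[[cn]])
        if (is.null(properties)) properties <- colnames(qualities)
    }
    if (is.null(properties)) properties <- character()
    mcols(gr) <- mc
    new("CallSet", ranges = gr, caller = as.character(caller),
        comparison = match.arg(comparison, .VALID_COMPARISONS),
        pairId = as.character(pairId), properties = properties,
        provenance = provenance)
}

#' @rdname CallSet-class
#' @aliases caller comparison pairId provenance qualityMatrix
#' @export
setMethod("caller", "CallSet", function(x) x@caller)

#' @rdname CallSet-class
#' @export
setMethod("comparison", "CallSet", function(x) x@comparison)

#' @rdname CallSet-class
#' @export
setMethod("pairId", "CallSet", function(x) x@pairId)

#' @rdname CallSet-class
#' @export
setMethod("provenance", "CallSet", function(x) x@provenance)

#' @rdname CallSet-class
#' @export
setMethod("qualityMatrix", "CallSet", function(x) {
    m <- as.matrix(as.data.frame(mcols(x@ranges)[x@properties]))
    storage.mode(m) <- "double"
    m
})

#' @rdname CallSet-class
#' @export
setMethod("length", "CallSet", function(x) length(x@ranges))

#' @describeIn CallSet-class subset the calls (keeps metadata and provenance).
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "CallSet", function(x, i, j, ..., drop = FALSE) {
    x@ranges <- x@ranges[i]
    x
})

#' @describeIn CallSet-class calls as a plain data.frame
#'   (chrom, pos, ref, alt, then quality and score columns).
#' @param row.names,optional passed through to data.frame conventions.
#' @export
setMethod("as.data.frame", "CallSet",
          function(x, row.names = NULL, optional = FALSE, ...) {
    gr <- x@ranges
    df <- data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
                     stringsAsFactors = FALSE)
    cbind(df, as.data.frame(mcols(gr)))
})

setMethod("show", "CallSet", function(object) {
    cat("CallSet:", length(object), "calls |", object@caller, "|",
        object@comparison, "|", object@pairId, "\n")
    if (length(object@properties))
        cat("  qualities:", paste(object@properties, collapse = ", "), "\n")
    extra <- intersect(c("Q", "FDR"), colnames(mcols(object@ranges)))
    if (length(extra)) cat("  scored:", paste(extra, collapse = ", "), "\n")
    if (length(object@provenance))
        cat("  provenance:\n", paste0("    ", object@provenance, "\n"), sep = "")
})
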