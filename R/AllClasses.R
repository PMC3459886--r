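#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start width
NULL

.VALID_COMPARISONS <- c("tumor_normal", "same_same")
.BASES <- c("A", "C", "G", "T")

#' CallerConfig: per-caller quality-property configuration
#'
#' Describes, for one mutation caller, the ordered list of per-call quality
#' properties used by the confidence model, how each property is extracted
#' from a VCF record, and the per-property grid size \code{p} used when the
#' quality space is sampled for model training.
#'
#' @slot caller caller identifier, e.g. \code{"samtools"}.
#' @slot properties ordered character vector of property names; the order
#'   fixes the component order of every quality vector for this caller.
#' @slot fieldMap named character vector mapping each property to a VCF
#'   field: \code{"QUAL"}, \code{"INFO/<key>"} or \code{"FORMAT/<key>"}
#'   (first sample).
#' @slot p integer grid size: up to \code{p} uniformly spaced values are
#'   sampled per property when the quality space is discretized.
#' @export
setClass("CallerConfig",
    representation(caller = "character", properties = "character",
                   fieldMap = "character", p = "integer"))

setValidity("CallerConfig", function(object) {
    msg <- NULL
    if (length(object@caller) != 1L || !nzchar(object@caller))
        msg <- c(msg, "'caller' must be a single non-empty string")
    if (length(object@properties) < 1L)
        msg <- c(msg, "'properties' must be non-empty")
    if (anyDuplicated(object@properties))
        msg <- c(msg, "'properties' must be unique")
    if (!setequal(names(object@fieldMap), object@properties))
        msg <- c(msg, "'fieldMap' must name exactly the configured properties")
    if (length(object@p) != 1L || is.na(object@p) || object@p < 2L)
        msg <- c(msg, "'p' must be a single integer >= 2")
    if (is.null(msg)) TRUE else msg
})

#' CallSet: a filtered set of single-nucleotide variant calls
#'
#' A container for biallelic SNV calls from one caller and one comparison
#' (tumor-vs-normal, or the replicate same-vs-same null), with the caller's
#' quality properties carried as numeric metadata columns on the underlying
#' \link[GenomicRanges]{GRanges}. Scored sets additionally carry \code{Q}
#' and \code{FDR} columns.
#'
#' @slot ranges \code{GRanges} of call loci (1-based positions, width 1)
#'   with metadata columns \code{ref}, \code{alt} and one numeric column per
#'   configured quality property.
#' @slot caller caller identifier.
#' @slot comparison \code{"tumor_normal"} or \code{"same_same"}.
#' @slot pairId identifier of the sample pairing.
#' @slot properties names of the quality-property columns (fixed order).
#' @slot provenance character log of ingestion and filter steps.
#' @export
setClass("CallSet",
    representation(ranges = "GRanges", caller = "character",
                   comparison = "character", pairId = "character",
                   properties = "character", provenance = "character"))

setValidity("CallSet", function(object) {
    msg <- NULL
    gr <- object@ranges
    mc <- mcols(gr)
    if (!(object@comparison %in% .VALID_COMPARISONS))
        msg <- c(msg, sprintf("'comparison' must be one of: %s",
                              paste(.VALID_COMPARISONS, collapse = ", ")))
    if (!all(c("ref", "alt") %in% colnames(mc)))
        msg <- c(msg, "metadata columns 'ref' and 'alt' are required")
    if (length(gr)) {
        if (any(width(gr) != 1L))
            msg <- c(msg, "all calls must be width-1 SNVs")
        if (any(start(gr) < 1L))
            msg <- c(msg, "positions must be >= 1")
        bad <- !(mc$ref %in% .BASES) | !(mc$alt %in% .BASES) |
            mc$ref == mc$alt
        if (any(bad))
            msg <- c(msg, "ref and alt must be distinct single bases in ACGT")
        if (anyDuplicated(paste(seqnames(gr), start(gr), mc$alt)))
            msg <- c(msg, "duplicate (chrom, pos, alt) keys")
    }
    miss <- setdiff(object@properties, colnames(mc))
    if (length(miss))
        msg <- c(msg, sprintf("missing quality columns: %s",
                              paste(miss, collapse = ", ")))
    for (pp in intersect(object@properties, colnames(mc))) {
        v <- mc[[pp]]
        if (!is.numeric(v) || any(!is.finite(v)))
            msg <- c(msg, sprintf("quality column '%s' must be finite numeric", pp))
    }
    if (is.null(msg)) TRUE else msg
})

#' CoverageTrack: per-sample covered positions
#'
#' The set of reference positions covered by at least one read in one
#' sample, stored as a maximally merged (reduced) \code{GRanges}.
#'
#' @slot ranges reduced \code{GRanges} of covered bases.
#' @slot sampleId sample identifier.
#' @export
setClass("CoverageTrack",
    representation(ranges = "GRanges", sampleId = "character"))

#' CommonCoverage: shared searchable space of a comparison
#'
#' The number of reference bases covered (depth >= 1) in both members of a
#' comparison. Call counts from different comparisons are made commensurable
#' by dividing by this quantity.
#'
#' @slot pairId identifier of the comparison.
#' @slot bases non-negative base count.
#' @export
setClass("CommonCoverage",
    representation(pairId = "character", bases = "numeric"))

setValidity("CommonCoverage", function(object) {
    if (length(object@bases) != 1L || is.na(object@bases) || object@bases < 0)
        "'bases' must be a single non-negative number" else TRUE
})

#' QualityModel: regression fusing quality properties into one score Q
#'
#' A trained random-forest regression from a caller's quality vector to the
#' dominance-order intermediate FDR. The generalized quality score is
#' \code{Q = 1 - predicted IFDR}, so \code{Q} lies in [0, 1] and larger
#' values mean higher confidence.
#'
#' @slot caller caller identifier the model was trained for.
#' @slot properties property names, in training order.
#' @slot forest the fitted \link[randomForest]{randomForest} object.
#' @slot meta list of training metadata: \code{p}, \code{gridSize},
#'   \code{sampleFraction}, \code{nTrain}, \code{ntree}, \code{seed}.
#' @export
setClass("QualityModel",
    representation(caller = "character", properties = "character",
                   forest = "ANY", meta = "list"))

#' FDRFunction: empirical FDR as a function of Q
#'
#' The empirical mapping from a quality score \code{q} to a false discovery
#' rate, built from the same-vs-same reference scores (the null) and the
#' tumor-comparison scores, each normalized by its common coverage:
#' \deqn{FDR(q) = \frac{\#\{ss \ge q\} / C_{ss}}{\#\{tn \ge q\} / C_{tn}}}
#' clamped to [0, 1].
#'
#' @slot ssQ sorted Q scores of the same-vs-same calls.
#' @slot tnQ sorted Q scores of the tumor-vs-normal calls.
#' @slot cSS common coverage (bases) of the same-vs-same comparison.
#' @slot cTN common coverage (bases) of the tumor comparison.
#' @slot smooth if TRUE, evaluations are made monotone non-increasing in q
#'   (q-value-style); the default reports the raw ratio.
#' @export
setClass("FDRFunction",
    representation(ssQ = "numeric", tnQ = "numeric",
                   cSS = "numeric", cTN = "numeric", smooth = "logical"))

setValidity("FDRFunction", function(object) {
    msg <- NULL
    if (!length(object@tnQ))
        msg <- c(msg, "'tnQ' must be non-empty")
    if (is.unsorted(object@ssQ) || is.unsorted(object@tnQ))
        msg <- c(msg, "reference score lists must be sorted ascending")
    if (object@cSS <= 0 || object@cTN <= 0)
        msg <- c(msg, "common coverages must be positive")
    if (is.null(msg)) TRUE else msg
})

#' ROCCurve: an (estimated or label-based) ROC curve with its AUC
#'
#' @slot fpr,tpr ordered curve coordinates, beginning at (0, 0).
#' @slot auc trapezoid area under the stored points.
#' @slot kind \code{"estimated"} (built from FDRs alone) or
#'   \code{"labeled"} (built from validation labels).
#' @export
setClass("ROCCurve",
    representation(fpr = "numeric", tpr = "numeric", auc = "numeric",
                   kind = "character"))

setValidity("ROCCurve", function(object) {
    msg <- NULL
    if (length(object@fpr) != length(object@tpr))
        msg <- c(msg, "'fpr' and 'tpr' must have equal length")
    if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
        msg <- c(msg, "'fpr' and 'tpr' must be non-decreasing")
    if (!(object@kind %in% c("estimated", "labeled")))
        msg <- c(msg, "'kind' must be 'estimated' or 'labeled'")
    if (is.null(msg)) TRUE else msg
})

#' MeanROC: pointwise mean of several estimated ROC curves
#'
#' Member curves are aligned on a common axis (cumulative rank fraction of
#' the sorted mutation list), linearly interpolated, and averaged; 95%
#' confidence half-widths for the mean are carried in both dimensions.
#'
#' @slot positions uniform evaluation positions in [0, 1].
#' @slot meanFpr,meanTpr pointwise means.
#' @slot hwFpr,hwTpr 95% half-widths (1.96 x standard error of the mean).
#' @slot nMembers number of member curves.
#' @export
setClass("MeanROC",
    representation(positions = "numeric", meanFpr = "numeric",
                   meanTpr = "numeric", hwFpr = "numeric", hwTpr = "numeric",
                   nMembers = "integer"))

#' SyntheticExperiment: labeled synthetic call sets for validation
#'
#' A tumor-vs-normal call set that is a known mixture of true mutations and
#' artifacts, a same-vs-same call set drawn from the artifact distribution
#' only, truth labels keyed by (chrom, pos, alt), and the pair of common
#' coverages.
#'
#' @slot tumorNormal,sameSame \linkS4class{CallSet}s.
#' @slot labels named character vector, \code{"positive"}/\code{"negative"},
#'   one per tumor-normal call, named by its (chrom:pos:alt) key.
#' @slot cSS,cTN \linkS4class{CommonCoverage} of the two comparisons.
#' @slot config the generating configuration (list).
#' @export
setClass("SyntheticExperiment",
    representation(tumorNormal = "CallSet", sameSame = "CallSet",
                   labels = "character", cSS = "CommonCoverage",
                   cTN = "CommonCoverage", config = "list"))
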