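#' @rdname CallSet-class
#' @param x,object an object.
#' @export
setGeneric("caller", function(x) standardGeneric("caller"))

#' @rdname CallSet-class
#' @export
setGeneric("comparison", function(x) standardGeneric("comparison"))

#' @rdname CallSet-class
#' @export
setGeneric("pairId", function(x) standardGeneric("pairId"))

#' @rdname CallSet-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname CallSet-class
#' @export
setGeneric("qualityMatrix", function(x) standardGeneric("qualityMatrix"))

#' @rdname CommonCoverage-class
#' @export
setGeneric("coveredBases", function(x) standardGeneric("coveredBases"))

#' @rdname ROCCurve-class
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname ROCCurve-class
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname trainQualityModel
#' @param model a \linkS4class{QualityModel}.
#' @param v quality vectors: a numeric vector (one call), matrix or
#'   data.frame (one row per call), or a \linkS4class{CallSet}.
#' @export
setGeneric("scoreQuality", function(model, v) standardGeneric("scoreQuality"))
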