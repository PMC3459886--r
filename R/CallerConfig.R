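#' Construct a CallerConfig
#'
#' @param caller caller identifier.
#' @param properties ordered character vector of quality-property names.
#' @param fieldMap named character vector (names = properties) mapping each
#'   property to \code{"QUAL"}, \code{"INFO/<key>"} or \code{"FORMAT/<key>"}.
#' @param p per-property grid size used by \code{\link{sampleQualityGrid}}.
#'
#' @return a \linkS4class{CallerConfig}.
#' @examples
#' cfg <- CallerConfig("toy", c("snpq", "depth"),
#'                     c(snpq = "QUAL", depth = "INFO/DP"), p = 10)
#' @export
CallerConfig <- function(caller, properties, fieldMap, p = 20L) {
    new("CallerConfig", caller = as.character(caller),
        properties = as.character(properties),
        fieldMap = fieldMap, p = as.integer(p))
}

#' Built-in caller configurations
#'
#' Ready-made configurations for the three callers the framework was
#' developed around. Each lists the quality properties fed to the model and
#' the per-property grid size \code{p}; the differing \code{p} values keep
#' the sampled quality grids at comparable size across callers
#' (\eqn{20^4 \approx 12^5}).
#'
#' \describe{
#'   \item{samtoolsConfig}{SNP quality, coverage depth, consensus quality,
#'     RMS mapping quality; p = 20.}
#'   \item{gatkConfig}{SNP quality, coverage depth, variant
#'     confidence/unfiltered depth, RMS mapping quality; p = 20.}
#'   \item{somaticSniperConfig}{SNP quality, coverage depth, consensus
#'     quality, RMS mapping quality, somatic score; p = 12.}
#' }
#'
#' The field mappings follow the VCF conventions of the bundled synthetic
#' writer (\code{QUAL} plus INFO keys \code{DP}, \code{CQ}, \code{MQ},
#' \code{VDP}, \code{SSC}); adjust \code{fieldMap} for VCFs produced by
#' other caller versions.
#'
#' @return a \linkS4class{CallerConfig}.
#' @rdname builtinConfigs
#' @export
samtoolsConfig <- function() {
    props <- c("snp_quality", "coverage_depth", "consensus_quality",
               "rms_mapping_quality")
    CallerConfig("samtools", props,
                 c(snp_quality = "QUAL", coverage_depth = "INFO/DP",
                   consensus_quality = "INFO/CQ",
                   rms_mapping_quality = "INFO/MQ"), p = 20L)
}

#' @rdname builtinConfigs
#' @export
gatkConfig <- function() {
    props <- c("snp_quality", "coverage_depth", "variant_confidence",
               "rms_mapping_quality")
    CallerConfig("gatk", props,
                 c(snp_quality = "QUAL", coverage_depth = "INFO/DP",
                   variant_confidence = "INFO/VDP",
                   rms_mapping_quality = "INFO/MQ"), p = 20L)
}

#' @rdname builtinConfigs
#' @export
somaticSniperConfig <- function() {
    props <- c("snp_quality", "coverage_depth", "consensus_quality",
               "rms_mapping_quality", "somatic_score")
    CallerConfig("somaticsniper", props,
                 c(snp_quality = "QUAL", coverage_depth = "INFO/DP",
                   consensus_quality = "INFO/CQ",
                   rms_mapping_quality = "INFO/MQ",
                   somatic_score = "INFO/SSC"), p = 12L)
}

setMethod("show", "CallerConfig", function(object) {
    cat("CallerConfig for '", object@caller, "'\n", sep = "")
    cat("  properties (", length(object@properties), "): ",
        paste(object@properties, collapse = ", "), "\n", sep = "")
    cat("  grid size p:", object@p, "\n")
})
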