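#' Read a caller's VCF into a CallSet
#'
#' Ingests a VCF 4.x file and extracts, for every biallelic SNV record,
#' the quality properties named by the \linkS4class{CallerConfig} field
#' map. Multi-allelic records are split into one call per alternate
#' allele, each inheriting the record's qualities; indel records (and
#' symbolic alleles) are skipped and counted in the provenance log.
#'
#' @param vcfPath path to a VCF file.
#' @param config \linkS4class{CallerConfig} naming the properties and the
#'   VCF fields (\code{"QUAL"}, \code{"INFO/<key>"}, \code{"FORMAT/<key>"})
#'   that feed them.
#' @param comparison \code{"tumor_normal"} or \code{"same_same"}.
#' @param pairId identifier of the sample pairing.
#' @return a \linkS4class{CallSet}.
#' @examples
#' exp <- generateExperiment(syntheticConfig(nTnCalls = 50, seed = 1))
#' d <- tempfile(); paths <- writeFixtures(exp, d)
#' cs <- readCalls(paths[["tnVcf"]], samtoolsConfig(),
#'                 "tumor_normal", "pair1")
#' @export
readCalls <- function(vcfPath, config, comparison = c("tumor_normal",
                      "same_same"), pairId = "pair1") {
    stopifnot(is(config, "CallerConfig"))
    comparison <- match.arg(comparison)
    if (!file.exists(vcfPath)) stop("VCF file not found: ", vcfPath)
    vcf <- VariantAnnotation::readVcf(vcfPath)
    nRecords <- nrow(vcf)
    vcf <- suppressWarnings(VariantAnnotation::expand(vcf))

    ref <- as.character(VariantAnnotation::ref(vcf))
    alt <- as.character(VariantAnnotation::alt(vcf))
    isSnv <- ref %in% .BASES & alt %in% .BASES & ref != alt
    nIndel <- sum(!isSnv)

    qual <- DataFrame(row.names = seq_len(length(vcf)))
    infoDf <- VariantAnnotation::info(vcf)
    for (prop in config@properties) {
        field <- config@fieldMap[[prop]]
        vals <- if (identical(field, "QUAL")) {
            VariantAnnotation::qual(vcf)
        } else if (startsWith(field, "INFO/")) {
            key <- sub("^INFO/", "", field)
            if (!(key %in% colnames(infoDf)))
                stop("VCF '", vcfPath, "' has no INFO field '", key,
                     "' (mapped to property '", prop, "')")
            v <- infoDf[[key]]
            if (is(v, "List") || is.list(v))
                v <- vapply(v, function(x)
                    if (length(x)) as.numeric(x[[1L]]) else NA_real_,
                    numeric(1))
            v
        } else if (startsWith(field, "FORMAT/")) {
            key <- sub("^FORMAT/", "", field)
            g <- VariantAnnotation::geno(vcf)
            if (!(key %in% names(g)))
                stop("VCF '", vcfPath, "' has no FORMAT field '", key,
                     "' (mapped to property '", prop, "')")
            as.numeric(g[[key]][, 1L])
        } else stop("unsupported field spec '", field, "' for property '",
                    prop, "'")
        vals <- as.numeric(vals)
        bad <- which(!is.finite(vals) & isSnv)
        if (length(bad))
            stop("record ", rownames(vcf)[bad[1L]], " (", vcfPath,
                 ") lacks a value for mapped field '", field,
                 "' (property '", prop, "')")
        qual[[prop]] <- vals
    }

    rr <- SummarizedExperiment::rowRanges(vcf)[isSnv]
    cs <- CallSet(chrom = as.character(seqnames(rr)), pos = start(rr),
                  ref = ref[isSnv], alt = alt[isSnv],
                  qualities = as.data.frame(qual[isSnv, , drop = FALSE]),
                  caller = config@caller, comparison = comparison,
                  pairId = pairId, properties = config@properties)
    .logStep(cs, "read_calls: %d records from %s; %d SNV calls kept, %d indel/symbolic skipped",
             nRecords, basename(vcfPath), sum(isSnv), nIndel)
}

#' Write scored mutations
#'
#' Writes a scored call set (Q and FDR assigned) either as a TSV table with
#' columns \code{chrom, pos, ref, alt, caller, Q, FDR}, sorted by FDR
#' ascending, or as a VCF whose INFO carries \code{GQS} (the generalized
#' quality score Q) and \code{FDR}. The TSV round-trips losslessly through
#' \code{\link{readScoredCalls}}.
#'
#' @param scored a \linkS4class{CallSet} with \code{Q} and \code{FDR}
#'   metadata columns (see \code{\link{assignFdr}}), or an equivalent
#'   data.frame.
#' @param outPath output file.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @return \code{outPath}, invisibly.
#' @export
writeScoredCalls <- function(scored, outPath, format = c("tsv", "vcf")) {
    format <- match.arg(format)
    df <- if (is(scored, "CallSet")) as.data.frame(scored) else
        as.data.frame(scored)
    need <- c("chrom", "pos", "ref", "alt", "Q", "FDR")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("scored calls lack columns: ", paste(miss, collapse = ", "))
    if (!("caller" %in% colnames(df)))
        df$caller <- rep(if (is(scored, "CallSet")) caller(scored) else
            "unknown", nrow(df))
    df <- df[order(df$FDR, df$chrom, df$pos),
             c("chrom", "pos", "ref", "alt", "caller", "Q", "FDR")]
    dir.create(dirname(outPath), showWarnings = FALSE, recursive = TRUE)
    if (format == "tsv") {
        utils::write.table(df, outPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        header <- c("##fileformat=VCFv4.2",
            "##INFO=<ID=GQS,Number=1,Type=Float,Description=\"Generalized quality score Q (1 - predicted IFDR)\">",
            "##INFO=<ID=FDR,Number=1,Type=Float,Description=\"Per-mutation empirical false discovery rate\">",
            paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                  "INFO", sep = "\t"))
        body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tGQS=%s;FDR=%s",
                        df$chrom, df$pos, df$ref, df$alt,
                        format(df$Q, digits = 15, trim = TRUE),
                        format(df$FDR, digits = 15, trim = TRUE))
        writeLines(c(header, body), outPath)
    }
    invisible(outPath)
}

#' @describeIn writeScoredCalls read a scored TSV back into a data.frame.
#' @param path a TSV written by \code{writeScoredCalls}.
#' @export
readScoredCalls <- function(path) {
    if (!file.exists(path)) stop("scored-call table not found: ", path)
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = c(chrom = "character", ref = "character",
                                     alt = "character", caller = "character"),
                      stringsAsFactors = FALSE)
}
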