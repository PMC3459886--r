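#' Default synthetic quality-property specifications
#'
#' Four independent quality properties mimicking the per-call scores a
#' pileup-style caller emits (SNP quality, coverage depth, consensus
#' quality, RMS mapping quality). Artifact calls draw each property from a
#' truncated Gaussian; true mutations draw from the same Gaussian shifted
#' upward by \code{shift} (0.75 standard deviations per property at the
#' default - a moderate, partially overlapping separation). The
#' \code{shiftScale} multiplier scales all shifts at once: 0 gives
#' zero-separation data, values > 1 progressively cleaner separation.
#'
#' @param shiftScale multiplier applied to every property's location shift.
#' @return list of per-property specs
#'   (\code{name, mean, sd, min, max, shift}).
#' @export
syntheticProperties <- function(shiftScale = 1) {
    base <- list(
        list(name = "snp_quality", mean = 30, sd = 12, min = 0, max = 255),
        list(name = "coverage_depth", mean = 20, sd = 8, min = 1, max = 250),
        list(name = "consensus_quality", mean = 30, sd = 12, min = 0,
             max = 255),
        list(name = "rms_mapping_quality", mean = 40, sd = 8, min = 0,
             max = 60))
    lapply(base, function(s) { s$shift <- 0.75 * s$sd * shiftScale; s })
}

#' Configuration for the synthetic call-set generator
#'
#' Defines a labeled synthetic experiment: a tumor-vs-normal call set that
#' is a \code{trueFraction} : (1 - \code{trueFraction}) mixture of true
#' mutations and artifacts, and a same-vs-same call set drawn from the
#' artifact distribution only. Unless overridden, the same-vs-same size is
#' \code{(cSS / cTN) * (1 - trueFraction) * nTnCalls}, so the artifact rate
#' per covered base matches between the two comparisons and assigned FDRs
#' are directly interpretable.
#'
#' @param nTnCalls number of tumor-vs-normal calls.
#' @param trueFraction mixture weight of true mutations in [0, 1].
#' @param properties per-property specs, see
#'   \code{\link{syntheticProperties}}.
#' @param nSsCalls same-vs-same call count; NULL for the matched default.
#' @param cSS,cTN common coverage (bases) of the same-vs-same and tumor
#'   comparisons; defaults are exome-scale (a ~50 Mb capture design with
#'   near-complete 1x coverage).
#' @param meanDepth mean per-base read depth used when depth fixtures are
#'   written.
#' @param contig name of the virtual contig calls are placed on.
#' @param seed integer seed; generation is fully reproducible.
#' @return a list with class \code{"syntheticConfig"}.
#' @export
syntheticConfig <- function(nTnCalls = 5000L, trueFraction = 0.5,
                            properties = syntheticProperties(),
                            nSsCalls = NULL, cSS = 4.5e7, cTN = 4.5e7,
                            meanDepth = 38, contig = "chrS", seed = 1L) {
    stopifnot(nTnCalls >= 1, trueFraction >= 0, trueFraction <= 1,
              cSS >= 1, cTN >= 1, length(properties) >= 1)
    for (s in properties)
        stopifnot(all(c("name", "mean", "sd", "min", "max", "shift") %in%
                          names(s)), s$shift >= 0, s$sd > 0, s$min < s$max)
    if (is.null(nSsCalls))
        nSsCalls <- max(1L, round((cSS / cTN) * (1 - trueFraction) *
                                      nTnCalls))
    structure(list(nTnCalls = as.integer(nTnCalls),
                   trueFraction = trueFraction, properties = properties,
                   nSsCalls = as.integer(nSsCalls), cSS = cSS, cTN = cTN,
                   meanDepth = meanDepth, contig = contig,
                   seed = as.integer(seed)),
              class = "syntheticConfig")
}

# inverse-CDF draw from a Gaussian truncated to [lo, hi]
.rtruncnorm <- function(n, mean, sd, lo, hi) {
    pl <- stats::pnorm(lo, mean, sd); ph <- stats::pnorm(hi, mean, sd)
    stats::qnorm(stats::runif(n, pl, ph), mean, sd)
}

# n quality vectors; shifted = TRUE draws the true-mutation distribution
.drawQualities <- function(n, properties, shifted) {
    cols <- lapply(properties, function(s) {
        mu <- s$mean + if (shifted) s$shift else 0
        round(.rtruncnorm(n, mu, s$sd, s$min, s$max), 4)
    })
    names(cols) <- vapply(properties, `[[`, character(1), "name")
    as.data.frame(cols)
}

.randomAlleles <- function(n) {
    ref <- sample(.BASES, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1L),
                  character(1), USE.NAMES = FALSE)
    list(ref = ref, alt = alt)
}

.makeCallSet <- function(pos, qualities, config, comparison, pairId) {
    al <- .randomAlleles(length(pos))
    o <- order(pos)
    CallSet(chrom = config$contig, pos = pos[o], ref = al$ref[o],
            alt = al$alt[o], qualities = qualities[o, , drop = FALSE],
            caller = "synthetic", comparison = comparison, pairId = pairId,
            provenance = sprintf("synthetic: %d calls, seed %d",
                                 length(pos), config$seed))
}

#' Generate a labeled synthetic experiment
#'
#' Draws the tumor-vs-normal mixture (true mutations from the shifted
#' property distributions, artifacts from the base distributions), the
#' all-artifact same-vs-same set, and uncollided uniform loci on the
#' virtual contig. Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return a \linkS4class{SyntheticExperiment}.
#' @examples
#' exp <- generateExperiment(syntheticConfig(nTnCalls = 200, seed = 7))
#' table(syntheticLabels(exp))
#' @export
generateExperiment <- function(config) {
    stopifnot(inherits(config, "syntheticConfig"))
    set.seed(config$seed)
    nTn <- config$nTnCalls
    nTrue <- round(config$trueFraction * nTn)
    nArt <- nTn - nTrue

    tnPos <- sample.int(min(config$cTN, .Machine$integer.max - 1), nTn)
    qual <- rbind(.drawQualities(nTrue, config$properties, shifted = TRUE),
                  .drawQualities(nArt, config$properties, shifted = FALSE))
    isTrue <- rep(c(TRUE, FALSE), c(nTrue, nArt))

    o <- order(tnPos)
    tn <- .makeCallSet(tnPos, qual, config, "tumor_normal", "tn_pair")
    labels <- ifelse(isTrue[o], "positive", "negative")
    names(labels) <- .callKeys(tn)

    ssPos <- sample.int(min(config$cSS, .Machine$integer.max - 1),
                        config$nSsCalls)
    ss <- .makeCallSet(ssPos,
                       .drawQualities(config$nSsCalls, config$properties,
                                      shifted = FALSE),
                       config, "same_same", "ss_pair")

    new("SyntheticExperiment", tumorNormal = tn, sameSame = ss,
        labels = labels,
        cSS = CommonCoverage(config$cSS, "ss_pair"),
        cTN = CommonCoverage(config$cTN, "tn_pair"),
        config = unclass(config))
}

#' @describeIn generateExperiment truth labels keyed by (chrom:pos:alt).
#' @param exp a \linkS4class{SyntheticExperiment}.
#' @export
syntheticLabels <- function(exp) {
    stopifnot(is(exp, "SyntheticExperiment"))
    exp@labels
}

setMethod("show", "SyntheticExperiment", function(object) {
    cat("SyntheticExperiment:", length(object@tumorNormal),
        "tumor-vs-normal calls (",
        sum(object@labels == "positive"), "true ),",
        length(object@sameSame), "same-vs-same calls\n")
    cat("  common coverage ss/tn:",
        format(object@cSS@bases, big.mark = ","), "/",
        format(object@cTN@bases, big.mark = ","), "bases\n")
})

#' Draw a replicate tumor-vs-normal call set
#'
#' Emulates a technical replicate of the tumor experiment: the true
#' mutations keep their loci and alleles (their quality vectors are
#' redrawn, as an independent measurement would), while the artifact calls
#' are redrawn entirely - new loci, new qualities - because sequencing
#' artifacts do not reproduce across replicates. Intersecting replicates
#' therefore enriches for true mutations.
#'
#' @param exp a \linkS4class{SyntheticExperiment}.
#' @param seed seed for the replicate draw.
#' @return list with elements \code{calls} (a \linkS4class{CallSet}) and
#'   \code{labels} (named character, as in \code{\link{syntheticLabels}}).
#' @export
replicateTumorNormal <- function(exp, seed) {
    stopifnot(is(exp, "SyntheticExperiment"))
    config <- exp@config
    set.seed(as.integer(seed))
    tn <- exp@tumorNormal
    truthKeys <- names(exp@labels)[exp@labels == "positive"]
    keys <- .callKeys(tn)
    keepTrue <- keys %in% truthKeys
    nTrue <- sum(keepTrue); nArt <- length(tn) - nTrue

    trueGr <- tn@ranges[keepTrue]
    trueQual <- .drawQualities(nTrue, config$properties, shifted = TRUE)
    artPos <- sample.int(min(config$cTN, .Machine$integer.max - 1), nArt)
    # avoid locus collisions with the retained true calls
    artPos <- setdiff(artPos, start(trueGr))[seq_len(min(nArt,
        length(setdiff(artPos, start(trueGr)))))]
    artAl <- .randomAlleles(length(artPos))
    artQual <- .drawQualities(length(artPos), config$properties,
                              shifted = FALSE)

    chrom <- c(as.character(seqnames(trueGr)),
               rep(config$contig, length(artPos)))
    pos <- c(start(trueGr), artPos)
    ref <- c(mcols(trueGr)$ref, artAl$ref)
    alt <- c(mcols(trueGr)$alt, artAl$alt)
    qual <- rbind(trueQual, artQual)
    o <- order(chrom, pos)
    cs <- CallSet(chrom = chrom[o], pos = pos[o], ref = ref[o],
                  alt = alt[o], qualities = qual[o, , drop = FALSE],
                  caller = caller(tn), comparison = "tumor_normal",
                  pairId = paste0(pairId(tn), "_rep"),
                  provenance = sprintf(
                      "synthetic replicate: %d true + %d artifact calls, seed %d",
                      nTrue, length(artPos), as.integer(seed)))
    labels <- ifelse(.callKeys(cs) %in% truthKeys, "positive", "negative")
    names(labels) <- .callKeys(cs)
    list(calls = cs, labels = labels)
}

# minimal but valid VCF emission for a CallSet, fields per the CallerConfig
.writeCallSetVcf <- function(callset, path, callerConfig) {
    df <- as.data.frame(callset)
    fm <- callerConfig@fieldMap
    qualField <- names(fm)[fm == "QUAL"]
    infoProps <- names(fm)[startsWith(fm, "INFO/")]
    infoKeys <- sub("^INFO/", "", fm[infoProps])
    header <- c("##fileformat=VCFv4.2",
        sprintf("##source=somaticFDR synthetic generator (%s, %s)",
                callset@comparison, callset@pairId),
        sprintf("##contig=<ID=%s>", unique(df$chrom)),
        sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                infoKeys, infoProps),
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              sep = "\t"))
    qualCol <- if (length(qualField))
        sprintf("%.4f", df[[qualField[1L]]]) else "."
    info <- if (length(infoKeys)) {
        parts <- mapply(function(key, prop)
            sprintf("%s=%.4f", key, df[[prop]]),
            infoKeys, infoProps, SIMPLIFY = FALSE)
        do.call(paste, c(parts, sep = ";"))
    } else rep(".", nrow(df))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t%s",
                    df$chrom, df$pos, df$ref, df$alt, qualCol, info)
    writeLines(c(header, body), path)
    path
}

#' Write a synthetic experiment to disk as pipeline-ready fixtures
#'
#' Emits five plain-text files readable by the package's own readers:
#' the tumor-vs-normal VCF, the same-vs-same VCF, per-base depth TSVs for
#' the tumor and normal samples (covering exactly the configured common
#' coverage), and a truth-label TSV (chrom, pos, alt, label). Identical
#' seeds give byte-identical files.
#'
#' Per-base depth emission is intended for compact test scenarios; totals
#' above \code{maxDepthBases} are refused to avoid runaway file sizes.
#'
#' @param exp a \linkS4class{SyntheticExperiment}.
#' @param outDir output directory (created if needed).
#' @param callerConfig \linkS4class{CallerConfig} controlling the VCF field
#'   layout; defaults to \code{\link{samtoolsConfig}} when the property
#'   names match, else to a generic mapping.
#' @param maxDepthBases refusal threshold for per-base depth emission.
#' @return named character vector of paths: \code{tnVcf, ssVcf,
#'   tumorDepth, normalDepth, labels}.
#' @export
writeFixtures <- function(exp, outDir, callerConfig = NULL,
                          maxDepthBases = 2e6) {
    stopifnot(is(exp, "SyntheticExperiment"))
    config <- exp@config
    if (is.null(callerConfig)) {
        props <- vapply(config$properties, `[[`, character(1), "name")
        callerConfig <- if (setequal(props, samtoolsConfig()@properties))
            samtoolsConfig()
        else CallerConfig("synthetic", props,
                          stats::setNames(c("QUAL", paste0("INFO/P",
                              seq_len(length(props) - 1L)))[seq_along(props)],
                              props), p = 20L)
    }
    covBases <- max(coveredBases(exp@cSS), coveredBases(exp@cTN))
    if (covBases > maxDepthBases)
        stop("per-base depth fixtures refused for ",
             format(covBases, big.mark = ","), " bases (limit ",
             format(maxDepthBases, big.mark = ","),
             "); use a smaller coverage configuration")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(tnVcf = file.path(outDir, "tumor_normal.vcf"),
               ssVcf = file.path(outDir, "same_same.vcf"),
               tumorDepth = file.path(outDir, "tumor_depth.tsv"),
               normalDepth = file.path(outDir, "normal_depth.tsv"),
               labels = file.path(outDir, "labels.tsv"))
    .writeCallSetVcf(exp@tumorNormal, paths[["tnVcf"]], callerConfig)
    .writeCallSetVcf(exp@sameSame, paths[["ssVcf"]], callerConfig)

    set.seed(config$seed)  # depth draws reproducible independently
    nTn <- coveredBases(exp@cTN)
    for (p in c("tumorDepth", "normalDepth")) {
        depth <- stats::rpois(nTn, config$meanDepth - 1) + 1L
        writeLines(sprintf("%s\t%d\t%d", config$contig, seq_len(nTn), depth),
                   paths[[p]])
    }
    lab <- exp@labels
    keyParts <- do.call(rbind, strsplit(names(lab), ":", fixed = TRUE))
    writeLines(c("chrom\tpos\talt\tlabel",
                 sprintf("%s\t%s\t%s\t%s", keyParts[, 1L], keyParts[, 2L],
                         keyParts[, 3L], unname(lab))),
               paths[["labels"]])
    paths
}

#' Read a truth-label TSV
#'
#' @param path TSV with columns chrom, pos, alt, label.
#' @return named character vector of labels keyed by (chrom:pos:alt).
#' @export
readLabels <- function(path) {
    if (!file.exists(path)) stop("label file not found: ", path)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character")
    stats::setNames(df$label, paste(df$chrom, df$pos, df$alt, sep = ":"))
}
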