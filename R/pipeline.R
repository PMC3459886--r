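#' Run a pipeline command
#'
#' Orchestrates the full confidence-assignment workflow from a single
#' structured YAML configuration (or an equivalent R list). Every run
#' writes a log - to stderr and to \code{run.log} in the output directory -
#' recording the config hash, seed, package version, and the record counts
#' in and out of every filter stage.
#'
#' Commands:
#' \describe{
#'   \item{simulate}{write labeled synthetic fixtures (VCFs, depth TSVs,
#'     labels) plus a ready-made config for the downstream commands.}
#'   \item{train}{read the tumor-vs-normal and same-vs-same VCFs and the
#'     coverage inputs, train the \linkS4class{QualityModel}, build the
#'     \linkS4class{FDRFunction}, and persist both to one model file.}
#'   \item{assign}{score a tumor-vs-normal VCF with a trained model, apply
#'     the configured filters, and write the FDR-sorted scored table (TSV
#'     and VCF).}
#'   \item{roc}{estimated ROC curve + AUC from a scored table.}
#'   \item{sweep}{sensitivity/specificity threshold table from a scored
#'     table and truth labels.}
#'   \item{compare}{mean estimated ROC with 95\% band across several
#'     scored tables.}
#' }
#'
#' @param command one of \code{"simulate"}, \code{"train"},
#'   \code{"assign"}, \code{"roc"}, \code{"sweep"}, \code{"compare"}.
#' @param config path to a YAML file, or a named list with the same
#'   structure (see the package vignette for the schema).
#' @param outDir output directory; overrides \code{config$out_dir}.
#' @param seed integer seed; overrides \code{config$seed}.
#' @return named character vector of artifact paths, invisibly.
#' @export
runCommand <- function(command = c("simulate", "train", "assign", "roc",
                                   "sweep", "compare"),
                       config, outDir = NULL, seed = NULL) {
    command <- match.arg(command)
    cfgPath <- NULL
    if (is.character(config)) {
        if (!file.exists(config))
            stop("config file not found: ", config)
        cfgPath <- config
        config <- yaml::read_yaml(config)
    }
    if (!is.list(config)) stop("'config' must be a YAML path or a list")
    if (!is.null(outDir)) config$out_dir <- outDir
    if (!is.null(seed)) config$seed <- seed
    if (is.null(config$out_dir)) stop("config key 'out_dir' is required")
    if (is.null(config$seed)) config$seed <- 1L
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

    logFile <- file.path(config$out_dir, "run.log")
    log <- function(fmt, ...) {
        line <- sprintf("[%s] %s", command, sprintf(fmt, ...))
        message(line)
        cat(line, "\n", file = logFile, append = TRUE, sep = "")
    }
    hash <- if (!is.null(cfgPath)) unname(tools::md5sum(cfgPath)) else
        "(in-memory config)"
    log("somaticFDR %s | seed %s | config %s",
        as.character(utils::packageVersion("somaticFDR")), config$seed, hash)

    out <- switch(command,
        simulate = .cmdSimulate(config, log),
        train = .cmdTrain(config, log),
        assign = .cmdAssign(config, log),
        roc = .cmdRoc(config, log),
        sweep = .cmdSweep(config, log),
        compare = .cmdCompare(config, log))
    log("done: %s", paste(basename(out), collapse = ", "))
    invisible(out)
}

.need <- function(config, key) {
    v <- config[[key]]
    if (is.null(v)) stop("config key '", key, "' is required")
    v
}

.needFile <- function(path, what) {
    if (!file.exists(path))
        stop("input ", what, " does not exist: ", path)
    path
}

.callerConfigFromConfig <- function(config) {
    cc <- config$caller_config
    if (is.null(cc)) return(samtoolsConfig())
    if (is.character(cc))
        return(switch(cc, samtools = samtoolsConfig(), gatk = gatkConfig(),
                      somaticsniper = somaticSniperConfig(),
                      stop("unknown built-in caller config '", cc, "'")))
    CallerConfig(cc$caller, vapply(cc$properties, `[[`, character(1), "name"),
                 stats::setNames(vapply(cc$properties, `[[`, character(1),
                                        "field"),
                                 vapply(cc$properties, `[[`, character(1),
                                        "name")),
                 p = cc$p %||% 20L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a comparison's common coverage: either two depth/BED files or a number
.coverageFromConfig <- function(spec, pairId, log) {
    if (is.numeric(spec)) return(CommonCoverage(spec, pairId))
    a <- readCoverage(.needFile(spec$a, "coverage file"),
                      spec$format %||% "depth_tsv")
    b <- readCoverage(.needFile(spec$b, "coverage file"),
                      spec$format %||% "depth_tsv")
    restrict <- if (!is.null(spec$target_bed))
        rtracklayer::import(.needFile(spec$target_bed, "target BED"),
                            format = "BED")
    cov <- commonCoverage(a, b, restrict = restrict, pairId = pairId)
    log("common coverage (%s): %s bases", pairId,
        format(coveredBases(cov), big.mark = ","))
    cov
}

.cmdSimulate <- function(config, log) {
    sim <- config$synthetic %||% list()
    args <- sim[intersect(names(sim),
                          names(formals(syntheticConfig)))]
    args$seed <- config$seed
    sc <- do.call(syntheticConfig, args)
    exp <- generateExperiment(sc)
    log("simulated %d tumor-vs-normal calls (%d true), %d same-vs-same",
        length(exp@tumorNormal), sum(exp@labels == "positive"),
        length(exp@sameSame))
    paths <- writeFixtures(exp, config$out_dir)
    runCfg <- list(
        out_dir = config$out_dir, seed = config$seed,
        caller_config = "samtools",
        tn_vcf = paths[["tnVcf"]], ss_vcf = paths[["ssVcf"]],
        labels = paths[["labels"]],
        tn_coverage = list(a = paths[["tumorDepth"]],
                           b = paths[["normalDepth"]]),
        ss_coverage = sc$cSS,
        model = file.path(config$out_dir, "model.rds"),
        scored = file.path(config$out_dir, "scored.tsv"))
    cfgOut <- file.path(config$out_dir, "run.yaml")
    yaml::write_yaml(runCfg, cfgOut)
    c(paths, runConfig = cfgOut)
}

.cmdTrain <- function(config, log) {
    cc <- .callerConfigFromConfig(config)
    tn <- readCalls(.needFile(.need(config, "tn_vcf"), "tumor VCF"), cc,
                    "tumor_normal")
    ss <- readCalls(.needFile(.need(config, "ss_vcf"), "same-vs-same VCF"),
                    cc, "same_same")
    for (line in c(provenance(tn), provenance(ss))) log("%s", line)
    cTN <- .coverageFromConfig(.need(config, "tn_coverage"), "tn_pair", log)
    cSS <- .coverageFromConfig(.need(config, "ss_coverage"), "ss_pair", log)
    model <- trainQualityModel(ss, tn, cSS, cTN, cc,
                               sampleFraction = config$sample_fraction %||%
                                   0.01,
                               seed = config$seed)
    log("trained forest on %d of %d grid points", model@meta$nTrain,
        model@meta$gridSize)
    fn <- buildFdrFunction(scoreQuality(model, ss), scoreQuality(model, tn),
                           cSS, cTN, smooth = isTRUE(config$smooth))
    modelPath <- config$model %||% file.path(config$out_dir, "model.rds")
    saveQualityModel(model, modelPath, fdrFunction = fn)
    log("model written to %s", modelPath)
    c(model = modelPath)
}

.applyConfiguredFilters <- function(calls, config, log) {
    if (!is.null(config$normal_depth)) {
        cov <- readCoverage(.needFile(config$normal_depth, "normal depth"),
                            "depth_tsv")
        calls <- filterNormalCoverage(calls, cov)
    }
    if (!is.null(config$blacklist_bed))
        calls <- filterBlacklist(calls, .needFile(config$blacklist_bed,
                                                  "blacklist BED"))
    for (mp in config$min_property %||% list())
        calls <- filterMinProperty(calls, mp$property, mp$threshold)
    for (line in provenance(calls)) log("%s", line)
    calls
}

.cmdAssign <- function(config, log) {
    stored <- loadQualityModel(.needFile(.need(config, "model"),
                                         "model file"))
    cc <- .callerConfigFromConfig(config)
    tn <- readCalls(.needFile(.need(config, "tn_vcf"), "tumor VCF"), cc,
                    "tumor_normal")
    tn <- .applyConfiguredFilters(tn, config, log)
    mcols(tn@ranges)$Q <- scoreQuality(stored$model, tn)
    fn <- stored$fdrFunction
    if (is.null(fn)) stop("model file carries no FDRFunction; run 'train'")
    if (isTRUE(config$refit_tn))
        fn <- reuseReference(fn, mcols(tn@ranges)$Q)
    scored <- assignFdr(fn, tn)
    log("assigned FDRs to %d calls (median %.3f)", length(scored),
        stats::median(mcols(scored@ranges)$FDR))
    tsv <- file.path(config$out_dir, "scored.tsv")
    vcf <- file.path(config$out_dir, "scored.vcf")
    writeScoredCalls(scored, tsv, "tsv")
    writeScoredCalls(scored, vcf, "vcf")
    c(scoredTsv = tsv, scoredVcf = vcf)
}

.cmdRoc <- function(config, log) {
    df <- readScoredCalls(.needFile(.need(config, "scored"),
                                    "scored table"))
    curve <- rocFromFdrs(df$FDR)
    log("estimated ROC over %d mutations: AUC = %.4f", nrow(df), auc(curve))
    out <- file.path(config$out_dir, "roc.tsv")
    utils::write.table(cbind(rocPoints(curve), auc = auc(curve)), out,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(roc = out)
    if (isTRUE(config$plot)) {
        png <- file.path(config$out_dir, "roc.png")
        grDevices::png(png, width = 600, height = 600)
        plotRoc(curve, main = sprintf("Estimated ROC (AUC = %.3f)",
                                      auc(curve)))
        grDevices::dev.off()
        paths <- c(paths, plot = png)
    }
    paths
}

.joinLabels <- function(df, labels) {
    key <- paste(df$chrom, df$pos, df$alt, sep = ":")
    lab <- unname(labels[key])
    lab[is.na(lab)] <- "inconclusive"
    lab
}

.cmdSweep <- function(config, log) {
    df <- readScoredCalls(.needFile(.need(config, "scored"),
                                    "scored table"))
    labels <- readLabels(.needFile(.need(config, "labels"), "label TSV"))
    lab <- .joinLabels(df, labels)
    tab <- thresholdSweep(df$FDR, lab, step = config$step %||% 0.05)
    log("threshold sweep: %d thresholds, %d labeled calls", nrow(tab),
        sum(lab != "inconclusive"))
    out <- file.path(config$out_dir, "sweep.tsv")
    utils::write.table(tab, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    c(sweep = out)
}

.cmdCompare <- function(config, log) {
    paths <- .need(config, "scored_sets")
    if (length(paths) < 2L) stop("'compare' needs at least 2 scored tables")
    sets <- lapply(paths, function(p)
        readScoredCalls(.needFile(p, "scored table"))$FDR)
    mr <- meanRoc(sets, nPositions = config$n_positions %||% 100L)
    log("mean estimated ROC over %d member sets", mr@nMembers)
    out <- file.path(config$out_dir, "mean_roc.tsv")
    utils::write.table(meanRocTable(mr), out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    c(meanRoc = out)
}
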