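# Shared fixture builders and independent oracles. Everything is generated
# in code; no files ship with the tests.

# --- toy VCF ---------------------------------------------------------------

# Minimal samtools-style VCF (QUAL + INFO DP/CQ/MQ); `rows` are body lines.
writeToyVcf <- function(rows, path = tempfile(fileext = ".vcf")) {
    header <- c("##fileformat=VCFv4.2",
        "##contig=<ID=chrT>",
        "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
        "##INFO=<ID=CQ,Number=1,Type=Float,Description=\"consensus quality\">",
        "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"rms mapping quality\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              sep = "\t"))
    writeLines(c(header, rows), path)
    path
}

toyVcfRow <- function(pos, ref, alt, qual = 30, dp = 10, cq = 25, mq = 40) {
    sprintf("chrT\t%d\t.\t%s\t%s\t%s\t.\tDP=%s;CQ=%s;MQ=%s",
            pos, ref, alt, format(qual), format(dp), format(cq), format(mq))
}

# --- toy CallSet -----------------------------------------------------------

toyCallSet <- function(pos = c(100L, 200L, 300L),
                       alt = NULL,
                       snpq = seq(30, by = 5, length.out = length(pos)),
                       comparison = "tumor_normal",
                       caller = "toy", pairId = "p1") {
    n <- length(pos)
    ref <- rep(c("A", "C", "G", "T"), length.out = n)
    if (is.null(alt)) alt <- rep(c("G", "T", "A", "C"), length.out = n)
    CallSet(chrom = "chrT", pos = pos, ref = ref, alt = alt,
            qualities = data.frame(snpq = snpq,
                                   depth = seq_len(n) + 10),
            caller = caller, comparison = comparison, pairId = pairId)
}

# --- independent oracles ---------------------------------------------------

# brute-force double loop for dominance counting
bruteCountAtOrAbove <- function(point, pool) {
    n <- 0L
    for (i in seq_len(nrow(pool))) {
        ok <- TRUE
        for (j in seq_along(point))
            if (pool[i, j] < point[j]) { ok <- FALSE; break }
        if (ok) n <- n + 1L
    }
    n
}

# direct-counting FDR evaluator (no sorting tricks)
bruteFdr <- function(q, ssQ, tnQ, cSS, cTN) {
    vapply(q, function(x) {
        nSS <- sum(ssQ >= x); nTN <- sum(tnQ >= x)
        if (nTN == 0) return(if (nSS == 0) 0 else 1)
        min(1, max(0, (nSS / cSS) / (nTN / cTN)))
    }, numeric(1))
}

# Mann-Whitney pair counting: (concordant + ties/2) / (nPos * nNeg)
pairCountAuc <- function(score, isPos) {
    pos <- score[isPos]; neg <- score[!isPos]
    tot <- 0
    for (p in pos) for (n in neg)
        tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
    tot / (length(pos) * length(neg))
}

# per-base set intersection for coverage tracks on one small contig
brutePerBaseCommon <- function(covA, covB, maxPos = 500L) {
    inTrack <- function(track, pos) {
        gr <- track@ranges
        any(GenomicRanges::start(gr) <= pos & GenomicRanges::end(gr) >= pos)
    }
    sum(vapply(seq_len(maxPos), function(p)
        inTrack(covA, p) && inTrack(covB, p), logical(1)))
}

# --- cached end-to-end pipeline runs ---------------------------------------

.pipelineCache <- new.env(parent = emptyenv())

# generate -> train -> score -> assign; memoized across test files
trainedPipeline <- function(nTn = 2000L, shiftScale = 1, seed = 1L,
                            trueFraction = 0.5) {
    key <- paste(nTn, shiftScale, seed, trueFraction, sep = "|")
    if (!is.null(.pipelineCache[[key]])) return(.pipelineCache[[key]])
    cfg <- syntheticConfig(nTnCalls = nTn, trueFraction = trueFraction,
                           properties = syntheticProperties(shiftScale),
                           seed = seed)
    exp <- generateExperiment(cfg)
    model <- suppressWarnings(trainQualityModel(
        exp@sameSame, exp@tumorNormal, exp@cSS, exp@cTN, samtoolsConfig(),
        seed = seed))
    qTn <- scoreQuality(model, exp@tumorNormal)
    qSs <- scoreQuality(model, exp@sameSame)
    fn <- buildFdrFunction(qSs, qTn, exp@cSS, exp@cTN)
    fdr <- evaluateFdr(fn, qTn)
    labels <- unname(syntheticLabels(exp))
    out <- list(exp = exp, model = model, qTn = qTn, qSs = qSs, fn = fn,
                fdr = fdr, labels = labels)
    .pipelineCache[[key]] <- out
    out
}
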