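test_that("VCF ingestion keeps biallelic SNVs and their mapped qualities", {
    path <- writeToyVcf(c(toyVcfRow(100L, "A", "G", qual = 50, dp = 12),
                          toyVcfRow(200L, "C", "T", qual = 40, dp = 8),
                          toyVcfRow(300L, "G", "A", qual = 30, dp = 5)))
    cs <- readCalls(path, samtoolsConfig(), "tumor_normal", "p1")
    expect_s4_class(cs, "CallSet")
    expect_equal(length(cs), 3L)
    df <- as.data.frame(cs)
    expect_equal(df$pos, c(100L, 200L, 300L))
    expect_equal(df$snp_quality, c(50, 40, 30))
    expect_equal(df$coverage_depth, c(12, 8, 5))
    expect_equal(caller(cs), "samtools")
})

test_that("indel records are skipped and logged; multi-allelic records split", {
    path <- writeToyVcf(c(toyVcfRow(100L, "A", "G"),
                          toyVcfRow(150L, "C", "CAT"),     # insertion
                          toyVcfRow(200L, "G", "T,C"),     # multi-allelic
                          toyVcfRow(250L, "TA", "T")))     # deletion
    cs <- readCalls(path, samtoolsConfig(), "tumor_normal", "p1")
    df <- as.data.frame(cs)
    expect_equal(df$pos, c(100L, 200L, 200L))
    expect_equal(df$alt, c("G", "T", "C"))
    # both alt alleles of the split record inherit the record's qualities
    expect_equal(df$snp_quality[2], df$snp_quality[3])
    expect_match(paste(provenance(cs), collapse = " "), "2 indel")
})

test_that("a record missing a mapped field is a hard error naming the field", {
    rows <- c(toyVcfRow(100L, "A", "G"),
              "chrT\t200\t.\tC\tT\t40\t.\tCQ=25;MQ=40")  # no DP
    path <- writeToyVcf(rows)
    expect_error(readCalls(path, samtoolsConfig(), "tumor_normal"),
                 "DP")
    expect_error(readCalls(tempfile(), samtoolsConfig()), "not found")
})

test_that("normal-coverage filtering keeps loci sequenced in the normal", {
    cs <- toyCallSet(pos = c(100L, 500L))
    cov <- CoverageTrack(GenomicRanges::GRanges("chrT:90-110"), "normal")
    kept <- filterNormalCoverage(cs, cov)
    expect_equal(length(kept), 1L)
    expect_equal(as.data.frame(kept)$pos, 100L)
    expect_match(provenance(kept)[1], "removed 1 of 2")

    covAll <- CoverageTrack(GenomicRanges::GRanges("chrT:1-1000"))
    expect_equal(as.data.frame(filterNormalCoverage(cs, covAll)),
                 as.data.frame(cs))
    empty <- toyCallSet(pos = integer(0), snpq = numeric(0))
    expect_equal(length(filterNormalCoverage(empty, cov)), 0L)
    ssSet <- toyCallSet(comparison = "same_same")
    expect_error(filterNormalCoverage(ssSet, cov), "tumor_normal")
})

test_that("blacklist filtering honors BED half-open boundary semantics", {
    bed <- tempfile(fileext = ".bed")
    writeLines("chrT\t100\t200", bed)  # 0-based [100, 200)
    cs <- toyCallSet(pos = c(100L, 101L, 200L, 201L))
    kept <- filterBlacklist(cs, bed)
    # 1-based pos p is inside iff 100 <= p-1 < 200: 101..200 removed
    expect_equal(as.data.frame(kept)$pos, c(100L, 201L))
    expect_equal(length(filterBlacklist(cs, GenomicRanges::GRanges())),
                 length(cs))
})

test_that("minimum-property filtering uses an inclusive threshold", {
    cs <- toyCallSet(pos = c(1L, 2L, 3L), snpq = c(29, 30, 31))
    kept <- filterMinProperty(cs, "snpq", 30)
    expect_equal(as.data.frame(kept)$snpq, c(30, 31))
    expect_equal(length(filterMinProperty(cs, "snpq", -Inf)), 3L)
    expect_error(filterMinProperty(cs, "nope", 1), "unknown quality property")
})

test_that("filters are idempotent and commute", {
    set.seed(42)
    cs <- toyCallSet(pos = sample.int(1000, 40), snpq = runif(40, 0, 60))
    cov <- CoverageTrack(GenomicRanges::GRanges(
        "chrT", IRanges::IRanges(start = c(1, 400), end = c(300, 800))))
    bl <- GenomicRanges::GRanges("chrT:150-600")
    ap <- function(x, which) switch(which,
        cov = filterNormalCoverage(x, cov),
        bl = filterBlacklist(x, bl),
        mp = filterMinProperty(x, "snpq", 20))
    once <- ap(ap(ap(cs, "cov"), "bl"), "mp")
    twice <- ap(ap(once, "cov"), "bl")
    expect_equal(as.data.frame(twice), as.data.frame(once))
    for (ord in list(c("bl", "mp", "cov"), c("mp", "cov", "bl"))) {
        alt <- Reduce(ap, ord, accumulate = FALSE, init = cs)
        expect_equal(as.data.frame(alt), as.data.frame(once))
    }
})

test_that("pairing intersection keeps keys present in every set", {
    # same alt allele at shared loci so the (chrom, pos, alt) keys agree
    a <- toyCallSet(pos = c(10L, 20L, 30L), alt = c("T", "T", "T"),
                    snpq = c(1, 2, 3))
    b <- toyCallSet(pos = c(20L, 30L, 40L), alt = c("T", "T", "T"),
                    snpq = c(9, 9, 9))
    c3 <- toyCallSet(pos = c(5L, 20L, 30L), alt = c("T", "T", "T"),
                     snpq = c(7, 7, 7))
    out <- intersectPairings(list(a, b, c3))
    expect_equal(as.data.frame(out)$pos, c(20L, 30L))
    # qualities come from the first listed set
    expect_equal(as.data.frame(out)$snpq, c(2, 3))
    # a key present in 2 of 3 sets is excluded
    expect_false(10L %in% as.data.frame(out)$pos)
    expect_equal(as.data.frame(intersectPairings(list(a))),
                 as.data.frame(a))
    expect_error(intersectPairings(list()), "non-empty")
    expect_lte(length(out), min(length(a), length(b), length(c3)))
    # alt identity is part of the consensus key
    d <- toyCallSet(pos = c(20L, 30L), alt = c("G", "T"), snpq = c(1, 1))
    out2 <- intersectPairings(list(a, d))
    expect_equal(as.data.frame(out2)$pos, 30L)
})

test_that("scored tables are FDR-sorted and round-trip losslessly", {
    cs <- toyCallSet(pos = c(100L, 200L))
    S4Vectors::mcols(cs@ranges)$Q <- c(0.2, 0.9)
    S4Vectors::mcols(cs@ranges)$FDR <- c(0.5, 0.006)
    tsv <- tempfile(fileext = ".tsv")
    writeScoredCalls(cs, tsv, "tsv")
    back <- readScoredCalls(tsv)
    expect_equal(back$FDR, c(0.006, 0.5))   # ascending
    expect_equal(back$pos, c(200L, 100L))
    # round-trip through write -> read -> write is lossless
    tsv2 <- tempfile(fileext = ".tsv")
    writeScoredCalls(back, tsv2, "tsv")
    expect_identical(readLines(tsv), readLines(tsv2))

    # empty set -> header-only file
    empty <- toyCallSet(pos = integer(0), snpq = numeric(0))
    S4Vectors::mcols(empty@ranges)$Q <- numeric(0)
    S4Vectors::mcols(empty@ranges)$FDR <- numeric(0)
    tsv3 <- tempfile(fileext = ".tsv")
    writeScoredCalls(empty, tsv3, "tsv")
    expect_equal(length(readLines(tsv3)), 1L)

    # VCF output carries Q and FDR as INFO keys and parses as VCF
    vcf <- tempfile(fileext = ".vcf")
    writeScoredCalls(cs, vcf, "vcf")
    v <- VariantAnnotation::readVcf(vcf)
    expect_equal(unname(VariantAnnotation::info(v)$FDR), c(0.006, 0.5))
    expect_equal(unname(VariantAnnotation::info(v)$GQS), c(0.9, 0.2))
})
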