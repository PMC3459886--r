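test_that("dominance is componentwise-strict and irreflexive", {
    expect_true(dominates(c(30, 10), c(20, 5)))
    expect_false(dominates(c(30, 5), c(20, 10)))   # incomparable
    expect_false(dominates(c(20, 10), c(30, 5)))
    expect_false(dominates(c(30, 10), c(30, 5)))   # equality not strict
    expect_false(dominates(c(7, 7), c(7, 7)))      # irreflexive
    expect_error(dominates(c(1, 2), c(1, 2, 3)), "arity")
})

test_that("at-or-above counting includes equality and matches brute force", {
    pool <- rbind(c(30, 30), c(10, 10))
    expect_equal(countAtOrAbove(c(10, 10), pool), 2L)
    expect_equal(countAtOrAbove(c(30, 30), pool), 1L)
    expect_equal(countAtOrAbove(c(31, 31), pool), 0L)
    set.seed(11)
    for (rep in 1:30) {
        d <- sample(2:5, 1)
        pool <- matrix(sample.int(6, d * 50, replace = TRUE), ncol = d)
        point <- sample.int(6, d, replace = TRUE)
        expect_equal(countAtOrAbove(point, pool),
                     bruteCountAtOrAbove(point, pool))
    }
})

test_that("the intermediate FDR is the coverage-normalized dominance ratio", {
    ss <- rbind(c(10, 10))
    tn <- rbind(c(30, 30), c(10, 10))
    expect_equal(ifdr(c(30, 30), ss, tn, 1e6, 1e6), 0)     # no ss at-or-above
    expect_equal(ifdr(c(10, 10), ss, tn, 1e6, 1e6), 0.5)   # 1/2, equal coverage
    # doubling the tumor coverage doubles the ratio, then clamps exactly
    expect_equal(ifdr(c(10, 10), ss, tn, 1e6, 2e6), 1)
    expect_error(ifdr(c(10, 10), ss, tn, 0, 1e6), "positive")
    # clamped to [0, 1] under any coverage imbalance
    expect_lte(ifdr(c(10, 10), ss, tn, 1, 1e9), 1)
    # empty tumor tail with empty ss tail is 0, with non-empty ss tail is 1
    expect_equal(ifdr(c(40, 40), ss, tn, 1e6, 1e6), 0)
    expect_equal(ifdr(c(5, 31), rbind(c(10, 40)), tn, 1e6, 1e6), 1)
})

test_that("quality-grid sampling spans ranges and respects small value sets", {
    one <- matrix(c(0, seq(3, 97, length.out = 40), 100),
                  dimnames = list(NULL, "a"))
    g <- sampleQualityGrid(one, 20)   # 42 distinct values -> 20 sampled
    expect_equal(nrow(g), 20L)
    expect_equal(range(g[, "a"]), c(0, 100))
    expect_equal(diff(g[, "a"]), rep(100 / 19, 19))   # uniform spacing
    # fewer distinct values than p: the observed set is used verbatim
    three <- matrix(c(0, 25, 100), dimnames = list(NULL, "a"))
    expect_equal(sampleQualityGrid(three, 20)[, "a"], c(0, 25, 100))

    binary <- matrix(c(0, 1, 0, 1), dimnames = list(NULL, "b"))
    expect_equal(sampleQualityGrid(binary, 20)[, "b"], c(0, 1))

    two <- cbind(x = runif(30, 0, 50), y = runif(30, 0, 9))
    g2 <- sampleQualityGrid(two, 12)
    expect_lte(nrow(g2), 144L)   # p^n bound
    expect_equal(ncol(g2), 2L)
    expect_error(sampleQualityGrid(two, 1), ">= 2")
})

test_that("training subsamples the grid with a 1000-point floor", {
    set.seed(3)
    ss <- cbind(a = runif(300, 0, 40), b = runif(300, 0, 40))
    tn <- cbind(a = runif(300, 0, 100), b = runif(300, 0, 100))
    cfg <- CallerConfig("toy", c("a", "b"),
                        c(a = "QUAL", b = "INFO/DP"), p = 100L)
    m <- trainQualityModel(ss, tn, 1e6, 1e6, cfg, sampleFraction = 0.01,
                           seed = 5, ntree = 50)
    expect_equal(m@meta$gridSize, 10000L)
    expect_equal(m@meta$nTrain, 1000L)   # floor beats 1% of 10,000
    # tiny grid: the whole grid is used
    cfg2 <- CallerConfig("toy", c("a", "b"),
                         c(a = "QUAL", b = "INFO/DP"), p = 5L)
    # a 25-point grid has few distinct IFDR values, which randomForest flags
    m2 <- suppressWarnings(trainQualityModel(ss, tn, 1e6, 1e6, cfg2,
                                             seed = 5, ntree = 50))
    expect_equal(m2@meta$nTrain, m2@meta$gridSize)
})

test_that("seeded training is reproducible and Q is oriented as 1 - IFDR", {
    set.seed(8)
    ss <- cbind(a = runif(200, 0, 30), b = runif(200, 0, 30))
    tn <- rbind(cbind(a = runif(150, 40, 100), b = runif(150, 40, 100)),
                cbind(a = runif(150, 0, 30), b = runif(150, 0, 30)))
    cfg <- CallerConfig("toy", c("a", "b"),
                        c(a = "QUAL", b = "INFO/DP"), p = 15L)
    probes <- cbind(a = runif(50, 0, 100), b = runif(50, 0, 100))
    # cleanly separated pools make the IFDR response nearly binary, which
    # randomForest flags; that is exactly the intended geometry here
    m1 <- suppressWarnings(trainQualityModel(ss, tn, 1e6, 1e6, cfg,
                                             seed = 42))
    m2 <- suppressWarnings(trainQualityModel(ss, tn, 1e6, 1e6, cfg,
                                             seed = 42))
    expect_identical(scoreQuality(m1, probes), scoreQuality(m2, probes))

    q <- scoreQuality(m1, probes)
    expect_true(all(q >= 0 & q <= 1))
    # well-separated data: scores at the model's own training points track
    # the training IFDR closely
    inSample <- scoreQuality(m1, m1@meta$trainX)
    expect_lt(mean(abs((1 - inSample) - m1@meta$trainY)), 0.1)
    expect_error(scoreQuality(m1, cbind(a = 1)), "lacks properties")
})

test_that("with one property, Q recovers the property's ranking", {
    prop1 <- list(list(name = "snp_quality", mean = 30, sd = 12, min = 0,
                       max = 255, shift = 24))
    cfg <- syntheticConfig(nTnCalls = 1500L, properties = prop1, seed = 5)
    exp <- generateExperiment(cfg)
    cc <- CallerConfig("synthetic", "snp_quality",
                       c(snp_quality = "QUAL"), p = 20L)
    m <- trainQualityModel(exp@sameSame, exp@tumorNormal, exp@cSS, exp@cTN,
                           cc, seed = 5)
    probes <- matrix(seq(0, 80, length.out = 400), ncol = 1,
                     dimnames = list(NULL, "snp_quality"))
    rho <- cor(probes[, 1], scoreQuality(m, probes), method = "spearman")
    expect_gte(rho, 0.9)
})

test_that("model persistence round-trips model and FDR function", {
    pl <- trainedPipeline(nTn = 500L, seed = 2)
    path <- tempfile(fileext = ".rds")
    saveQualityModel(pl$model, path, fdrFunction = pl$fn)
    back <- loadQualityModel(path)
    probes <- qualityMatrix(pl$exp@tumorNormal)[1:20, ]
    expect_identical(scoreQuality(back$model, probes),
                     scoreQuality(pl$model, probes))
    expect_equal(evaluateFdr(back$fdrFunction, c(0.1, 0.5, 0.9)),
                 evaluateFdr(pl$fn, c(0.1, 0.5, 0.9)))
    junk <- tempfile(); saveRDS(list(a = 1), junk)
    expect_error(loadQualityModel(junk), "model container")
})
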