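test_that("constant-FDR lists give the diagonal and AUC exactly 0.5", {
    for (const in c(0.1, 0.5, 0.9)) {
        curve <- rocFromFdrs(rep(const, 50))
        expect_identical(auc(curve), 0.5)
        pts <- rocPoints(curve)
        expect_equal(pts$fpr, pts$tpr)   # every point on the diagonal
    }
    # a single mutation normalizes to one full step
    expect_identical(auc(rocFromFdrs(0.3)), 0.5)
})

test_that("estimated curves accumulate FDR/1-FDR contributions in FDR order", {
    curve <- rocFromFdrs(c(0.0, 0.0, 1.0, 1.0))
    expect_equal(auc(curve), 1.0)
    pts <- rocPoints(curve)
    expect_equal(pts$fpr, c(0, 0, 1))
    expect_equal(pts$tpr, c(0, 1, 1))
    expect_error(rocFromFdrs(c(0.5, 1.2)), "\\[0, 1\\]")
    expect_error(rocFromFdrs(numeric(0)), "non-empty")
    # curve starts at (0,0), ends at (1,1), both axes non-decreasing
    set.seed(4)
    f <- runif(200)
    pts <- rocPoints(rocFromFdrs(f))
    expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
    expect_true(!is.unsorted(pts$fpr) && !is.unsorted(pts$tpr))
    # AUC invariant under duplication of the FDR list
    for (k in c(2, 5))
        expect_equal(auc(rocFromFdrs(rep(f, k))), auc(rocFromFdrs(f)))
    # degenerate all-zero / all-one lists stay inside the unit square
    expect_equal(auc(rocFromFdrs(rep(0, 5))), 1)
    expect_equal(auc(rocFromFdrs(rep(1, 5))), 0)
})

test_that("trapezoid integration matches a fine Riemann oracle", {
    expect_equal(aucTrapezoid(c(0, 1), c(0, 1)), 0.5)
    expect_equal(aucTrapezoid(c(0, 0, 1), c(0, 1, 1)), 1.0)
    expect_error(aucTrapezoid(c(0.5, 0.2), c(0, 1)), "non-decreasing")
    expect_error(aucTrapezoid(c(0, 2), c(0, 1)), "unit square")
    set.seed(13)
    for (rep in 1:10) {
        x <- sort(runif(30)); x <- c(0, x, 1)
        y <- sort(runif(30)); y <- c(0, y, 1)
        # Riemann sum on a fine partition refined with the curve's knots
        grid <- sort(unique(c(seq(0, 1, length.out = 1e5 + 1), x)))
        fy <- approx(x, y, xout = grid, ties = "ordered")$y
        riemann <- sum(diff(grid) * (fy[-1] + fy[-length(fy)]) / 2)
        expect_equal(aucTrapezoid(x, y), riemann, tolerance = 1e-9)
    }
})

test_that("labeled ROC uses 1-FDR as score and matches pair counting", {
    expect_equal(auc(rocFromLabels(c(0, 0, 1, 1),
        c("positive", "positive", "negative", "negative"))), 1)
    # identical scores for all: one tie group, chance performance
    expect_equal(auc(rocFromLabels(rep(0.3, 6),
        rep(c("positive", "negative"), 3))), 0.5)
    expect_error(rocFromLabels(c(0.1, 0.2), c("positive", "positive")),
                 "at least one")
    # inconclusive labels are excluded, not counted either way
    expect_equal(auc(rocFromLabels(c(0, 1, 0.2),
        c("positive", "negative", "inconclusive"))),
        auc(rocFromLabels(c(0, 1), c("positive", "negative"))))

    # the 4-item toy, frozen from the pair-count oracle
    toyF <- c(0.1, 0.2, 0.3, 0.05)
    toyL <- c("positive", "positive", "negative", "negative")
    expect_equal(pairCountAuc(1 - toyF, toyL == "positive"), 0.5)
    expect_equal(auc(rocFromLabels(toyF, toyL)), 0.5)

    set.seed(17)
    for (rep in 1:30) {
        n <- sample(4:40, 1)
        f <- round(runif(n), 2)   # rounded to force ties
        lab <- ifelse(rbinom(n, 1, 0.5) == 1, "positive", "negative")
        if (length(unique(lab)) < 2) next
        expect_equal(auc(rocFromLabels(f, lab)),
                     pairCountAuc(1 - f, lab == "positive"))
    }
})

test_that("mean curves average member curves with a 95% band", {
    set.seed(9)
    f <- runif(100)
    m <- meanRoc(replicate(5, f, simplify = FALSE))
    expect_equal(m@nMembers, 5L)
    expect_true(all(m@hwFpr == 0) && all(m@hwTpr == 0))  # no variance
    # constant-FDR members are diagonals regardless of the constant
    m2 <- meanRoc(list(rep(0.2, 40), rep(0.8, 40)))
    expect_equal(m2@meanFpr, m2@positions, tolerance = 1e-12)
    expect_equal(m2@meanTpr, m2@positions, tolerance = 1e-12)
    # as many member sets as reference-set combinations in a triplicate design
    m3 <- meanRoc(lapply(1:18, function(i) runif(30)))
    expect_equal(m3@nMembers, 18L)
    expect_error(meanRoc(list(runif(5))), "at least 2")
    tab <- meanRocTable(m2)
    expect_true(all(tab$fprLo <= tab$fpr & tab$fpr <= tab$fprHi))
})

test_that("threshold sweeps classify at fdr <= t and tabulate 21 rows", {
    f <- c(0.02, 0.3, 0.6, 0.9)
    lab <- c("positive", "positive", "negative", "negative")
    tab <- thresholdSweep(f, lab, step = 0.05)
    expect_equal(nrow(tab), 21L)
    expect_equal(tab$threshold, seq(0, 1, 0.05))
    expect_equal(tab$sensitivity[tab$threshold == 1], 1)   # all predicted +
    expect_equal(tab$specificity[tab$threshold == 0], 1)   # all fdrs > 0
    # at t = 0.3 the second positive is recovered (inclusive threshold)
    at03 <- which.min(abs(tab$threshold - 0.3))
    expect_equal(tab$sensitivity[at03], 1)
    expect_equal(tab$specificity[at03], 1)
    # inconclusive labels do not enter either denominator
    tab2 <- thresholdSweep(c(f, 0.5), c(lab, "inconclusive"), step = 0.5)
    expect_equal(tab2$tp + tab2$fp + tab2$tn + tab2$fn, rep(4L, 3))
})

test_that("resampled AUC balances group sizes and is seed-stable", {
    high <- data.frame(fdr = runif(50, 0, 0.02),
                       label = "positive", stringsAsFactors = FALSE)
    low <- data.frame(fdr = runif(44, 0.9, 1),
                      label = "negative", stringsAsFactors = FALSE)
    r <- resampledAuc(high, low, nPerGroup = 10, reps = 50, seed = 3)
    expect_equal(r$meanAuc, 1)
    expect_equal(r$sd, 0)
    # overlapping score ranges: each draw changes the rank pattern
    set.seed(31)
    highO <- data.frame(fdr = runif(50, 0, 0.5), label = "positive",
                        stringsAsFactors = FALSE)
    lowO <- data.frame(fdr = runif(44, 0.3, 1), label = "negative",
                       stringsAsFactors = FALSE)
    inter <- data.frame(fdr = runif(37, 0.1, 0.6),
                        label = sample(c("positive", "negative"), 37,
                                       replace = TRUE),
                        stringsAsFactors = FALSE)
    r2 <- resampledAuc(highO, lowO, inter, nPerGroup = 10, reps = 200,
                       seed = 11)
    r3 <- resampledAuc(highO, lowO, inter, nPerGroup = 10, reps = 200,
                       seed = 11)
    expect_identical(r2[c("meanAuc", "sd")], r3[c("meanAuc", "sd")])
    expect_gt(r2$sd, 0)
    expect_error(resampledAuc(high[1:5, ], low, nPerGroup = 10),
                 "smaller than")
})
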