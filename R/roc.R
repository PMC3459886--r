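#' Trapezoid area under an ROC curve
#'
#' Sums the areas of all consecutive trapezoids between the curve and the
#' x-axis.
#'
#' @param fpr,tpr curve coordinates; \code{fpr} must be non-decreasing and
#'   both must lie in [0, 1]. \code{fpr} may also be a two-column
#'   matrix/data.frame of (fpr, tpr).
#' @return the area.
#' @examples
#' aucTrapezoid(c(0, 1), c(0, 1))     # 0.5
#' aucTrapezoid(c(0, 0, 1), c(0, 1, 1))  # 1
#' @export
aucTrapezoid <- function(fpr, tpr = NULL) {
    if (is.null(tpr)) {
        m <- as.matrix(fpr); fpr <- m[, 1L]; tpr <- m[, 2L]
    }
    stopifnot(length(fpr) == length(tpr), length(fpr) >= 2L)
    if (is.unsorted(fpr)) stop("'fpr' must be non-decreasing")
    if (any(fpr < 0 | fpr > 1 | tpr < 0 | tpr > 1))
        stop("curve points must lie in the unit square")
    n <- length(fpr)
    sum(diff(fpr) * (tpr[-1L] + tpr[-n]) / 2)
}

# raw estimated-curve geometry: tie-collapsed steps plus the rank-fraction
# axis used for curve averaging
.estimatedRocPoints <- function(fdrs) {
    fdrs <- as.numeric(fdrs)
    if (!length(fdrs)) stop("'fdrs' must be non-empty")
    if (any(!is.finite(fdrs)) || any(fdrs < 0 | fdrs > 1))
        stop("all FDRs must lie in [0, 1]")
    # per mutation: FP contribution = FDR, TP contribution = 1 - FDR
    # (the unique solution of FDR = FPR/(FPR+TPR) with FPR + TPR = 1);
    # equal-FDR mutations merge into a single order-independent step
    u <- sort(unique(fdrs))
    cnt <- tabulate(match(fdrs, u), nbins = length(u))
    fp <- cumsum(u * cnt)
    tp <- cumsum((1 - u) * cnt)
    n <- length(fdrs)
    totFp <- fp[length(fp)]; totTp <- tp[length(tp)]
    fpr <- c(0, if (totFp > 0) fp / totFp else rep(0, length(fp)))
    tpr <- c(0, if (totTp > 0) tp / totTp else rep(0, length(tp)))
    t <- c(0, (fp + tp) / n)   # each mutation contributes exactly 1 overall
    last <- length(fpr)
    if (fpr[last] != 1 || tpr[last] != 1) {   # degenerate all-0 / all-1 input
        fpr <- c(fpr, 1); tpr <- c(tpr, 1); t <- c(t, 1)
    }
    list(fpr = fpr, tpr = tpr, t = t)
}

#' Estimated ROC curve from per-mutation FDRs alone
#'
#' Builds an ROC curve without validation labels: each mutation contributes
#' its FDR to the false-positive sum and 1 - FDR to the true-positive sum
#' (so each mutation's two contributions add to one). Mutations are sorted
#' by FDR ascending, equal-FDR mutations are merged into one step, the
#' cumulative sums are normalized by the grand totals, (0, 0) is prepended,
#' and the AUC is the trapezoid integral. A list of identical FDRs of 0.5
#' gives the diagonal and an AUC of exactly 0.5 - no information, random
#' ranking.
#'
#' @param fdrs numeric vector of per-mutation FDRs in [0, 1].
#' @return an \linkS4class{ROCCurve} of kind \code{"estimated"}.
#' @examples
#' auc(rocFromFdrs(rep(0.5, 100)))          # 0.5
#' auc(rocFromFdrs(c(0, 0, 1, 1)))          # 1
#' @export
rocFromFdrs <- function(fdrs) {
    p <- .estimatedRocPoints(fdrs)
    new("ROCCurve", fpr = p$fpr, tpr = p$tpr,
        auc = aucTrapezoid(p$fpr, p$tpr), kind = "estimated")
}

#' Classical ROC curve from validation labels
#'
#' Uses \code{1 - FDR} as the probability that a mutation is a true call
#' and sweeps a threshold over the distinct scores in descending order;
#' at each threshold the TPR is the fraction of validated-positive
#' mutations at-or-above it and the FPR the fraction of
#' validated-negative ones. Inconclusive labels are excluded.
#'
#' @param fdr numeric vector of per-mutation FDRs in [0, 1].
#' @param label parallel character vector: \code{"positive"},
#'   \code{"negative"} (or \code{"inconclusive"}, dropped).
#' @return an \linkS4class{ROCCurve} of kind \code{"labeled"}.
#' @examples
#' auc(rocFromLabels(c(0, 0, 1, 1), c("positive", "positive",
#'                                    "negative", "negative")))  # 1
#' @export
rocFromLabels <- function(fdr, label) {
    stopifnot(length(fdr) == length(label))
    keep <- label %in% c("positive", "negative")
    fdr <- as.numeric(fdr[keep]); label <- label[keep]
    if (any(!is.finite(fdr)) || any(fdr < 0 | fdr > 1))
        stop("all FDRs must lie in [0, 1]")
    nPos <- sum(label == "positive"); nNeg <- sum(label == "negative")
    if (nPos == 0L || nNeg == 0L)
        stop("need at least one positive and one negative label")
    score <- 1 - fdr
    o <- order(score, decreasing = TRUE)
    score <- score[o]; pos <- label[o] == "positive"
    # cumulative counts after each tie group of equal scores
    grpEnd <- which(!duplicated(score, fromLast = TRUE))
    tpr <- c(0, cumsum(pos)[grpEnd] / nPos)
    fpr <- c(0, cumsum(!pos)[grpEnd] / nNeg)
    new("ROCCurve", fpr = fpr, tpr = tpr, auc = aucTrapezoid(fpr, tpr),
        kind = "labeled")
}

#' @rdname ROCCurve-class
#' @export
setMethod("auc", "ROCCurve", function(x) x@auc)

#' @rdname ROCCurve-class
#' @export
setMethod("rocPoints", "ROCCurve",
          function(x) data.frame(fpr = x@fpr, tpr = x@tpr))

setMethod("show", "ROCCurve", function(object) {
    cat(object@kind, "ROCCurve:", length(object@fpr), "points, AUC =",
        format(object@auc, digits = 4), "\n")
})

#' Mean estimated ROC curve with 95\% confidence band
#'
#' Converts each member FDR set into an estimated ROC curve, aligns the
#' curves on a common axis - the cumulative rank fraction of the
#' FDR-sorted mutation list (each mutation advances the curve by exactly
#' one unit of combined contribution) - by linear interpolation at
#' \code{nPositions} uniform positions, and reports the pointwise mean and
#' a 95\% confidence interval for the mean (1.96 standard errors) in both
#' the FPR and TPR dimensions. Used to show that FDR assignments are
#' stable when the same-vs-same reference sets are exchanged.
#'
#' @param fdrSets list (>= 2) of numeric FDR vectors, one per member, e.g.
#'   one per reference-set combination.
#' @param nPositions number of uniform evaluation positions.
#' @return a \linkS4class{MeanROC}.
#' @export
meanRoc <- function(fdrSets, nPositions = 100L) {
    if (!is.list(fdrSets) || length(fdrSets) < 2L)
        stop("'fdrSets' must be a list of at least 2 FDR vectors")
    pts <- lapply(fdrSets, .estimatedRocPoints)
    pos <- seq(0, 1, length.out = as.integer(nPositions))
    interp <- function(p, what)
        stats::approx(p$t, p[[what]], xout = pos, ties = "ordered",
                      rule = 2)$y
    fprM <- vapply(pts, interp, numeric(length(pos)), what = "fpr")
    tprM <- vapply(pts, interp, numeric(length(pos)), what = "tpr")
    k <- length(fdrSets)
    sem <- function(m) apply(m, 1L, stats::sd) / sqrt(k)
    new("MeanROC", positions = pos,
        meanFpr = rowMeans(fprM), meanTpr = rowMeans(tprM),
        hwFpr = 1.96 * sem(fprM), hwTpr = 1.96 * sem(tprM),
        nMembers = as.integer(k))
}

setMethod("show", "MeanROC", function(object) {
    cat("MeanROC over", object@nMembers, "member curves at",
        length(object@positions), "positions\n")
    cat("  mean AUC of mean curve:",
        format(aucTrapezoid(object@meanFpr, object@meanTpr), digits = 4),
        "\n")
})

#' @describeIn meanRoc the mean curve and band as a data.frame.
#' @param x a \code{MeanROC}.
#' @export
meanRocTable <- function(x) {
    stopifnot(is(x, "MeanROC"))
    data.frame(position = x@positions, fpr = x@meanFpr, tpr = x@meanTpr,
               fprLo = pmax(0, x@meanFpr - x@hwFpr),
               fprHi = pmin(1, x@meanFpr + x@hwFpr),
               tprLo = pmax(0, x@meanTpr - x@hwTpr),
               tprHi = pmin(1, x@meanTpr + x@hwTpr))
}

#' Sensitivity/specificity sweep over FDR thresholds
#'
#' Classifies each mutation as positive iff its FDR is at or below a
#' threshold, for thresholds from 0 to 1 in steps of \code{step}
#' (21 rows at the default), and tabulates sensitivity and specificity
#' against validation labels. Inconclusive labels are excluded. Supports
#' choosing an operating FDR cutoff for use as a binary classifier.
#'
#' @param fdr numeric vector of per-mutation FDRs.
#' @param label parallel labels (\code{"positive"}/\code{"negative"}/
#'   \code{"inconclusive"}).
#' @param step threshold step size in (0, 1].
#' @return data.frame with columns \code{threshold}, \code{sensitivity},
#'   \code{specificity}, \code{tp}, \code{fp}, \code{tn}, \code{fn}.
#' @export
thresholdSweep <- function(fdr, label, step = 0.05) {
    stopifnot(length(fdr) == length(label), step > 0, step <= 1)
    keep <- label %in% c("positive", "negative")
    fdr <- as.numeric(fdr[keep]); isPos <- label[keep] == "positive"
    # round away float drift so an FDR of exactly t is classified positive
    thr <- round(seq(0, 1, by = step), 12)
    rows <- lapply(thr, function(t) {
        pred <- fdr <= t
        tp <- sum(pred & isPos); fp <- sum(pred & !isPos)
        fn <- sum(!pred & isPos); tn <- sum(!pred & !isPos)
        data.frame(threshold = t,
                   sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                   specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                   tp = tp, fp = fp, tn = tn, fn = fn)
    })
    do.call(rbind, rows)
}

#' Resampled AUC over balanced validation draws
#'
#' Guards the labeled AUC against imbalanced validation-set sizes: per
#' repetition, draws \code{nPerGroup} mutations without replacement from
#' the high-confidence group and from the low-confidence group, adds all
#' intermediate-confidence mutations, computes the labeled ROC AUC, and
#' repeats. Reports the mean and standard deviation over repetitions;
#' deterministic given the seed.
#'
#' @param highConf,lowConf,intermediate data.frames with columns \code{fdr}
#'   and \code{label}; \code{intermediate} may be empty.
#' @param nPerGroup draws per extreme group per repetition.
#' @param reps number of repetitions.
#' @param seed integer seed.
#' @return list with \code{meanAuc}, \code{sd}, and the vector \code{aucs}.
#' @export
resampledAuc <- function(highConf, lowConf, intermediate =
                             data.frame(fdr = numeric(), label = character()),
                         nPerGroup = 10L, reps = 1000L, seed = 1L) {
    for (g in list(highConf, lowConf))
        if (nrow(g) < nPerGroup)
            stop("group smaller than nPerGroup (", nPerGroup, ")")
    set.seed(seed)
    aucs <- vapply(seq_len(reps), function(i) {
        sub <- rbind(
            highConf[sample.int(nrow(highConf), nPerGroup), , drop = FALSE],
            lowConf[sample.int(nrow(lowConf), nPerGroup), , drop = FALSE],
            intermediate)
        auc(rocFromLabels(sub$fdr, sub$label))
    }, numeric(1))
    list(meanAuc = mean(aucs), sd = stats::sd(aucs), aucs = aucs)
}

#' Plot an ROC curve or a mean curve with its confidence band
#'
#' @param x an \linkS4class{ROCCurve} or \linkS4class{MeanROC}.
#' @param add overlay on an existing plot.
#' @param col curve color.
#' @param ... further arguments to \code{plot}.
#' @return invisibly, \code{x}.
#' @export
plotRoc <- function(x, add = FALSE, col = "steelblue4", ...) {
    if (is(x, "ROCCurve")) {
        fpr <- x@fpr; tpr <- x@tpr
    } else if (is(x, "MeanROC")) {
        fpr <- x@meanFpr; tpr <- x@meanTpr
    } else stop("'x' must be an ROCCurve or MeanROC")
    if (!add) {
        graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                       xlab = "False positive rate",
                       ylab = "True positive rate", ...)
        graphics::abline(0, 1, col = "grey70", lty = 2)
    }
    if (is(x, "MeanROC")) {
        graphics::segments(x@meanFpr - x@hwFpr, x@meanTpr,
                           x@meanFpr + x@hwFpr, x@meanTpr, col = "grey60")
        graphics::segments(x@meanFpr, x@meanTpr - x@hwTpr,
                           x@meanFpr, x@meanTpr + x@hwTpr, col = "grey60")
    }
    graphics::lines(fpr, tpr, col = col, lwd = 2)
    invisible(x)
}
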