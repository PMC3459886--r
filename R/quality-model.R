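#' Dominance ordering of quality vectors
#'
#' A quality vector S is superior to T if and only if every component of S
#' strictly exceeds the corresponding component of T; many pairs are
#' incomparable under this ordering, which is why the intermediate FDR is
#' generalized by regression afterwards.
#'
#' @param s,t numeric quality vectors of equal arity (same property order).
#' @return logical: does \code{s} strictly dominate \code{t}?
#' @examples
#' dominates(c(30, 10), c(20, 5))   # TRUE
#' dominates(c(30, 5), c(20, 10))   # FALSE (incomparable)
#' @export
dominates <- function(s, t) {
    s <- as.numeric(s); t <- as.numeric(t)
    if (length(s) != length(t))
        stop("quality vectors have different arity: ", length(s), " vs ",
             length(t))
    all(s > t)
}

# logical vector: which rows of matrix `pool` are componentwise >= `point`
.rowsAtOrAbove <- function(pool, point) {
    if (ncol(pool) != length(point))
        stop("arity mismatch: pool has ", ncol(pool), " properties, point ",
             length(point))
    ok <- rep(TRUE, nrow(pool))
    for (j in seq_along(point)) ok <- ok & (pool[, j] >= point[j])
    ok
}

#' Count pool members at-or-above a quality point
#'
#' Counts the quality vectors in \code{pool} whose every component is
#' greater than or equal to the corresponding component of \code{point}
#' ("a score of Q or better" in dominance space). A point always counts
#' itself.
#'
#' @param point numeric quality vector.
#' @param pool matrix/data.frame of quality vectors (one row each), or a
#'   \linkS4class{CallSet}.
#' @return integer count.
#' @examples
#' countAtOrAbove(c(10, 10), rbind(c(30, 30), c(10, 10)))  # 2
#' @export
countAtOrAbove <- function(point, pool) {
    pool <- .asQualityMatrix(pool)
    sum(.rowsAtOrAbove(pool, as.numeric(point)))
}

#' Intermediate FDR of a quality point
#'
#' The dominance-order false discovery rate of a point in quality space:
#' the coverage-normalized ratio of same-vs-same calls at-or-above the
#' point to tumor-comparison calls at-or-above it,
#' \deqn{IFDR(S) = \frac{\#\{T \in ss : T \ge S\} / C_{ss}}
#'                     {\#\{T \in tn : T \ge S\} / C_{tn}}}
#' clamped to [0, 1]. When no tumor call is at-or-above the point the ratio
#' is taken as 0 if the same-vs-same count is also 0, else 1.
#'
#' @param point numeric quality vector.
#' @param ssPool,tnPool quality-vector pools (matrix, data.frame or
#'   \linkS4class{CallSet}) of the same-vs-same and tumor comparisons.
#' @param cSS,cTN \linkS4class{CommonCoverage} (or bare base counts) of the
#'   two comparisons; must be positive.
#' @return IFDR in [0, 1].
#' @examples
#' ss <- rbind(c(10, 10)); tn <- rbind(c(30, 30), c(10, 10))
#' ifdr(c(30, 30), ss, tn, 1e6, 1e6)  # 0
#' ifdr(c(10, 10), ss, tn, 1e6, 1e6)  # 0.5
#' @export
ifdr <- function(point, ssPool, tnPool, cSS, cTN) {
    cSS <- .baseCount(cSS, "cSS"); cTN <- .baseCount(cTN, "cTN")
    nSS <- countAtOrAbove(point, ssPool)
    nTN <- countAtOrAbove(point, tnPool)
    .ifdrRatio(nSS, nTN, cSS, cTN)
}

.ifdrRatio <- function(nSS, nTN, cSS, cTN) {
    out <- numeric(length(nSS))
    zero <- nTN == 0
    out[zero] <- ifelse(nSS[zero] == 0, 0, 1)
    out[!zero] <- .clamp01((nSS[!zero] / cSS) / (nTN[!zero] / cTN))
    out
}

# IFDR for each row of `points` against full pools
.ifdrBatch <- function(points, ssPool, tnPool, cSS, cTN) {
    nSS <- integer(nrow(points)); nTN <- integer(nrow(points))
    for (i in seq_len(nrow(points))) {
        nSS[i] <- sum(.rowsAtOrAbove(ssPool, points[i, ]))
        nTN[i] <- sum(.rowsAtOrAbove(tnPool, points[i, ]))
    }
    .ifdrRatio(nSS, nTN, cSS, cTN)
}

#' Sample a uniform grid over the observed quality space
#'
#' For each quality property, takes the value range observed in the pool
#' and emits up to \code{p} uniformly spaced values covering it (both ends
#' inclusive); when a property has fewer than \code{p} distinct observed
#' values, that set is used instead. Returns the full Cartesian product, at
#' most \eqn{p^n} points.
#'
#' @param pool quality-vector pool (matrix, data.frame or CallSet).
#' @param p per-property grid size (>= 2).
#' @return numeric matrix of grid points, one column per property.
#' @examples
#' g <- sampleQualityGrid(cbind(a = c(0, 100), b = c(0, 1)), p = 20)
#' dim(g)  # both properties have 2 distinct values -> 4 grid points
#' @export
sampleQualityGrid <- function(pool, p) {
    pool <- .asQualityMatrix(pool)
    p <- as.integer(p)
    if (p < 2L) stop("'p' must be >= 2")
    if (!nrow(pool)) stop("cannot build a quality grid from an empty pool")
    axes <- lapply(seq_len(ncol(pool)), function(j) {
        uniq <- sort(unique(pool[, j]))
        if (length(uniq) < p) uniq
        else seq(min(uniq), max(uniq), length.out = p)
    })
    names(axes) <- colnames(pool)
    total <- prod(vapply(axes, length, numeric(1)))
    if (total > 1e7)
        stop("quality grid would have ", format(total, big.mark = ","),
             " points; reduce 'p' or the number of properties")
    g <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
    storage.mode(g) <- "double"
    g
}

#' Train the generalized quality-score model
#'
#' Discretizes the tumor-comparison quality space on a uniform grid
#' (\code{\link{sampleQualityGrid}} with the configured \code{p}), draws a
#' random subset of grid points, computes each point's intermediate FDR
#' against the full same-vs-same and tumor pools, and fits a random-forest
#' regression from quality vector to IFDR. The model's generalized quality
#' score is \code{Q = 1 - predicted IFDR}: a single value in [0, 1], higher
#' meaning higher confidence, that totally orders mutations whose raw
#' quality vectors are incomparable.
#'
#' The subset size is \code{max(round(sampleFraction * gridSize), 1000)},
#' capped at the grid size; the floor keeps small grids from under-training
#' while leaving the nominal 1\% fraction in charge on large grids.
#'
#' @param ssPool,tnPool quality pools (matrix, data.frame or CallSet) of
#'   the same-vs-same and tumor comparisons.
#' @param cSS,cTN \linkS4class{CommonCoverage} (or base counts) of the two
#'   comparisons.
#' @param config \linkS4class{CallerConfig} (fixes property order and p).
#' @param sampleFraction fraction of grid points used for training.
#' @param seed integer seed; training is reproducible given the seed.
#' @param ntree number of regression trees.
#' @return a \linkS4class{QualityModel}.
#' @seealso \code{\link{scoreQuality}}, \code{\link{buildFdrFunction}}
#' @export
trainQualityModel <- function(ssPool, tnPool, cSS, cTN, config,
                              sampleFraction = 0.01, seed = 1L,
                              ntree = 500L) {
    stopifnot(is(config, "CallerConfig"))
    if (sampleFraction <= 0 || sampleFraction > 1)
        stop("'sampleFraction' must be in (0, 1]")
    props <- config@properties
    ssM <- .asQualityMatrix(ssPool, props)
    tnM <- .asQualityMatrix(tnPool, props)
    if (!nrow(tnM)) stop("tumor-comparison pool is empty")
    cSS <- .baseCount(cSS, "cSS"); cTN <- .baseCount(cTN, "cTN")

    grid <- sampleQualityGrid(tnM, config@p)
    gridSize <- nrow(grid)
    nTrain <- min(gridSize, max(round(sampleFraction * gridSize), 1000L))

    set.seed(seed)
    idx <- sample.int(gridSize, nTrain)  # without replacement
    train <- grid[idx, , drop = FALSE]
    y <- .ifdrBatch(train, ssM, tnM, cSS, cTN)
    forest <- randomForest::randomForest(x = train, y = y,
                                         ntree = as.integer(ntree))
    new("QualityModel", caller = config@caller, properties = props,
        forest = forest,
        meta = list(p = config@p, gridSize = gridSize,
                    sampleFraction = sampleFraction, nTrain = nTrain,
                    ntree = as.integer(ntree), seed = as.integer(seed),
                    trainX = train, trainY = y))
}

#' @describeIn trainQualityModel predict the generalized quality score
#'   \code{Q = 1 - predicted IFDR} (clamped to [0, 1]) for quality vectors.
#' @export
setMethod("scoreQuality", "QualityModel", function(model, v) {
    m <- .asQualityMatrix(v, model@properties)
    pred <- stats::predict(model@forest, newdata = m)
    unname(1 - .clamp01(pred))
})

setMethod("show", "QualityModel", function(object) {
    cat("QualityModel for '", object@caller, "' (",
        length(object@properties), " properties)\n", sep = "")
    cat("  grid:", object@meta$gridSize, "points (p =", object@meta$p,
        "), trained on", object@meta$nTrain, "\n")
    cat("  forest:", object@meta$ntree, "trees | seed", object@meta$seed, "\n")
})

#' Persist and restore a trained model
#'
#' Saves a \linkS4class{QualityModel} (optionally together with its
#' \linkS4class{FDRFunction}) to a single self-describing file, so the
#' same-vs-same reference work needs to be done only once per platform and
#' caller.
#'
#' @param model a \linkS4class{QualityModel}.
#' @param path file to write/read.
#' @param fdrFunction optional \linkS4class{FDRFunction} stored alongside.
#' @return \code{saveQualityModel}: the path, invisibly.
#'   \code{loadQualityModel}: a list with elements \code{model} and
#'   \code{fdrFunction} (NULL if absent).
#' @export
saveQualityModel <- function(model, path, fdrFunction = NULL) {
    stopifnot(is(model, "QualityModel"))
    obj <- list(format = "somaticFDR-model", version = 1L,
                package = as.character(utils::packageVersion("somaticFDR")),
                model = model, fdrFunction = fdrFunction)
    saveRDS(obj, path)
    invisible(path)
}

#' @rdname saveQualityModel
#' @export
loadQualityModel <- function(path) {
    obj <- readRDS(path)
    if (!is.list(obj) || !identical(obj$format, "somaticFDR-model"))
        stop("'", path, "' is not a somaticFDR model container")
    list(model = obj$model, fdrFunction = obj$fdrFunction)
}
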