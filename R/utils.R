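# shared internal helpers

.clamp01 <- function(x) pmin(1, pmax(0, x))

# number of elements of `sorted` (ascending) that are >= each q
.countGE <- function(q, sorted) {
    length(sorted) - findInterval(q, sorted, left.open = TRUE)
}

# canonical (chrom, pos, alt) key used for consensus and labels
.callKeys <- function(callset) {
    gr <- callset@ranges
    paste(as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr), S4Vectors::mcols(gr)$alt, sep = ":")
}

.stamp <- function(fmt, ...) sprintf(fmt, ...)

# append a provenance line to a CallSet
.logStep <- function(callset, fmt, ...) {
    callset@provenance <- c(callset@provenance, sprintf(fmt, ...))
    callset
}

# accept a CommonCoverage or a bare positive count
.baseCount <- function(x, what = "coverage") {
    if (is(x, "CommonCoverage")) x <- x@bases
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
        stop(sprintf("'%s' must be a CommonCoverage or a single number", what))
    if (x <= 0)
        stop(sprintf("'%s' must be positive (zero common coverage is not evaluable)",
                     what))
    as.numeric(x)
}

# quality vectors as a numeric matrix (rows = calls, cols = properties)
.asQualityMatrix <- function(pool, properties = NULL) {
    if (is.matrix(pool)) {
        m <- pool
    } else if (is.data.frame(pool) || is(pool, "DataFrame")) {
        m <- as.matrix(as.data.frame(pool))
    } else if (is.numeric(pool)) {
        m <- matrix(pool, nrow = 1L, dimnames = list(NULL, names(pool)))
    } else if (is(pool, "CallSet")) {
        return(qualityMatrix(pool))
    } else if (is.list(pool)) {
        m <- do.call(rbind, pool)
    } else {
        stop("cannot interpret quality pool of class ", class(pool)[1L])
    }
    storage.mode(m) <- "double"
    if (!is.null(properties)) {
        if (is.null(colnames(m))) {
            if (ncol(m) != length(properties))
                stop("quality matrix has ", ncol(m), " columns; expected ",
                     length(properties))
            colnames(m) <- properties
        } else {
            miss <- setdiff(properties, colnames(m))
            if (length(miss))
                stop("quality matrix lacks properties: ",
                     paste(miss, collapse = ", "))
            m <- m[, properties, drop = FALSE]
        }
    }
    if (any(!is.finite(m))) stop("quality values must be finite")
    m
}
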