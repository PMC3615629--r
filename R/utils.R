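`%||%` <- function(a, b) if (is.null(a)) b else a

# population SD (divide by n), the convention used for discretization
popSd <- function(v) sqrt(mean((v - mean(v))^2))

# row-wise standardization; constant rows become all-zero
rowStandardize <- function(m) {
    mu <- rowMeans(m)
    s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
    z <- (m - mu) / ifelse(s > 0, s, 1)
    z[s == 0, ] <- 0
    z
}

# centered rows plus their sums of squares, for vectorized correlations
centerRows <- function(m) {
    cm <- m - rowMeans(m)
    list(c = cm, ss = rowSums(cm^2))
}

PATH_ARROW <- "\u2192"

arrowJoin <- function(nodes) paste(nodes, collapse = PATH_ARROW)

arrowSplit <- function(s) strsplit(s, PATH_ARROW, fixed = TRUE)

# derive a bounded secondary seed from a primary one
deriveSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}
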