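#' Rank transition hubs by path crossings
#'
#' Counts, for every gene, the number of signal propagation paths whose
#' interior contains it (each path counts a gene at most once; endpoints
#' — the biomarkers themselves — are not transition genes unless
#' \code{includeEndpoints} is set). Genes are ranked by crossing count,
#' ties broken alphabetically.
#'
#' @param paths a path table from \code{\link{screenTransitions}} or
#'   \code{\link{readPathTable}}.
#' @param includeEndpoints also count path endpoints (sensitivity
#'   analysis; off by default).
#' @return A data frame with columns \code{gene} and \code{nPaths},
#'   sorted by decreasing count; only genes crossed at least once appear.
#' @export
countCrossings <- function(paths, includeEndpoints = FALSE) {
    nodes <- arrowSplit(paths$path)
    per <- lapply(nodes, function(nn) {
        if (!includeEndpoints)
            nn <- if (length(nn) <= 2L) character(0) else nn[-c(1L, length(nn))]
        unique(nn)
    })
    tab <- table(unlist(per))
    if (!length(tab))
        return(data.frame(gene = character(0), nPaths = integer(0),
                          stringsAsFactors = FALSE))
    gene <- names(tab)
    cnt <- as.integer(tab)
    ord <- order(-cnt, gene)
    data.frame(gene = gene[ord], nPaths = cnt[ord],
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Overlap statistics of two gene sets
#'
#' Expected overlap under independent draws from a common universe,
#' \code{|set1| * |set2| / nUniverse} (the hypergeometric mean), and the
#' classical 2x2 cross-product odds ratio with cells a = overlap,
#' b = set1-only, c = set2-only, d = the remainder of the universe.
#' Disjoint sets give an odds ratio of 0; identical sets (b or c empty)
#' leave it undefined (\code{NA}).
#'
#' @param set1,set2 character vectors of gene identifiers, both subsets of
#'   the universe.
#' @param nUniverse size of the gene universe.
#' @return A list of class \code{OverlapStats}: \code{nUniverse},
#'   \code{nSet1}, \code{nSet2}, \code{nOverlap}, \code{expectedOverlap},
#'   \code{oddsRatio}.
#' @examples
#' # 158 early vs 284 late biomarkers, 1 shared gene, 19,621-gene universe
#' overlapStatistics(paste0("e", 1:158),
#'                   c("e1", paste0("l", 1:283)), 19621)
#' @export
overlapStatistics <- function(set1, set2, nUniverse) {
    set1 <- unique(set1)
    set2 <- unique(set2)
    n1 <- length(set1)
    n2 <- length(set2)
    if (nUniverse < length(union(set1, set2)))
        stop("universe smaller than the union of the two sets")
    a <- length(intersect(set1, set2))
    b <- n1 - a
    cc <- n2 - a
    d <- nUniverse - n1 - n2 + a
    out <- list(nUniverse = nUniverse, nSet1 = n1, nSet2 = n2, nOverlap = a,
                expectedOverlap = n1 * n2 / nUniverse,
                oddsRatio = if (b * cc == 0) NA_real_ else (a * d) / (b * cc))
    class(out) <- "OverlapStats"
    out
}

#' @export
print.OverlapStats <- function(x, ...) {
    cat("Overlap of", x$nSet1, "and", x$nSet2, "genes in a universe of",
        x$nUniverse, "\n")
    cat("  observed overlap:", x$nOverlap, "\n")
    cat("  expected overlap:", signif(x$expectedOverlap, 3), "\n")
    cat("  odds ratio:      ",
        if (is.na(x$oddsRatio)) "undefined" else signif(x$oddsRatio, 3), "\n")
    invisible(x)
}
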