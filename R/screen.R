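#' Map biomarkers onto the network
#'
#' Subsets a gene list to those present as network nodes, preserving
#' order; the number left unmapped is reported with a message.
#'
#' @param genes character vector of gene symbols.
#' @param network a \linkS4class{PPINetwork}.
#' @return The mapped subset of \code{genes}.
#' @export
mapBiomarkers <- function(genes, network) {
    mapped <- genes[genes %in% nodeNames(network)]
    nLost <- length(genes) - length(mapped)
    if (nLost > 0)
        message(nLost, " of ", length(genes),
                " biomarker(s) could not be mapped onto the network")
    if (!length(mapped))
        warning("no biomarkers could be mapped onto the network")
    mapped
}

#' Pearson correlation test
#'
#' Sample Pearson correlation with a two-sided p-value from the
#' t-distribution with n - 2 degrees of freedom (via
#' \code{stats::cor.test}). Constant input yields \code{NA} with a
#' warning; such pairs are excluded from screening.
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @return A list with \code{r} and \code{p}.
#' @export
pearsonTest <- function(x, y) {
    if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
    if (length(x) < 3L) stop("need at least 3 paired observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("constant vector: correlation undefined")
        return(list(r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value)
}

#' Two-sided Pearson p-value from r and n
#'
#' The p-value of the Pearson correlation test as a closed form of the
#' sample correlation and sample size: \code{t = r * sqrt((n - 2) /
#' (1 - r^2))} referred to the t-distribution with n - 2 df. Used by the
#' vectorized screening stage; identical to \code{stats::cor.test}.
#'
#' @param r sample Pearson correlation(s).
#' @param n sample size(s), n >= 3.
#' @return Two-sided p-value(s).
#' @examples
#' pearsonPFromR(0.317, 185)
#' @export
pearsonPFromR <- function(r, n) {
    r <- pmin(1, pmax(-1, r))
    tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.xmin))
    2 * stats::pt(-tstat, df = n - 2)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (monotone, capped at 1), via
#' \code{stats::p.adjust}.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Adjusted values, same length and order as \code{p}.
#' @export
bhAdjust <- function(p) {
    if (!length(p)) return(numeric(0))
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Screen early-late biomarker pairs for signal propagation paths
#'
#' Forms all ordered early x late pairs (a gene appearing in both sets is
#' never paired with itself), computes each pair's intimacy-weighted
#' shortest-path length and the Pearson correlation of the two genes over
#' the pooled Dukes B and C samples, applies one Benjamini-Hochberg
#' adjustment across all tested pairs, and retains the pairs satisfying
#' both strict criteria: path length below \code{lengthCutoff} and
#' correlation FDR below \code{fdrCutoff}. For every retained pair the
#' deterministic shortest path is reconstructed; its interior nodes are
#' the transition genes.
#'
#' @param network a \linkS4class{PPINetwork}.
#' @param earlyMapped,lateMapped mapped biomarker symbols (see
#'   \code{\link{mapBiomarkers}}).
#' @param cohort a \linkS4class{StageCohort} containing stage B and C
#'   samples.
#' @param lengthCutoff strict upper bound on path length (default 300,
#'   the intimacy weight of a 0.700-confidence edge).
#' @param fdrCutoff strict upper bound on correlation FDR (default 0.001).
#' @param corStages stages pooled for the correlation test (default B, C).
#' @return An \code{S4Vectors::DataFrame} with one row per retained path
#'   (columns \code{early}, \code{late}, \code{path}, \code{length},
#'   \code{r}, \code{p}, \code{fdr}, \code{permFdr} = NA). Its
#'   \code{metadata()} records the tested family (\code{earlyMapped},
#'   \code{lateMapped}, \code{corStages}, cutoffs) and a \code{summary}
#'   list (pairs tested, pairs excluded as constant, paths retained,
#'   distinct early/late genes linked).
#' @export
screenTransitions <- function(network, earlyMapped, lateMapped, cohort,
                              lengthCutoff = 300, fdrCutoff = 0.001,
                              corStages = c("B", "C")) {
    if (lengthCutoff < 0 || fdrCutoff < 0)
        stop("cutoffs must be non-negative")
    stage <- stageOf(cohort)
    for (s in corStages)
        if (!any(stage == s))
            stop("cohort has no stage-", s, " samples; correlation test impossible")
    if (!length(earlyMapped) || !length(lateMapped))
        return(emptyPathTable(earlyMapped, lateMapped, corStages,
                              lengthCutoff, fdrCutoff))
    stopifnot(all(earlyMapped %in% nodeNames(network)),
              all(lateMapped %in% nodeNames(network)),
              all(earlyMapped %in% rownames(cohort)),
              all(lateMapped %in% rownames(cohort)))

    grid <- expand.grid(e = seq_along(earlyMapped),
                        l = seq_along(lateMapped), KEEP.OUT.ATTRS = FALSE)
    eg <- earlyMapped[grid$e]
    lg <- lateMapped[grid$l]
    keep <- eg != lg  # no self-paths for genes in both biomarker sets
    eg <- eg[keep]; lg <- lg[keep]

    dmat <- pairDistances(network, earlyMapped, lateMapped)
    plen <- dmat[cbind(match(eg, earlyMapped), match(lg, lateMapped))]

    cols <- stage %in% corStages
    n <- sum(cols)
    if (n < 3L) stop("need at least 3 pooled samples for the correlation test")
    cz <- centerRows(exprValues(cohort)[, cols, drop = FALSE])
    ssE <- cz$ss[eg]; ssL <- cz$ss[lg]
    valid <- ssE > 0 & ssL > 0
    r <- rep(NA_real_, length(eg))
    denom <- sqrt(ssE[valid] * ssL[valid])
    r[valid] <- rowSums(cz$c[eg[valid], , drop = FALSE] *
                        cz$c[lg[valid], , drop = FALSE]) / denom
    p <- rep(NA_real_, length(eg))
    p[valid] <- pearsonPFromR(r[valid], n)
    nConstant <- sum(!valid)
    if (nConstant > 0)
        message(nConstant, " pair(s) excluded: constant expression in the ",
                paste(corStages, collapse = "/"), " samples")
    fdr <- rep(NA_real_, length(eg))
    fdr[valid] <- bhAdjust(pmax(p[valid], .Machine$double.xmin))

    retain <- which(valid & is.finite(plen) & plen < lengthCutoff &
                    fdr < fdrCutoff)
    pathStr <- character(length(retain))
    for (i in seq_along(retain)) {
        sp <- shortestPath(network, eg[retain[i]], lg[retain[i]])
        pathStr[i] <- arrowJoin(sp$nodes)
    }
    out <- S4Vectors::DataFrame(
        early = eg[retain], late = lg[retain], path = pathStr,
        length = plen[retain], r = r[retain], p = p[retain],
        fdr = fdr[retain], permFdr = rep(NA_real_, length(retain)))
    S4Vectors::metadata(out) <- list(
        earlyMapped = earlyMapped, lateMapped = lateMapped,
        corStages = corStages, lengthCutoff = lengthCutoff,
        fdrCutoff = fdrCutoff,
        summary = list(nPairsTested = length(eg),
                       nPairsExcludedConstant = nConstant,
                       nPathsRetained = length(retain),
                       nEarlyLinked = length(unique(eg[retain])),
                       nLateLinked = length(unique(lg[retain]))))
    out
}

emptyPathTable <- function(earlyMapped, lateMapped, corStages,
                           lengthCutoff, fdrCutoff) {
    out <- S4Vectors::DataFrame(
        early = character(0), late = character(0), path = character(0),
        length = numeric(0), r = numeric(0), p = numeric(0),
        fdr = numeric(0), permFdr = numeric(0))
    S4Vectors::metadata(out) <- list(
        earlyMapped = earlyMapped, lateMapped = lateMapped,
        corStages = corStages, lengthCutoff = lengthCutoff,
        fdrCutoff = fdrCutoff,
        summary = list(nPairsTested = 0L, nPairsExcludedConstant = 0L,
                       nPathsRetained = 0L, nEarlyLinked = 0L,
                       nLateLinked = 0L))
    out
}

#' Interior (transition) genes of a path table
#'
#' @param paths a path table from \code{\link{screenTransitions}}.
#' @return A list, one character vector of interior nodes per path.
#' @export
transitionGenes <- function(paths) {
    lapply(arrowSplit(paths$path), function(nn)
        if (length(nn) <= 2L) character(0) else nn[-c(1L, length(nn))])
}
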