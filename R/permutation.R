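#' Jointly permute gene symbols of a network and a cohort
#'
#' Draws one random bijection over the union of network node names and
#' cohort gene identifiers and applies it simultaneously to both, so the
#' relabeled network and cohort stay mutually consistent while every
#' symbol's structural position (graph neighbourhood, expression row) is
#' randomized. Topology, edge scores and expression values are untouched,
#' so relabeling invariants hold: the degree sequence and the multiset of
#' pairwise expression correlations are unchanged. With
#' \code{independentRelabeling = TRUE} two independent bijections are
#' drawn instead.
#'
#' @param network a \linkS4class{PPINetwork}.
#' @param cohort a \linkS4class{StageCohort} sharing the symbol namespace.
#' @param seed integer seed; identical seeds give identical permutations.
#' @param independentRelabeling use separate bijections for network and
#'   cohort.
#' @return A list with relabeled \code{network} and \code{cohort}, plus
#'   \code{mapping} (named character: original symbol -> new label; in
#'   independent mode a two-column matrix-like list with \code{network}
#'   and \code{cohort} mappings).
#' @export
permuteInstance <- function(network, cohort, seed,
                            independentRelabeling = FALSE) {
    set.seed(seed)
    syms <- union(nodeNames(network), rownames(cohort))
    permG <- stats::setNames(sample(syms), syms)
    permC <- if (independentRelabeling)
        stats::setNames(sample(syms), syms) else permG
    g <- ppiGraph(network)
    g <- igraph::set_vertex_attr(g, "name",
                                 value = unname(permG[igraph::V(g)$name]))
    m <- exprValues(cohort)
    rownames(m) <- unname(permC[rownames(m)])
    list(network = new("PPINetwork", graph = g),
         cohort = StageCohort(m, as.character(stageOf(cohort))),
         mapping = if (independentRelabeling)
             list(network = permG, cohort = permC) else permG)
}

#' Permutation FDR of signal propagation paths
#'
#' Assigns every retained path a permutation-based false discovery rate:
#' gene symbols are randomly relabeled (jointly across network and
#' cohort, see \code{\link{permuteInstance}}) \code{nPermutations} times;
#' in each permutation the path's early-late symbol pair gets a new
#' shortest-path length and a new Benjamini-Hochberg correlation FDR,
#' the latter recomputed over the same early x late pair family as the
#' actual screen so the values are comparable. The path's FDR is
#' \code{N1 / N2}, where \code{N1} counts permutations in which the
#' permuted length and the permuted correlation FDR are both strictly
#' smaller than the actual values, and \code{N2 = nPermutations}. A pair
#' unreachable in a permuted graph (or with a symbol relabeled outside
#' the cohort) cannot beat the actual path.
#'
#' @param paths a path table from \code{\link{screenTransitions}} (its
#'   metadata supplies the tested pair family).
#' @param network,cohort the objects the screen was run on.
#' @param nPermutations number of permutations N2 (default 20,000;
#'   validation tests use far fewer).
#' @param seed integer seed governing the whole permutation stream.
#' @param independentRelabeling draw separate bijections for network and
#'   cohort instead of one joint bijection.
#' @return \code{paths} with the \code{permFdr} column filled; metadata
#'   gains \code{nPermutations} and \code{permSeed}.
#' @export
pathFdr <- function(paths, network, cohort, nPermutations = 20000,
                    seed = 1, independentRelabeling = FALSE) {
    stopifnot(nPermutations >= 1)
    md <- S4Vectors::metadata(paths)
    if (nrow(paths) == 0L) {
        md$nPermutations <- as.integer(nPermutations)
        md$permSeed <- as.integer(seed)
        S4Vectors::metadata(paths) <- md
        return(paths)
    }
    eFam <- md$earlyMapped
    lFam <- md$lateMapped
    corStages <- md$corStages %||% c("B", "C")

    g <- ppiGraph(network)
    gNodes <- igraph::V(g)$name
    w <- igraph::E(g)$intimacy
    genes <- rownames(cohort)
    syms <- union(gNodes, genes)

    cols <- stageOf(cohort) %in% corStages
    n <- sum(cols)
    cz <- centerRows(exprValues(cohort)[, cols, drop = FALSE])

    grid <- expand.grid(e = seq_along(eFam), l = seq_along(lFam),
                        KEEP.OUT.ATTRS = FALSE)
    famE <- eFam[grid$e]
    famL <- lFam[grid$l]
    keep <- famE != famL
    famE <- famE[keep]; famL <- famL[keep]
    pathPos <- match(paste(paths$early, paths$late, sep = "\r"),
                     paste(famE, famL, sep = "\r"))

    actualLen <- paths$length
    actualFdr <- paths$fdr
    n1 <- integer(nrow(paths))

    set.seed(seed)
    for (b in seq_len(nPermutations)) {
        permG <- sample(syms)
        permC <- if (independentRelabeling) sample(syms) else permG
        invG <- stats::setNames(syms, permG)  # new label -> original symbol
        invC <- if (independentRelabeling)
            stats::setNames(syms, permC) else invG

        # permuted shortest-path lengths for the retained pairs
        se <- unname(invG[paths$early])
        sl <- unname(invG[paths$late])
        ok <- se %in% gNodes & sl %in% gNodes
        plen <- rep(Inf, nrow(paths))
        if (any(ok)) {
            us <- unique(se[ok]); ut <- unique(sl[ok])
            dm <- igraph::distances(g, v = us, to = ut, weights = w)
            plen[ok] <- dm[cbind(match(se[ok], us), match(sl[ok], ut))]
        }

        # permuted correlation FDR over the full pair family
        ge <- unname(invC[famE])
        gl <- unname(invC[famL])
        okc <- ge %in% genes & gl %in% genes
        pfdr <- rep(NA_real_, length(famE))
        if (any(okc)) {
            ssE <- cz$ss[ge[okc]]; ssL <- cz$ss[gl[okc]]
            nz <- ssE > 0 & ssL > 0
            idx <- which(okc)[nz]
            if (length(idx)) {
                r <- rowSums(cz$c[ge[idx], , drop = FALSE] *
                             cz$c[gl[idx], , drop = FALSE]) /
                    sqrt(cz$ss[ge[idx]] * cz$ss[gl[idx]])
                p <- pmax(pearsonPFromR(r, n), .Machine$double.xmin)
                pfdr[idx] <- bhAdjust(p)
            }
        }
        pf <- pfdr[pathPos]
        n1 <- n1 + (plen < actualLen & !is.na(pf) & pf < actualFdr)
    }
    paths$permFdr <- n1 / nPermutations
    md$nPermutations <- as.integer(nPermutations)
    md$permSeed <- as.integer(seed)
    S4Vectors::metadata(paths) <- md
    paths
}
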