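# Fixtures and independent oracles used across the suite.

ARROW <- "\u2192"

# small random cohort built directly (independent of simulateCohort)
makeCohortFixture <- function(nGenes = 12, nPerStage = c(A = 4, B = 4, C = 4, D = 4),
                              seed = 1) {
    set.seed(seed)
    n <- sum(nPerStage)
    m <- matrix(rnorm(nGenes * n, 8, 1.5), nGenes, n,
                dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                                sprintf("s%02d", seq_len(n))))
    StageCohort(m, rep(names(nPerStage), nPerStage))
}

# triangle network: AB and BC strong (0.9 -> weight 100), AC weak (0.75 -> 250)
makeTriangleNet <- function() {
    buildGraph(data.frame(protein1 = c("A", "B", "A"),
                          protein2 = c("B", "C", "C"),
                          score = c(0.9, 0.9, 0.75)))
}

randomScoredGraph <- function(nNodes, p = 0.4, seed = 1) {
    set.seed(seed)
    pairs <- t(combn(nNodes, 2))
    keep <- runif(nrow(pairs)) < p
    pairs <- pairs[keep, , drop = FALSE]
    if (!nrow(pairs)) return(NULL)
    nm <- sprintf("N%02d", seq_len(nNodes))
    buildGraph(data.frame(protein1 = nm[pairs[, 1]],
                          protein2 = nm[pairs[, 2]],
                          score = runif(nrow(pairs), 0.15, 1)))
}

# oracle: minimum weighted length over ALL simple paths (exhaustive)
bruteForceLength <- function(net, from, to) {
    g <- ppiGraph(net)
    ap <- igraph::all_simple_paths(g, from = from, to = to)
    if (!length(ap)) return(Inf)
    w <- igraph::E(g)$intimacy
    min(vapply(ap, function(vp) {
        ids <- igraph::get_edge_ids(g, rbind(vp[-length(vp)], vp[-1]))
        sum(w[ids])
    }, numeric(1)))
}

# oracle: hand-applied Benjamini-Hochberg step-up
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    out <- numeric(m)
    out[o] <- adj
    out
}

# oracle: literal greedy mRMR using only the public mutualInformation()
mrmrOracle <- function(disc, labels, nTop, scheme) {
    genes <- rownames(disc)
    rel <- sapply(genes, function(g) mutualInformation(disc[g, ], labels))
    sel <- character(0)
    for (step in seq_len(nTop)) {
        cand <- setdiff(genes, sel)
        score <- sapply(cand, function(g) {
            if (!length(sel)) return(rel[g])
            red <- mean(sapply(sel, function(s)
                mutualInformation(disc[g, ], disc[s, ])))
            if (scheme == "MIQ") rel[g] / max(red, .Machine$double.eps)
            else rel[g] - red
        })
        # ties toward input gene order
        best <- cand[which(score == max(score))]
        sel <- c(sel, genes[genes %in% best][1])
    }
    sel
}

# two-sample t statistics per gene (Welch), oracle for planted-marker checks
tStatsByStage <- function(cohort, s0, s1) {
    st <- stageOf(cohort)
    x0 <- exprValues(cohort)[, st == s0, drop = FALSE]
    x1 <- exprValues(cohort)[, st == s1, drop = FALSE]
    n0 <- ncol(x0); n1 <- ncol(x1)
    (rowMeans(x1) - rowMeans(x0)) /
        sqrt(apply(x0, 1, var) / n0 + apply(x1, 1, var) / n1)
}

pairKey <- function(e, l) paste(e, l, sep = "|")

plantedPairKeys <- function(truth) {
    vapply(plantedPairs(truth), function(p) pairKey(p$early, p$late), "")
}
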