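#' Confidence rank of an interaction score
#'
#' Classifies STRING-style combined confidence scores into the four
#' conventional ranks, using strict lower bounds: scores above 0.900 are
#' \code{highest}, above 0.700 \code{high}, above 0.400 \code{medium}, and
#' the remainder down to the admissible minimum 0.150 are \code{low} (the
#' boundary 0.150 itself is classified low).
#'
#' @param score numeric vector of confidence scores in [0.150, 1].
#' @return An ordered factor with levels low < medium < high < highest.
#' @examples
#' classifyConfidence(c(0.15, 0.5, 0.700, 0.95))
#' @export
classifyConfidence <- function(score) {
    checkScoreRange(score)
    cut(score, breaks = c(0.150, 0.400, 0.700, 0.900, 1),
        labels = c("low", "medium", "high", "highest"),
        include.lowest = TRUE, right = TRUE, ordered_result = TRUE)
}

checkScoreRange <- function(score) {
    if (any(!is.finite(score)) || any(score < 0.150) || any(score > 1))
        stop("confidence scores must lie in [0.150, 1]")
    invisible(score)
}

#' Intimacy weight of an interaction
#'
#' The edge distance used for shortest paths: \code{1000 * (1 - score)}.
#' A score of 0.700 maps to 300 (the path-length screening threshold), a
#' perfect score of 1 to distance 0, and the minimum admissible score
#' 0.150 to 850.
#'
#' @param score numeric vector of confidence scores in [0.150, 1].
#' @return Numeric vector of distances in [0, 850].
#' @examples
#' intimacyWeight(0.700)  # 300
#' @export
intimacyWeight <- function(score) {
    checkScoreRange(score)
    1000 * (1 - score)
}

# drop self-loops, collapse duplicate undirected edges keeping the maximum
# score, and drop edges below the admissible score range (never clamp)
normalizeEdges <- function(edges, verbose = TRUE) {
    stopifnot(all(c("protein1", "protein2", "score") %in% colnames(edges)))
    edges$protein1 <- as.character(edges$protein1)
    edges$protein2 <- as.character(edges$protein2)
    loops <- edges$protein1 == edges$protein2
    if (any(loops)) {
        if (verbose) message("dropping ", sum(loops), " self-loop(s)")
        edges <- edges[!loops, , drop = FALSE]
    }
    low <- edges$score < 0.150
    if (any(low)) {
        if (verbose)
            message("dropping ", sum(low),
                    " edge(s) with score below the admissible 0.150")
        edges <- edges[!low, , drop = FALSE]
    }
    if (any(edges$score > 1))
        stop("confidence scores above 1 after normalization; check score_scale")
    a <- pmin(edges$protein1, edges$protein2)
    b <- pmax(edges$protein1, edges$protein2)
    key <- paste(a, b, sep = "\r")
    ord <- order(key, -edges$score)
    keep <- !duplicated(key[ord])
    out <- data.frame(protein1 = a[ord][keep], protein2 = b[ord][keep],
                      score = edges$score[ord][keep],
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Build a weighted protein interaction network
#'
#' Constructs an undirected simple graph from a confidence-scored edge
#' list, attaching both the raw score and the intimacy distance
#' \code{1000 * (1 - score)} to every edge. Self-loops are dropped and
#' duplicate undirected edges collapsed to their maximum score.
#'
#' @param edges data frame with columns \code{protein1}, \code{protein2},
#'   \code{score} (e.g. from \code{\link{readNetwork}}).
#' @param nodes optional character vector of node names; lets the graph
#'   carry proteins without any (admissible) interaction. Edge endpoints
#'   are always included.
#' @return A \linkS4class{PPINetwork}.
#' @examples
#' el <- data.frame(protein1 = c("A", "B"), protein2 = c("B", "C"),
#'                  score = c(0.9, 0.8))
#' buildGraph(el)
#' @export
buildGraph <- function(edges, nodes = NULL) {
    edges <- normalizeEdges(edges, verbose = FALSE)
    nodes <- unique(c(nodes, edges$protein1, edges$protein2))
    if (nrow(edges)) {
        g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                           vertices = nodes)
        igraph::E(g)$score <- edges$score
        igraph::E(g)$intimacy <- intimacyWeight(edges$score)
    } else {
        g <- igraph::make_empty_graph(0, directed = FALSE)
        g <- if (length(nodes))
            igraph::add_vertices(g, length(nodes), name = nodes)
        else igraph::set_vertex_attr(g, "name", value = character(0))
    }
    new("PPINetwork", graph = g)
}

#' Weighted shortest path between two proteins
#'
#' Dijkstra shortest path under intimacy weights. Among paths of equal
#' total weight the result is made deterministic: the path with the fewest
#' edges is preferred, and remaining ties are broken by lexicographic node
#' sequence. Unreachable pairs are reported with \code{reachable = FALSE}
#' and infinite length.
#'
#' @param network a \linkS4class{PPINetwork}.
#' @param from,to node names, \code{from != to}.
#' @return A list with \code{nodes} (character vector of the node
#'   sequence, empty if unreachable), \code{length} (total intimacy
#'   weight) and \code{reachable} (logical).
#' @export
shortestPath <- function(network, from, to) {
    g <- ppiGraph(network)
    nm <- igraph::V(g)$name
    if (!from %in% nm) stop("unknown node: ", from)
    if (!to %in% nm) stop("unknown node: ", to)
    if (from == to) stop("'from' and 'to' must differ")
    w <- igraph::E(g)$intimacy
    ds <- as.numeric(igraph::distances(g, v = from, weights = w))
    iTo <- match(to, nm)
    if (!is.finite(ds[iTo]))
        return(list(nodes = character(0), length = Inf, reachable = FALSE))
    dt <- as.numeric(igraph::distances(g, v = to, weights = w))
    total <- ds[iTo]
    tol <- 1e-9 * max(1, total)

    # orient edges along the shortest-path DAG: u -> v iff
    # d(s,u) + w(u,v) + d(v,t) == d(s,t)
    el <- igraph::as_edgelist(g, names = FALSE)
    u <- el[, 1L]; v <- el[, 2L]
    f1 <- abs(ds[u] + w + dt[v] - total) <= tol
    f2 <- abs(ds[v] + w + dt[u] - total) <= tol
    dagFrom <- c(u[f1], v[f2])
    dagTo <- c(v[f1], u[f2])

    nV <- length(nm)
    adj <- split(dagTo, factor(dagFrom, levels = seq_len(nV)))
    radj <- split(dagFrom, factor(dagTo, levels = seq_len(nV)))

    # BFS from the target over reversed DAG edges: minimum hops to target
    hops <- rep(NA_integer_, nV)
    hops[iTo] <- 0L
    frontier <- iTo
    while (length(frontier)) {
        nxt <- unique(unlist(radj[frontier], use.names = FALSE))
        nxt <- nxt[is.na(hops[nxt])]
        hops[nxt] <- hops[frontier[1L]] + 1L
        frontier <- nxt
    }

    # greedy walk: always the lexicographically smallest successor that
    # still permits a minimum-hop completion
    cur <- match(from, nm)
    path <- cur
    while (cur != iTo) {
        succ <- adj[[cur]]
        succ <- succ[!is.na(hops[succ]) & hops[succ] == hops[cur] - 1L]
        cur <- succ[order(nm[succ])][1L]
        path <- c(path, cur)
    }
    list(nodes = nm[path], length = total, reachable = TRUE)
}

# all-pairs (sources x targets) intimacy-weighted distances
pairDistances <- function(network, sources, targets) {
    g <- ppiGraph(network)
    igraph::distances(g, v = sources, to = targets,
                      weights = igraph::E(g)$intimacy)
}
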