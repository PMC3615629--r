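#' Simulate a four-stage expression cohort with planted markers
#'
#' Background genes are i.i.d. Gaussian with gene-specific mean and SD
#' drawn from hyperpriors (a log-intensity-like scale). Each planted early
#' marker's mean shifts by \code{effectSize} (in units of its own SD)
#' between stage A and stage B samples, and each late marker's between
#' stages C and D. For every planted early-late pair the late gene's
#' values in the pooled B and C samples are replaced by a mixture
#' \code{rho * standardized(early) + sqrt(1 - rho^2) * noise}, rescaled to
#' the late gene's mean and SD, so the pair's Pearson correlation in the
#' samples the screening stage tests is approximately \code{pathRho}.
#' Intended path interiors are reserved from non-marker genes so the
#' companion \code{\link{simulateNetwork}} can wire them.
#'
#' Identical configurations (including the seed) give identical output.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A list with \code{cohort} (\linkS4class{StageCohort}) and
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @export
simulateCohort <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(config@seed)
    nps <- config@nPerStage[DUKES_STAGES]
    stages <- factor(rep(DUKES_STAGES, nps), levels = DUKES_STAGES)
    nS <- sum(nps)
    nG <- config@nGenes
    geneIds <- geneNames(nG)
    sampleIds <- sprintf("S%04d", seq_len(nS))

    mu <- stats::rnorm(nG, mean = 8, sd = 2)
    sdg <- stats::runif(nG, 0.5, 1.5)
    x <- matrix(stats::rnorm(nG * nS, mean = mu, sd = sdg), nG, nS,
                dimnames = list(geneIds, sampleIds))

    early <- sort(sample(geneIds, config@nEarlyMarkers))
    late <- sort(sample(setdiff(geneIds, early), config@nLateMarkers))
    if (config@effectSize > 0) {
        bCols <- stages == "B"
        dCols <- stages == "D"
        iE <- match(early, geneIds)
        iL <- match(late, geneIds)
        x[iE, bCols] <- x[iE, bCols] + config@effectSize * sdg[iE]
        x[iL, dCols] <- x[iL, dCols] + config@effectSize * sdg[iL]
    }

    pairs <- list()
    if (config@nPlantedPaths > 0L) {
        k <- config@nPlantedPaths
        pe <- sample(early, k)
        pl <- sample(late, k)
        nInterior <- config@plantedPathEdges - 1L
        pool <- setdiff(geneIds, c(early, late))
        interiors <- if (nInterior > 0L) sample(pool, k * nInterior) else character(0)
        bc <- stages %in% c("B", "C")
        rho <- config@pathRho
        for (i in seq_len(k)) {
            ev <- x[pe[i], bc]
            zEarly <- (ev - mean(ev)) / max(popSd(ev), .Machine$double.eps)
            iLate <- match(pl[i], geneIds)
            noise <- stats::rnorm(sum(bc))
            x[iLate, bc] <- mu[iLate] + sdg[iLate] *
                (rho * zEarly + sqrt(1 - rho^2) * noise)
            path <- c(pe[i],
                      if (nInterior > 0L)
                          interiors[((i - 1L) * nInterior + 1L):(i * nInterior)],
                      pl[i])
            pairs[[i]] <- list(early = pe[i], late = pl[i], path = path)
        }
    }

    cohort <- StageCohort(x, stats::setNames(as.character(stages), sampleIds))
    truth <- new("GroundTruth", earlyMarkers = early, lateMarkers = late,
                 plantedPairs = pairs)
    list(cohort = cohort, truth = truth)
}

geneNames <- function(n) sprintf("G%05d", seq_len(n))

# empirically-shaped background confidence scores: most mass near
# 0.15-0.4, a modest middle, and a thin tail above 0.9, so that the
# 300-length cutoff is non-trivially selective
sampleBackgroundScores <- function(m) {
    u <- stats::runif(m)
    ifelse(u < 0.80, stats::runif(m, 0.150, 0.400),
           ifelse(u < 0.95, stats::runif(m, 0.400, 0.900),
                  stats::runif(m, 0.900, 0.999)))
}

#' Simulate a confidence-weighted interaction network
#'
#' Generates a background random graph (Erdos-Renyi at the configured
#' mean degree) over a node set that shares the cohort's gene namespace,
#' then wires every planted pair's intended path with high-confidence
#' edges (score >= 0.95), so each planted path's intimacy-weighted length
#' stays below 300 (at most 5 such edges, each of weight <= 50).
#' Background scores follow a mixture with most mass in 0.15--0.4 and a
#' thin tail above 0.9. A configurable fraction of cohort genes outside
#' the planted paths is deliberately left out of the network, exercising
#' the biomarker mapping step. Deterministic under the configuration seed.
#'
#' @param config the \linkS4class{SimulationConfig} used for the cohort.
#' @param truth the matching \linkS4class{GroundTruth}.
#' @return A \linkS4class{PPINetwork}.
#' @export
simulateNetwork <- function(config, truth) {
    stopifnot(is(config, "SimulationConfig"), is(truth, "GroundTruth"))
    set.seed(deriveSeed(config@seed, 1))
    geneIds <- geneNames(config@nGenes)
    mustHave <- unique(unlist(lapply(plantedPairs(truth), `[[`, "path")))
    nNodes <- max(config@networkNNodes, length(mustHave))

    eligible <- setdiff(geneIds, mustHave)
    kept <- eligible[stats::runif(length(eligible)) >= config@unmappedFraction]
    nFill <- nNodes - length(mustHave)
    nodes <- if (length(kept) >= nFill) {
        c(mustHave, sample(kept, nFill))
    } else {
        c(mustHave, kept,
          sprintf("P%05d", seq_len(nFill - length(kept))))
    }

    m <- round(nNodes * config@networkMeanDegree / 2)
    m <- min(m, nNodes * (nNodes - 1) / 2)
    g <- igraph::sample_gnm(nNodes, m, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- data.frame(protein1 = nodes[el[, 1L]],
                        protein2 = nodes[el[, 2L]],
                        score = sampleBackgroundScores(nrow(el)),
                        stringsAsFactors = FALSE)

    planted <- do.call(rbind, lapply(plantedPairs(truth), function(pp) {
        p <- pp$path
        data.frame(protein1 = p[-length(p)], protein2 = p[-1L],
                   score = stats::runif(length(p) - 1L, 0.95, 0.999),
                   stringsAsFactors = FALSE)
    }))
    if (!is.null(planted))
        edges <- rbind(edges, planted)

    buildGraph(edges, nodes = nodes)
}
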