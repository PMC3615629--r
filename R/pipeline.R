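#' Run the full staged-network analysis
#'
#' Orchestrates the end-to-end pipeline: obtain a cohort and network
#' (either simulated from a \linkS4class{SimulationConfig} or read from
#' files), select early (A vs B) and late (C vs D) biomarkers by
#' mRMR + IFS, map them onto the network, screen all early-late pairs by
#' the dual path-length / correlation-FDR criterion, assign permutation
#' FDRs, rank transition hubs, and compute the early/late overlap
#' statistics. All stages are deterministic given the configuration, so a
#' rerun reproduces every output bit-identically.
#'
#' Exactly one input mode must be used: either \code{simConfig}, or all
#' three of \code{expressionFile}, \code{stageFile}, \code{networkFile}.
#'
#' @param simConfig a \linkS4class{SimulationConfig}, or \code{NULL}.
#' @param expressionFile,stageFile,networkFile input paths (see
#'   \code{\link{readExpression}}, \code{\link{readNetwork}}).
#' @param kSd,scheme,maxK biomarker-selection parameters
#'   (\code{\link{selectBiomarkers}}).
#' @param lengthCutoff,fdrCutoff screening cutoffs
#'   (\code{\link{screenTransitions}}).
#' @param nPermutations permutation count for \code{\link{pathFdr}}.
#' @param seed integer seed for the permutation stream (simulation uses
#'   the seed inside \code{simConfig}).
#' @param outDir if non-NULL, all result tables plus a JSON run manifest
#'   are written there.
#' @return Invisibly, a list with \code{cohort}, \code{network},
#'   \code{truth} (simulation mode only), \code{earlySet},
#'   \code{lateSet}, \code{paths}, \code{hubs}, \code{overlap} and
#'   \code{manifest}.
#' @export
runPipeline <- function(simConfig = NULL,
                        expressionFile = NULL, stageFile = NULL,
                        networkFile = NULL,
                        kSd = 1, scheme = "MIQ", maxK = 500,
                        lengthCutoff = 300, fdrCutoff = 0.001,
                        nPermutations = 1000, seed = 1,
                        outDir = NULL) {
    fileMode <- !is.null(expressionFile) || !is.null(stageFile) ||
        !is.null(networkFile)
    if (is.null(simConfig) == !fileMode)
        stop("provide exactly one of: simConfig, or the three input files")
    if (lengthCutoff < 0 || fdrCutoff < 0)
        stop("cutoffs must be non-negative")

    truth <- NULL
    if (!is.null(simConfig)) {
        sim <- simulateCohort(simConfig)
        cohort <- sim$cohort
        truth <- sim$truth
        network <- simulateNetwork(simConfig, truth)
    } else {
        if (is.null(expressionFile) || is.null(stageFile) ||
            is.null(networkFile))
            stop("file mode needs expressionFile, stageFile and networkFile")
        cohort <- readExpression(expressionFile, stageFile)
        network <- buildGraph(readNetwork(networkFile))
    }

    earlySet <- withStage("biomarker selection (early, A vs B)",
        selectBiomarkers(cohort, "early", kSd = kSd, scheme = scheme,
                         maxK = maxK))
    lateSet <- withStage("biomarker selection (late, C vs D)",
        selectBiomarkers(cohort, "late", kSd = kSd, scheme = scheme,
                         maxK = maxK))

    eMapped <- suppressMessages(mapBiomarkers(optimalGenes(earlySet), network))
    lMapped <- suppressMessages(mapBiomarkers(optimalGenes(lateSet), network))

    paths <- withStage("transition screening",
        screenTransitions(network, eMapped, lMapped, cohort,
                          lengthCutoff = lengthCutoff,
                          fdrCutoff = fdrCutoff))
    paths <- withStage("permutation FDR",
        pathFdr(paths, network, cohort, nPermutations = nPermutations,
                seed = deriveSeed(seed, 2)))
    hubs <- countCrossings(paths)
    overlap <- overlapStatistics(optimalGenes(earlySet),
                                 optimalGenes(lateSet), nrow(cohort))

    sm <- S4Vectors::metadata(paths)$summary
    manifest <- list(
        parameters = list(kSd = kSd, scheme = scheme, maxK = maxK,
                          lengthCutoff = lengthCutoff,
                          fdrCutoff = fdrCutoff,
                          nPermutations = nPermutations, seed = seed,
                          simulated = !is.null(simConfig)),
        package_version = as.character(utils::packageVersion("stagePath")),
        counts = list(
            nGenes = nrow(cohort), nSamples = ncol(cohort),
            earlyOptimalK = optimalK(earlySet),
            lateOptimalK = optimalK(lateSet),
            earlyMapped = length(eMapped), lateMapped = length(lMapped),
            pairsTested = sm$nPairsTested,
            pathsRetained = sm$nPathsRetained,
            earlyLinked = sm$nEarlyLinked, lateLinked = sm$nLateLinked,
            transitionGenes = nrow(hubs)))

    result <- list(cohort = cohort, network = network, truth = truth,
                   earlySet = earlySet, lateSet = lateSet, paths = paths,
                   hubs = hubs, overlap = overlap, manifest = manifest)
    if (!is.null(outDir))
        writeResultBundle(result, outDir)
    invisible(result)
}

withStage <- function(stageName, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline failed in stage '", stageName, "': ",
             conditionMessage(e), call. = FALSE))
}

writeBiomarkerTables <- function(set, prefix, outDir) {
    utils::write.table(
        data.frame(rank = seq_along(rankedGenes(set)),
                   gene = rankedGenes(set)),
        file.path(outDir, paste0(prefix, "_ranked.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
        data.frame(k = seq_along(ifsCurve(set)),
                   accuracy = formatNum(ifsCurve(set))),
        file.path(outDir, paste0(prefix, "_ifs_curve.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
        data.frame(gene = optimalGenes(set)),
        file.path(outDir, paste0(prefix, "_optimal.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
}

writeResultBundle <- function(result, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeBiomarkerTables(result$earlySet, "early", outDir)
    writeBiomarkerTables(result$lateSet, "late", outDir)
    writePathTable(result$paths, file.path(outDir, "paths.tsv"))
    utils::write.table(result$hubs, file.path(outDir, "hubs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ov <- result$overlap
    writeLines(sprintf("%s\t%s",
                       c("n_universe", "n_set1", "n_set2", "n_overlap",
                         "expected_overlap", "odds_ratio"),
                       c(ov$nUniverse, ov$nSet1, ov$nSet2, ov$nOverlap,
                         formatNum(ov$expectedOverlap),
                         formatNum(ov$oddsRatio))),
               file.path(outDir, "overlap.txt"))
    jsonlite::write_json(result$manifest,
                         file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (!is.null(result$truth))
        writeGroundTruth(result$truth, file.path(outDir, "ground_truth.json"))
    invisible(outDir)
}
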