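#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

DUKES_STAGES <- c("A", "B", "C", "D")

#' Four-stage expression cohort
#'
#' A genes-by-samples expression matrix together with a per-sample Dukes
#' stage label (A, B, C or D), stored as a
#' \linkS4class{SummarizedExperiment} whose \code{colData} carries the
#' \code{stage} factor. Early-stage biomarkers are selected from the A-vs-B
#' contrast, late-stage biomarkers from C-vs-D, and pair correlations are
#' tested on the pooled B and C samples.
#'
#' @slot .. inherits all slots from \code{SummarizedExperiment}.
#' @aliases StageCohort-class
#' @exportClass StageCohort
setClass("StageCohort", contains = "SummarizedExperiment")

setValidity("StageCohort", function(object) {
    msg <- character(0)
    if (length(SummarizedExperiment::assays(object)) < 1L)
        return("cohort must carry one expression assay")
    m <- SummarizedExperiment::assay(object, 1L)
    if (!is.numeric(m))
        msg <- c(msg, "expression values must be numeric")
    else if (any(!is.finite(m)))
        msg <- c(msg, "expression values must all be finite")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    if (!"stage" %in% colnames(cd)) {
        msg <- c(msg, "colData must contain a 'stage' column")
    } else {
        st <- cd$stage
        if (anyNA(st) || !all(as.character(st) %in% DUKES_STAGES))
            msg <- c(msg, "every sample needs a stage label in {A, B, C, D}")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a StageCohort
#'
#' @param values numeric matrix, genes in rows (unique rownames) and samples
#'   in columns (unique colnames).
#' @param stages character or factor of stage labels in \code{A}--\code{D},
#'   either in column order or named by sample identifier.
#' @return A \linkS4class{StageCohort}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' StageCohort(m, c("A", "B", "C", "D"))
#' @export
StageCohort <- function(values, stages) {
    if (!is.matrix(values))
        values <- as.matrix(values)
    stages <- stats::setNames(as.character(stages), names(stages))
    if (!is.null(names(stages))) {
        if (!all(colnames(values) %in% names(stages)))
            stop("stage labels missing for sample(s): ",
                 paste(setdiff(colnames(values), names(stages)), collapse = ", "))
        stages <- stages[colnames(values)]
    } else if (length(stages) != ncol(values)) {
        stop("'stages' must have one label per sample column")
    }
    bad <- !stages %in% DUKES_STAGES
    if (any(bad))
        stop("unknown stage token '", stages[bad][1L], "' for sample '",
             colnames(values)[bad][1L], "' (expected A, B, C or D)")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(
            stage = factor(stages, levels = DUKES_STAGES),
            row.names = colnames(values)))
    new("StageCohort", se)
}

#' Confidence-weighted protein interaction network
#'
#' An undirected simple graph whose edges carry a confidence score in
#' [0.150, 1] and the derived intimacy weight \code{1000 * (1 - score)},
#' so that high-confidence interactions correspond to short distances.
#'
#' @slot graph an igraph object with vertex \code{name} and edge
#'   \code{score} / \code{intimacy} attributes.
#' @aliases PPINetwork-class
#' @exportClass PPINetwork
setClass("PPINetwork", representation(graph = "ANY"))

setValidity("PPINetwork", function(object) {
    g <- object@graph
    if (!igraph::is_igraph(g))
        return("'graph' slot must hold an igraph object")
    msg <- character(0)
    if (igraph::is_directed(g))
        msg <- c(msg, "network must be undirected")
    nm <- igraph::V(g)$name
    if (is.null(nm) || anyDuplicated(nm))
        msg <- c(msg, "vertices must carry unique names")
    if (igraph::ecount(g) > 0) {
        if (any(igraph::which_loop(g)))
            msg <- c(msg, "self-loops are not allowed")
        if (any(igraph::which_multiple(g)))
            msg <- c(msg, "parallel edges are not allowed")
        sc <- igraph::E(g)$score
        iw <- igraph::E(g)$intimacy
        if (is.null(sc) || is.null(iw)) {
            msg <- c(msg, "edges must carry 'score' and 'intimacy' attributes")
        } else {
            if (any(sc < 0.150 - 1e-12) || any(sc > 1 + 1e-12))
                msg <- c(msg, "confidence scores must lie in [0.150, 1]")
            if (any(abs(iw - 1000 * (1 - sc)) > 1e-6))
                msg <- c(msg, "intimacy weights must equal 1000 * (1 - score)")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Biomarker set from mRMR ranking and incremental feature selection
#'
#' Holds the full mRMR gene ranking, the leave-one-out accuracy achieved by
#' every evaluated prefix of that ranking (the IFS curve), and the index of
#' the optimal prefix (smallest prefix attaining the maximum accuracy).
#'
#' @slot contrast character(2), the two stages compared (e.g. c("A","B")).
#' @slot rankedGenes character, genes in mRMR order.
#' @slot curve numeric, LOOCV accuracy of the top-k prefix, k = 1..maxK.
#' @slot optimalK integer, smallest k attaining \code{max(curve)}.
#' @aliases BiomarkerSet-class
#' @exportClass BiomarkerSet
setClass("BiomarkerSet", representation(
    contrast = "character",
    rankedGenes = "character",
    curve = "numeric",
    optimalK = "integer"))

setValidity("BiomarkerSet", function(object) {
    msg <- character(0)
    if (length(object@contrast) != 2L ||
        object@contrast[1L] == object@contrast[2L])
        msg <- c(msg, "contrast must name two distinct stages")
    if (length(object@curve) > length(object@rankedGenes))
        msg <- c(msg, "curve cannot be longer than the ranked gene list")
    if (length(object@curve)) {
        if (any(object@curve < 0 | object@curve > 1))
            msg <- c(msg, "accuracies must lie in [0, 1]")
        k <- object@optimalK
        if (length(k) != 1L || k < 1L || k > length(object@curve))
            msg <- c(msg, "optimalK out of range")
        else if (k != which.max(object@curve))
            msg <- c(msg, "optimalK must be the smallest index attaining the maximum accuracy")
    }
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated cohort/network pair
#'
#' Records which genes were planted as early and late markers and which
#' early-late pairs were made network-close and co-expressed, including the
#' intended high-confidence path for each pair.
#'
#' @slot earlyMarkers,lateMarkers character vectors of planted marker ids.
#' @slot plantedPairs list; each element is a list with components
#'   \code{early}, \code{late} and \code{path} (the intended node sequence
#'   from the early to the late gene).
#' @aliases GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
    earlyMarkers = "character",
    lateMarkers = "character",
    plantedPairs = "list"))

setValidity("GroundTruth", function(object) {
    msg <- character(0)
    for (pp in object@plantedPairs) {
        if (!all(c("early", "late", "path") %in% names(pp))) {
            msg <- c(msg, "each planted pair needs 'early', 'late' and 'path'")
            break
        }
        if (!pp$early %in% object@earlyMarkers ||
            !pp$late %in% object@lateMarkers) {
            msg <- c(msg, "planted pair endpoints must belong to the marker sets")
            break
        }
        if (length(pp$path) < 2L || pp$path[1L] != pp$early ||
            pp$path[length(pp$path)] != pp$late) {
            msg <- c(msg, "intended paths must run from the early to the late gene")
            break
        }
    }
    if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Parameters of the synthetic cohort/network generator. Defaults emulate
#' the shape of a staged colorectal-cancer microarray study (stage sizes
#' 44/94/91/61) at desk scale; see the package vignette for the rationale
#' behind each default.
#'
#' @slot nGenes number of genes in the cohort.
#' @slot nPerStage named integer, samples per stage A--D (all >= 1).
#' @slot nEarlyMarkers,nLateMarkers planted marker counts.
#' @slot effectSize mean shift, in within-group SD units, of early markers
#'   between stages A and B and of late markers between C and D.
#' @slot nPlantedPaths number of early-late pairs made network-close and
#'   co-expressed in the pooled B/C samples.
#' @slot pathRho target Pearson correlation of planted pairs in B and C.
#' @slot plantedPathEdges edges per planted path (1--5; at confidence
#'   >= 0.95 five edges keep the weighted length below 300).
#' @slot networkNNodes,networkMeanDegree background-network shape.
#' @slot confidenceRange admissible confidence scores, fixed [0.150, 1].
#' @slot unmappedFraction fraction of cohort genes (outside planted paths)
#'   deliberately absent from the network, exercising the mapping step.
#' @slot seed integer RNG seed.
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
    nGenes = "integer",
    nPerStage = "integer",
    nEarlyMarkers = "integer",
    nLateMarkers = "integer",
    effectSize = "numeric",
    nPlantedPaths = "integer",
    pathRho = "numeric",
    plantedPathEdges = "integer",
    networkNNodes = "integer",
    networkMeanDegree = "numeric",
    confidenceRange = "numeric",
    unmappedFraction = "numeric",
    seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character(0)
    nps <- object@nPerStage
    if (!identical(sort(names(nps)), DUKES_STAGES))
        msg <- c(msg, "nPerStage must name all four stages A, B, C, D")
    else if (any(nps < 1L))
        msg <- c(msg, "every stage needs at least one sample")
    if (object@nGenes < 1L)
        msg <- c(msg, "nGenes must be positive")
    if (object@nEarlyMarkers < 0L || object@nLateMarkers < 0L)
        msg <- c(msg, "marker counts cannot be negative")
    if (object@nEarlyMarkers + object@nLateMarkers > object@nGenes)
        msg <- c(msg, "marker counts exceed nGenes")
    if (object@effectSize < 0)
        msg <- c(msg, "effectSize must be >= 0")
    if (object@pathRho < 0 || object@pathRho > 1)
        msg <- c(msg, "pathRho must lie in [0, 1]")
    if (object@nPlantedPaths > min(object@nEarlyMarkers, object@nLateMarkers))
        msg <- c(msg, "nPlantedPaths cannot exceed the planted marker counts")
    if (object@plantedPathEdges < 1L || object@plantedPathEdges > 5L)
        msg <- c(msg, "plantedPathEdges must lie in 1..5 so planted lengths stay below 300")
    interiorNeeded <- object@nPlantedPaths * (object@plantedPathEdges - 1L)
    if (interiorNeeded > object@nGenes - object@nEarlyMarkers - object@nLateMarkers)
        msg <- c(msg, "not enough non-marker genes to host planted path interiors")
    if (!identical(object@confidenceRange, c(0.150, 1)))
        msg <- c(msg, "confidenceRange is fixed at [0.150, 1]")
    if (object@unmappedFraction < 0 || object@unmappedFraction >= 1)
        msg <- c(msg, "unmappedFraction must lie in [0, 1)")
    if (object@networkNNodes < 2L)
        msg <- c(msg, "networkNNodes must be >= 2")
    if (object@networkMeanDegree <= 0)
        msg <- c(msg, "networkMeanDegree must be positive")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig-class user constructor with defaults.
#' @param nGenes,nPerStage,nEarlyMarkers,nLateMarkers,effectSize,nPlantedPaths
#'   see slots.
#' @param pathRho,plantedPathEdges,networkNNodes,networkMeanDegree see slots.
#' @param unmappedFraction,seed see slots.
#' @return A validated \code{SimulationConfig}.
#' @export
simulationConfig <- function(nGenes = 1000,
                             nPerStage = c(A = 44, B = 94, C = 91, D = 61),
                             nEarlyMarkers = 10, nLateMarkers = 10,
                             effectSize = 3, nPlantedPaths = 5,
                             pathRho = 0.85, plantedPathEdges = 3,
                             networkNNodes = 300, networkMeanDegree = 6,
                             unmappedFraction = 0.1, seed = 1) {
    nps <- as.integer(nPerStage)
    names(nps) <- names(nPerStage)
    new("SimulationConfig",
        nGenes = as.integer(nGenes),
        nPerStage = nps,
        nEarlyMarkers = as.integer(nEarlyMarkers),
        nLateMarkers = as.integer(nLateMarkers),
        effectSize = as.numeric(effectSize),
        nPlantedPaths = as.integer(nPlantedPaths),
        pathRho = as.numeric(pathRho),
        plantedPathEdges = as.integer(plantedPathEdges),
        networkNNodes = as.integer(networkNNodes),
        networkMeanDegree = as.numeric(networkMeanDegree),
        confidenceRange = c(0.150, 1),
        unmappedFraction = as.numeric(unmappedFraction),
        seed = as.integer(seed))
}
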