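#' Accessors for stagePath classes
#'
#' Small accessor generics: stage labels of a cohort, the expression
#' matrix, the underlying igraph of a network, node names, the mRMR
#' ranking, IFS curve and optimal gene set of a \code{BiomarkerSet}, and
#' the components of a \code{GroundTruth}.
#'
#' @param x an object of the documented class.
#' @return See the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("stageOf", function(x) standardGeneric("stageOf"))

#' @rdname accessors
#' @export
setMethod("stageOf", "StageCohort", function(x) {
    stats::setNames(SummarizedExperiment::colData(x)$stage, colnames(x))
})

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setMethod("exprValues", "StageCohort", function(x) {
    SummarizedExperiment::assay(x, 1L)
})

#' @rdname accessors
#' @export
setGeneric("ppiGraph", function(x) standardGeneric("ppiGraph"))

#' @rdname accessors
#' @export
setMethod("ppiGraph", "PPINetwork", function(x) x@graph)

#' @rdname accessors
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname accessors
#' @export
setMethod("nodeNames", "PPINetwork", function(x) igraph::V(x@graph)$name)

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setMethod("edgeTable", "PPINetwork", function(x) {
    g <- x@graph
    el <- igraph::as_edgelist(g, names = TRUE)
    if (!nrow(el))
        return(data.frame(protein1 = character(0), protein2 = character(0),
                          score = numeric(0), intimacy = numeric(0),
                          stringsAsFactors = FALSE))
    # canonical endpoint order, independent of internal vertex indexing
    data.frame(protein1 = pmin(el[, 1L], el[, 2L]),
               protein2 = pmax(el[, 1L], el[, 2L]),
               score = igraph::E(g)$score,
               intimacy = igraph::E(g)$intimacy,
               stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setGeneric("rankedGenes", function(x) standardGeneric("rankedGenes"))

#' @rdname accessors
#' @export
setMethod("rankedGenes", "BiomarkerSet", function(x) x@rankedGenes)

#' @rdname accessors
#' @export
setGeneric("ifsCurve", function(x) standardGeneric("ifsCurve"))

#' @rdname accessors
#' @export
setMethod("ifsCurve", "BiomarkerSet", function(x) x@curve)

#' @rdname accessors
#' @export
setGeneric("optimalK", function(x) standardGeneric("optimalK"))

#' @rdname accessors
#' @export
setMethod("optimalK", "BiomarkerSet", function(x) x@optimalK)

#' @rdname accessors
#' @export
setGeneric("optimalGenes", function(x) standardGeneric("optimalGenes"))

#' @rdname accessors
#' @export
setMethod("optimalGenes", "BiomarkerSet", function(x) {
    x@rankedGenes[seq_len(x@optimalK)]
})

#' @rdname accessors
#' @export
setGeneric("contrastStages", function(x) standardGeneric("contrastStages"))

#' @rdname accessors
#' @export
setMethod("contrastStages", "BiomarkerSet", function(x) x@contrast)

#' @rdname accessors
#' @export
setGeneric("earlyMarkers", function(x) standardGeneric("earlyMarkers"))

#' @rdname accessors
#' @export
setMethod("earlyMarkers", "GroundTruth", function(x) x@earlyMarkers)

#' @rdname accessors
#' @export
setGeneric("lateMarkers", function(x) standardGeneric("lateMarkers"))

#' @rdname accessors
#' @export
setMethod("lateMarkers", "GroundTruth", function(x) x@lateMarkers)

#' @rdname accessors
#' @export
setGeneric("plantedPairs", function(x) standardGeneric("plantedPairs"))

#' @rdname accessors
#' @export
setMethod("plantedPairs", "GroundTruth", function(x) x@plantedPairs)

setMethod("show", "StageCohort", function(object) {
    st <- table(stageOf(object))
    cat("StageCohort:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("  stages:", paste(names(st), st, sep = "=", collapse = " "), "\n")
})

setMethod("show", "PPINetwork", function(object) {
    g <- object@graph
    cat("PPINetwork:", igraph::vcount(g), "proteins,",
        igraph::ecount(g), "scored interactions\n")
    if (igraph::ecount(g))
        cat("  score range:",
            paste(signif(range(igraph::E(g)$score), 3), collapse = " - "), "\n")
})

setMethod("show", "BiomarkerSet", function(object) {
    cat("BiomarkerSet (", object@contrast[1L], " vs ", object@contrast[2L],
        "): ", length(object@rankedGenes), " ranked genes\n", sep = "")
    if (length(object@curve))
        cat("  optimal set:", object@optimalK, "genes, LOOCV accuracy",
            signif(object@curve[object@optimalK], 3), "\n")
})

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", length(object@earlyMarkers), "early and",
        length(object@lateMarkers), "late planted markers;",
        length(object@plantedPairs), "planted pairs\n")
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nGenes, "genes;",
        paste(names(object@nPerStage), object@nPerStage, sep = "=",
              collapse = " "), "\n")
    cat("  markers:", object@nEarlyMarkers, "early /", object@nLateMarkers,
        "late; effect", object@effectSize, "SD; planted paths",
        object@nPlantedPaths, "(rho", object@pathRho, ")\n")
    cat("  network:", object@networkNNodes, "nodes, mean degree",
        object@networkMeanDegree, "; seed", object@seed, "\n")
})
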