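#' Read an expression cohort from TSV files
#'
#' The matrix file is tab-delimited with gene identifiers in the first
#' column and a header row of sample identifiers; the stage file is a
#' two-column tab-delimited table (\code{sample}, \code{stage}) assigning
#' every sample one of the Dukes stages A--D. Malformed input is rejected
#' with an error naming the offending gene, sample or token — nothing is
#' silently coerced.
#'
#' @param matrixPath path to the genes x samples TSV.
#' @param stagePath path to the sample-to-stage TSV.
#' @return A \linkS4class{StageCohort}.
#' @export
readExpression <- function(matrixPath, stagePath) {
    raw <- utils::read.delim(matrixPath, header = TRUE, check.names = FALSE,
                             colClasses = "character")
    if (ncol(raw) < 2L)
        stop("expression matrix needs a gene-id column plus sample columns")
    geneIds <- raw[[1L]]
    if (anyDuplicated(geneIds))
        stop("duplicate gene identifier(s): ",
             paste(unique(geneIds[duplicated(geneIds)]), collapse = ", "))
    sampleIds <- colnames(raw)[-1L]
    vals <- matrix(NA_real_, nrow(raw), length(sampleIds),
                   dimnames = list(geneIds, sampleIds))
    for (j in seq_along(sampleIds)) {
        col <- raw[[j + 1L]]
        num <- suppressWarnings(as.numeric(col))
        bad <- which(!is.finite(num))
        if (length(bad))
            stop("non-numeric or missing value for gene '", geneIds[bad[1L]],
                 "', sample '", sampleIds[j], "'")
        vals[, j] <- num
    }
    st <- utils::read.delim(stagePath, header = TRUE, check.names = FALSE,
                            colClasses = "character")
    if (ncol(st) < 2L)
        stop("stage file needs two columns: sample, stage")
    stages <- stats::setNames(st[[2L]], st[[1L]])
    missing <- setdiff(sampleIds, names(stages))
    if (length(missing))
        stop("no stage label for sample(s): ", paste(missing, collapse = ", "))
    bad <- !stages %in% DUKES_STAGES
    if (any(bad))
        stop("unknown stage token '", stages[bad][1L], "' for sample '",
             names(stages)[bad][1L], "'")
    StageCohort(vals, stages[sampleIds])
}

#' Write a cohort to TSV files
#'
#' Inverse of \code{\link{readExpression}}.
#'
#' @param cohort a \linkS4class{StageCohort}.
#' @param matrixPath,stagePath output file paths.
#' @return Invisibly, the two paths.
#' @export
writeCohort <- function(cohort, matrixPath, stagePath) {
    m <- exprValues(cohort)
    fm <- apply(m, 2L, formatNum)
    dimnames(fm) <- dimnames(m)
    df <- data.frame(gene = rownames(m), fm,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, matrixPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    st <- data.frame(sample = colnames(m),
                     stage = as.character(stageOf(cohort)),
                     stringsAsFactors = FALSE)
    utils::write.table(st, stagePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(matrixPath, stagePath))
}

#' Read a confidence-scored interaction edge list
#'
#' Reads a STRING-style whitespace- or tab-delimited three-column file
#' (\code{protein1}, \code{protein2}, combined score), with or without a
#' header line. Scores are brought onto the unit scale: \code{milli}
#' divides by 1000 (STRING's native 150--999 convention), \code{unit}
#' keeps them as-is, and \code{auto} infers \code{milli} whenever any
#' score exceeds 1. Self-loops are dropped; duplicate undirected edges
#' are collapsed keeping the maximum score; edges below the admissible
#' minimum 0.150 are dropped (never clamped) with a message reporting the
#' count.
#'
#' @param edgePath path to the edge-list file.
#' @param scoreScale one of \code{"auto"}, \code{"unit"}, \code{"milli"}.
#' @return A data frame with columns \code{protein1}, \code{protein2},
#'   \code{score} (unit scale).
#' @export
readNetwork <- function(edgePath, scoreScale = c("auto", "unit", "milli")) {
    scoreScale <- match.arg(scoreScale)
    first <- strsplit(trimws(readLines(edgePath, n = 1L)), "[ \t]+")[[1L]]
    hasHeader <- length(first) >= 3L &&
        is.na(suppressWarnings(as.numeric(first[3L])))
    df <- utils::read.table(edgePath, header = hasHeader,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 3L)
        stop("edge list needs three columns: protein1, protein2, score")
    df <- df[, 1:3]
    colnames(df) <- c("protein1", "protein2", "score")
    if (!is.numeric(df$score))
        stop("third column must be numeric confidence scores")
    if (scoreScale == "auto")
        scoreScale <- if (any(df$score > 1)) "milli" else "unit"
    if (scoreScale == "milli")
        df$score <- df$score / 1000
    normalizeEdges(df)
}

#' Write an edge list in STRING flavor
#'
#' @param edges data frame with \code{protein1}, \code{protein2},
#'   \code{score}, or a \linkS4class{PPINetwork}.
#' @param edgePath output path.
#' @return Invisibly, the path.
#' @export
writeNetwork <- function(edges, edgePath) {
    if (is(edges, "PPINetwork"))
        edges <- edgeTable(edges)[, c("protein1", "protein2", "score")]
    utils::write.table(
        data.frame(protein1 = edges$protein1, protein2 = edges$protein2,
                   score = formatNum(edges$score)),
        edgePath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(edgePath)
}

pathTableColumns <- c("early_gene", "late_gene", "path", "length",
                      "pearson_r", "pearson_p", "correlation_fdr",
                      "permutation_fdr")

#' Write a signal propagation path table
#'
#' One row per retained path: early gene, late gene, the arrow-joined node
#' sequence, weighted length, Pearson r, Pearson p, Benjamini-Hochberg
#' correlation FDR and (when computed) the permutation FDR. Numeric
#' columns are written at full precision so that
#' \code{\link{readPathTable}} round-trips losslessly.
#'
#' @param paths a path table as returned by \code{\link{screenTransitions}}.
#' @param outPath output TSV path.
#' @return Invisibly, the path.
#' @export
writePathTable <- function(paths, outPath) {
    df <- data.frame(
        early_gene = paths$early, late_gene = paths$late,
        path = paths$path,
        length = formatNum(paths$length),
        pearson_r = formatNum(paths$r),
        pearson_p = formatNum(paths$p),
        correlation_fdr = formatNum(paths$fdr),
        permutation_fdr = formatNum(paths$permFdr),
        stringsAsFactors = FALSE)
    colnames(df) <- pathTableColumns
    con <- file(outPath, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(outPath)
}

formatNum <- function(x) {
    out <- vapply(x, function(v) {
        if (is.na(v)) "NA" else sprintf("%.17g", v)
    }, character(1))
    out
}

#' Read back a signal propagation path table
#'
#' @param inPath TSV written by \code{\link{writePathTable}}.
#' @return An \code{S4Vectors::DataFrame} with the same columns as
#'   \code{\link{screenTransitions}} output.
#' @export
readPathTable <- function(inPath) {
    df <- utils::read.delim(inPath, header = TRUE, stringsAsFactors = FALSE,
                            encoding = "UTF-8")
    S4Vectors::DataFrame(
        early = as.character(df$early_gene),
        late = as.character(df$late_gene),
        path = as.character(df$path),
        length = as.numeric(df$length),
        r = as.numeric(df$pearson_r),
        p = as.numeric(df$pearson_p),
        fdr = as.numeric(df$correlation_fdr),
        permFdr = as.numeric(df$permutation_fdr))
}

#' Export a network for external viewers
#'
#' Writes either a SIF file (one \code{a pp b} line per edge) or GraphML
#' (including score, intimacy and optional node role attributes), both
#' loadable by standard network viewers.
#'
#' @param network a \linkS4class{PPINetwork}.
#' @param nodeAnnotations optional named character vector assigning nodes a
#'   role in \code{early}, \code{late}, \code{both}, \code{transition}.
#' @param format \code{"SIF"} or \code{"GraphML"} (case-insensitive).
#' @param outPath output file path.
#' @return Invisibly, the path.
#' @export
exportNetwork <- function(network, nodeAnnotations = NULL,
                          format = c("SIF", "GraphML"), outPath) {
    fmt <- tolower(format[1L])
    if (!fmt %in% c("sif", "graphml"))
        stop("unknown format token: ", format[1L])
    roles <- c("early", "late", "both", "transition")
    if (!is.null(nodeAnnotations)) {
        if (!all(nodeAnnotations %in% roles))
            stop("node roles must be one of: ", paste(roles, collapse = ", "))
        if (!all(names(nodeAnnotations) %in% nodeNames(network)))
            stop("annotation for unknown node(s)")
    }
    g <- ppiGraph(network)
    if (fmt == "sif") {
        et <- edgeTable(network)
        lines <- sprintf("%s\tpp\t%s", et$protein1, et$protein2)
        iso <- setdiff(nodeNames(network), c(et$protein1, et$protein2))
        writeLines(c(lines, iso), outPath)
    } else {
        role <- rep("", igraph::vcount(g))
        if (!is.null(nodeAnnotations)) {
            idx <- match(names(nodeAnnotations), igraph::V(g)$name)
            role[idx] <- unname(nodeAnnotations)
        }
        g <- igraph::set_vertex_attr(g, "role", value = role)
        igraph::write_graph(g, outPath, format = "graphml")
    }
    invisible(outPath)
}

#' Write / read simulation ground truth as JSON
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param path file path.
#' @return \code{writeGroundTruth}: invisibly, the path;
#'   \code{readGroundTruth}: a \linkS4class{GroundTruth}.
#' @export
writeGroundTruth <- function(truth, path) {
    jsonlite::write_json(
        list(early_markers = earlyMarkers(truth),
             late_markers = lateMarkers(truth),
             planted_pairs = lapply(plantedPairs(truth), function(pp)
                 list(early = pp$early, late = pp$late, path = pp$path))),
        path, auto_unbox = FALSE, pretty = TRUE)
    invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    pairs <- x$planted_pairs
    pairs <- if (is.data.frame(pairs)) {
        lapply(seq_len(nrow(pairs)), function(i)
            list(early = as.character(pairs$early[[i]]),
                 late = as.character(pairs$late[[i]]),
                 path = as.character(unlist(pairs$path[i]))))
    } else if (is.null(pairs) || !length(pairs)) {
        list()
    } else {
        lapply(pairs, function(pp)
            list(early = as.character(unlist(pp$early)),
                 late = as.character(unlist(pp$late)),
                 path = as.character(unlist(pp$path))))
    }
    new("GroundTruth",
        earlyMarkers = as.character(x$early_markers),
        lateMarkers = as.character(x$late_markers),
        plantedPairs = pairs)
}
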