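#' Ternary discretization of expression values
#'
#' Per gene, values below mean - kSd * SD map to -1, values above
#' mean + kSd * SD to +1, everything else (boundaries included) to 0.
#' The SD is the population SD (divide by n). Constant genes yield an
#' all-zero state vector; their count is reported with a message.
#'
#' @param x numeric vector, or a genes x samples matrix discretized
#'   row-wise.
#' @param kSd threshold in SD units (default 1).
#' @return Integer vector or matrix with values in \{-1, 0, 1\}.
#' @examples
#' discretizeExpression(c(0, 0, 0, 10))  # 0 0 0 1
#' @export
discretizeExpression <- function(x, kSd = 1) {
    if (is.matrix(x)) {
        out <- t(apply(x, 1L, discretizeVector, kSd = kSd))
        dimnames(out) <- dimnames(x)
        nConst <- sum(apply(x, 1L, function(v) popSd(v) == 0))
        if (nConst > 0)
            message(nConst, " constant gene(s) discretized to all-zero states")
        return(out)
    }
    v <- discretizeVector(x, kSd)
    if (popSd(x) == 0 && length(x) > 1L)
        message("constant vector discretized to all-zero states")
    v
}

discretizeVector <- function(v, kSd) {
    if (any(!is.finite(v))) stop("values must be finite")
    if (length(v) < 2L) stop("need at least 2 samples")
    m <- mean(v)
    s <- popSd(v)
    out <- integer(length(v))
    if (s > 0) {
        out[v < m - kSd * s] <- -1L
        out[v > m + kSd * s] <- 1L
    }
    out
}

#' Plug-in mutual information of two discrete vectors
#'
#' Empirical (maximum-likelihood) mutual information in nats, computed
#' from the joint table of the two vectors. \code{mutualInformation(x, x)}
#' equals the plug-in entropy of \code{x}.
#'
#' @param x,y discrete vectors of equal length (any values usable as
#'   factor levels).
#' @return Non-negative mutual information in nats.
#' @examples
#' mutualInformation(rep(0:1, 4), rep(0:1, 4))  # log(2)
#' @export
mutualInformation <- function(x, y) {
    if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
    if (!length(x)) return(0)
    xi <- as.integer(factor(x))
    yi <- as.integer(factor(y))
    miCoded(xi, max(xi), yi, max(yi))
}

# MI from integer codes in 1..nx / 1..ny (fast path for the mRMR loop)
miCoded <- function(xi, nx, yi, ny) {
    n <- length(xi)
    joint <- tabulate(xi + nx * (yi - 1L), nx * ny) / n
    px <- tabulate(xi, nx) / n
    py <- tabulate(yi, ny) / n
    e <- as.vector(outer(px, py))
    nz <- joint > 0
    sum(joint[nz] * log(joint[nz] / e[nz]))
}

#' mRMR gene ranking
#'
#' Greedy minimum-redundancy maximum-relevance forward selection on
#' discretized expression. The first gene maximizes relevance
#' \code{MI(gene, label)}; each subsequent gene maximizes relevance
#' divided by (MIQ, default) or minus (MID) its mean mutual information
#' with the genes already selected. Ties are broken by input gene order.
#'
#' @param disc integer matrix of discretized expression (genes x samples,
#'   rownames required), e.g. from \code{\link{discretizeExpression}}.
#' @param labels two-class factor, one label per sample.
#' @param nTop number of genes to rank (truncated to the gene count with a
#'   warning if larger).
#' @param scheme \code{"MIQ"} (quotient) or \code{"MID"} (difference).
#' @return Character vector of gene names in selection order.
#' @export
mrmrRank <- function(disc, labels, nTop, scheme = c("MIQ", "MID")) {
    scheme <- match.arg(scheme)
    stopifnot(is.matrix(disc), !is.null(rownames(disc)))
    labels <- factor(labels)
    if (nlevels(labels) != 2L)
        stop("labels must contain exactly two classes")
    if (ncol(disc) != length(labels))
        stop("one label per sample column required")
    nGenes <- nrow(disc)
    if (nTop > nGenes) {
        warning("nTop exceeds the gene count; truncating to ", nGenes)
        nTop <- nGenes
    }
    codes <- disc + 2L  # states -1/0/1 -> 1..3
    yi <- as.integer(labels)
    relevance <- vapply(seq_len(nGenes), function(g)
        miCoded(codes[g, ], 3L, yi, 2L), numeric(1))

    selected <- integer(nTop)
    selected[1L] <- which.max(relevance)
    redSum <- numeric(nGenes)
    isSel <- logical(nGenes)
    isSel[selected[1L]] <- TRUE
    if (nTop > 1L) {
        for (step in 2:nTop) {
            last <- selected[step - 1L]
            rest <- which(!isSel)
            redSum[rest] <- redSum[rest] + vapply(rest, function(g)
                miCoded(codes[g, ], 3L, codes[last, ], 3L), numeric(1))
            red <- redSum / (step - 1L)
            score <- if (scheme == "MIQ")
                relevance / pmax(red, .Machine$double.eps)
            else relevance - red
            score[isSel] <- -Inf
            nxt <- which.max(score)
            selected[step] <- nxt
            isSel[nxt] <- TRUE
        }
    }
    rownames(disc)[selected]
}

#' Nearest-neighbour leave-one-out accuracy
#'
#' Each sample is predicted as the class of its nearest other sample by
#' Euclidean distance on per-gene standardized expression; the accuracy is
#' the fraction of correctly predicted samples (the jackknife test).
#' Distance ties are resolved toward the smallest sample index.
#'
#' @param x numeric genes x samples matrix (a vector is treated as one
#'   gene).
#' @param labels factor of class labels, one per sample, with at least two
#'   samples per class.
#' @return Accuracy in [0, 1].
#' @examples
#' nnaLoocvAccuracy(matrix(c(0, 1, 10, 11), 1), factor(c("a", "a", "b", "b")))
#' @export
nnaLoocvAccuracy <- function(x, labels) {
    if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
    labels <- factor(labels)
    if (ncol(x) != length(labels))
        stop("one label per sample required")
    if (any(table(labels) < 2L))
        stop("each class needs at least 2 samples")
    z <- rowStandardize(x)
    d <- as.matrix(stats::dist(t(z)))
    diag(d) <- Inf
    nn <- max.col(-d, ties.method = "first")
    mean(labels[nn] == labels)
}

#' Incremental feature selection over an mRMR ranking
#'
#' Evaluates the nearest-neighbour LOOCV accuracy of every prefix of the
#' ranked gene list (k = 1..maxK) and returns the accuracy curve together
#' with the optimal prefix — the smallest k attaining the maximum
#' accuracy (parsimony tie-break).
#'
#' @param ranked character vector of genes in mRMR order.
#' @param x numeric genes x samples expression matrix containing at least
#'   the ranked genes.
#' @param labels two-class factor, one label per sample.
#' @param maxK largest prefix evaluated (default: all ranked genes).
#' @param contrast character(2) recorded in the result (the two stages
#'   compared).
#' @return A \linkS4class{BiomarkerSet}.
#' @export
ifsSelect <- function(ranked, x, labels, maxK = length(ranked),
                      contrast = c("A", "B")) {
    stopifnot(length(ranked) >= 1L, maxK >= 1L, maxK <= length(ranked))
    labels <- factor(labels)
    z <- rowStandardize(x[ranked, , drop = FALSE])
    n <- ncol(z)
    acc <- numeric(maxK)
    d2 <- matrix(0, n, n)
    for (k in seq_len(maxK)) {
        v <- z[k, ]
        d2 <- d2 + outer(v, v, "-")^2
        dk <- d2
        diag(dk) <- Inf
        nn <- max.col(-dk, ties.method = "first")
        acc[k] <- mean(labels[nn] == labels)
    }
    new("BiomarkerSet", contrast = as.character(contrast),
        rankedGenes = as.character(ranked), curve = acc,
        optimalK = which.max(acc))
}

#' Select stage biomarkers from a cohort
#'
#' Runs the full biomarker selection for one stage contrast: subset the
#' cohort to the two stages, discretize (mean +/- kSd population SD,
#' ternary), rank genes by mRMR, and pick the optimal prefix by
#' incremental feature selection under nearest-neighbour LOOCV.
#' The early contrast compares Dukes A vs B, the late contrast C vs D.
#'
#' @param cohort a \linkS4class{StageCohort}.
#' @param contrast \code{"early"} (A vs B) or \code{"late"} (C vs D).
#' @param kSd discretization threshold in SD units.
#' @param scheme mRMR scheme, \code{"MIQ"} or \code{"MID"}.
#' @param maxK largest prefix evaluated by IFS; defaults to
#'   \code{min(500, nGenes)}.
#' @return A \linkS4class{BiomarkerSet}.
#' @export
selectBiomarkers <- function(cohort, contrast = c("early", "late"),
                             kSd = 1, scheme = c("MIQ", "MID"),
                             maxK = NULL) {
    contrast <- match.arg(contrast)
    scheme <- match.arg(scheme)
    st <- if (contrast == "early") c("A", "B") else c("C", "D")
    stage <- stageOf(cohort)
    for (s in st) {
        if (sum(stage == s) < 2L)
            stop("the ", contrast, " contrast (", st[1L], " vs ", st[2L],
                 ") needs at least 2 stage-", s, " samples; found ",
                 sum(stage == s))
    }
    cols <- stage %in% st
    x <- exprValues(cohort)[, cols, drop = FALSE]
    labels <- droplevels(factor(stage[cols], levels = st))
    maxK <- maxK %||% min(500L, nrow(x))
    maxK <- min(maxK, nrow(x))
    disc <- suppressMessages(discretizeExpression(x, kSd))
    ranked <- mrmrRank(disc, labels, nTop = maxK, scheme = scheme)
    ifsSelect(ranked, x, labels, maxK = length(ranked), contrast = st)
}
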