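test_that("ternary discretization uses mean +/- k population SD with strict bounds", {
    # mean 2.5, population SD 4.33: only 10 exceeds mean + SD
    expect_equal(discretizeExpression(c(0, 0, 0, 10)), c(0L, 0L, 0L, 1L))
    # constant vector -> all zeros, reported
    expect_message(out <- discretizeExpression(c(3, 3, 3, 3)), "constant")
    expect_equal(out, c(0L, 0L, 0L, 0L))
    # boundary values map to state 0 (strict inequalities): mean 0, SD 10
    expect_equal(discretizeExpression(c(-10, 10)), c(0L, 0L))
    # asymmetric case with clear exceedance on both sides
    v <- c(-10, 0, 0, 0, 0, 10)
    m <- mean(v); s <- sqrt(mean((v - m)^2))
    expect_equal(discretizeExpression(v),
                 ifelse(v > m + s, 1L, ifelse(v < m - s, -1L, 0L)))
    # matrix input is row-wise and keeps dimnames
    x <- rbind(a = c(0, 0, 0, 10), b = c(5, 5, 5, 5))
    expect_message(d <- discretizeExpression(x), "1 constant")
    expect_equal(d["a", ], c(0L, 0L, 0L, 1L), ignore_attr = TRUE)
    expect_equal(d["b", ], rep(0L, 4), ignore_attr = TRUE)
})

test_that("plug-in mutual information matches hand-derived values", {
    x <- rep(c(0, 1), each = 4)
    expect_equal(mutualInformation(x, x), log(2))           # MI(x,x) = H(x)
    expect_equal(mutualInformation(x, rep(7, 8)), 0)        # constant partner
    expect_equal(mutualInformation(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)  # independent
    # a 3-state self-MI equals its entropy
    y <- c(-1, -1, 0, 0, 0, 1)
    p <- table(y) / length(y)
    expect_equal(mutualInformation(y, y), -sum(p * log(p)))
    expect_error(mutualInformation(1:3, 1:4), "equal length")
})

test_that("mRMR ranking matches a brute-force greedy oracle", {
    for (seed in 1:12) {
        set.seed(seed)
        nG <- 6; n <- 14
        disc <- matrix(sample(c(-1L, 0L, 1L), nG * n, replace = TRUE), nG, n,
                       dimnames = list(sprintf("g%d", 1:nG), NULL))
        labels <- factor(rep(c("x", "y"), length.out = n))
        for (scheme in c("MIQ", "MID")) {
            expect_equal(mrmrRank(disc, labels, nTop = nG, scheme = scheme),
                         mrmrOracle(disc, labels, nTop = nG, scheme = scheme),
                         info = paste("seed", seed, scheme))
        }
    }
})

test_that("a perfectly label-predictive gene is ranked first", {
    recovered <- vapply(1:50, function(seed) {
        set.seed(seed)
        n <- 24
        labels <- factor(rep(c("a", "b"), each = n / 2))
        disc <- rbind(marker = ifelse(labels == "a", -1L, 1L),
                      matrix(sample(c(-1L, 0L, 1L), 9 * n, replace = TRUE),
                             9, n, dimnames = list(sprintf("noise%d", 1:9), NULL)))
        mrmrRank(disc, labels, nTop = 1)[1] == "marker"
    }, logical(1))
    expect_true(all(recovered))
})

test_that("an exact duplicate of the top gene is demoted by redundancy", {
    labels <- factor(rep(c("a", "b"), each = 6))
    # g1 nearly predicts the labels (one flip); g2 is an exact copy of g1;
    # g3 is weaker but carries information g1 does not duplicate
    g1 <- c(-1L, -1L, -1L, -1L, -1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L)
    g3 <- c(-1L, -1L, 0L, 0L, 0L, -1L, 1L, 1L, 0L, 0L, 0L, 1L)
    disc <- rbind(g1 = g1, g2 = g1, g3 = g3,
                  g4 = rep(c(0L, 1L, -1L), 4))
    for (scheme in c("MIQ", "MID")) {
        ranked <- mrmrRank(disc, labels, nTop = 4, scheme = scheme)
        expect_equal(ranked[1], "g1")
        expect_false(ranked[2] == "g2")
        expect_equal(ranked, mrmrOracle(disc, labels, 4, scheme))
    }
})

test_that("nTop beyond the gene count truncates with a warning", {
    disc <- rbind(g1 = c(-1L, -1L, 1L, 1L), g2 = c(0L, 1L, 0L, 1L))
    expect_warning(r <- mrmrRank(disc, factor(c("a", "a", "b", "b")), nTop = 5),
                   "truncat")
    expect_length(r, 2)
})

test_that("nearest-neighbour LOOCV accuracy is exact on hand-traced fixtures", {
    # [0,1,10,11]: each sample's nearest other sample shares its class
    expect_equal(nnaLoocvAccuracy(matrix(c(0, 1, 10, 11), 1),
                                  factor(c("a", "a", "b", "b"))), 1.0)
    # two well-separated 2-gene clusters
    x <- cbind(c(0, 0), c(0.2, 0.1), c(5, 5), c(5.2, 5.1))
    expect_equal(nnaLoocvAccuracy(x, factor(c("a", "a", "b", "b"))), 1.0)
    # hand-traced: [0, 1, 3, 10], labels a a b b.
    # s1->s2 (a, ok); s2->s1 (a, ok); s3->s2 (a, wrong); s4->s3 (b, ok) => 3/4
    expect_equal(nnaLoocvAccuracy(matrix(c(0, 1, 3, 10), 1),
                                  factor(c("a", "a", "b", "b"))), 0.75)
    # exact distance ties resolve to the smallest sample index:
    # values [0, 5, 5, 9], labels a a b b: s1 ties s2/s3 -> s2 (a, ok);
    # s2->s3 at distance 0 (b, wrong); s3->s2 (a, wrong);
    # s4 ties s2/s3 at distance 4 -> s2 (a, wrong) => 1/4
    expect_equal(nnaLoocvAccuracy(matrix(c(0, 5, 5, 9), 1),
                                  factor(c("a", "a", "b", "b"))), 0.25)
})

test_that("label-independent features give near-chance LOOCV accuracy", {
    set.seed(42)
    acc <- replicate(200, {
        x <- matrix(rnorm(30), 1)
        nnaLoocvAccuracy(x, factor(sample(rep(c("a", "b"), 15))))
    })
    # P(nearest neighbour shares the label) = (n/2 - 1)/(n - 1) = 14/29
    expect_gt(mean(acc), 0.40)
    expect_lt(mean(acc), 0.57)
})

test_that("accuracy is invariant to sample and gene reordering", {
    set.seed(7)
    x <- matrix(rnorm(5 * 16), 5, 16,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:16)))
    labels <- factor(rep(c("a", "b"), 8))
    a0 <- nnaLoocvAccuracy(x, labels)
    ord <- sample(16)
    expect_equal(nnaLoocvAccuracy(x[, ord], labels[ord]), a0)
    expect_equal(nnaLoocvAccuracy(x[sample(5), ], labels), a0)
})

test_that("IFS curve equals from-scratch LOOCV at every prefix", {
    set.seed(11)
    x <- matrix(rnorm(8 * 20), 8, 20,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:20)))
    labels <- factor(rep(c("a", "b"), 10))
    ranked <- paste0("g", sample(8))
    bs <- ifsSelect(ranked, x, labels)
    expect_equal(length(ifsCurve(bs)), 8)
    for (k in seq_len(8)) {
        expect_equal(ifsCurve(bs)[k],
                     nnaLoocvAccuracy(x[ranked[1:k], , drop = FALSE], labels),
                     info = paste("prefix", k))
    }
    expect_equal(optimalK(bs), which.max(ifsCurve(bs)))
    expect_equal(optimalGenes(bs), ranked[seq_len(optimalK(bs))])
})

test_that("IFS ties resolve to the smallest prefix", {
    # both genes separate the classes perfectly: accuracy 1 at k = 1 and 2
    x <- rbind(g1 = c(0, 1, 10, 11), g2 = c(0, 2, 9, 11))
    labels <- factor(c("a", "a", "b", "b"))
    bs <- ifsSelect(c("g1", "g2"), x, labels)
    expect_equal(ifsCurve(bs), c(1, 1))
    expect_equal(optimalK(bs), 1L)
    # maxK = 1 reduces to the top-ranked gene
    bs1 <- ifsSelect(c("g1", "g2"), x, labels, maxK = 1)
    expect_equal(optimalGenes(bs1), "g1")
})

test_that("selectBiomarkers runs the documented contrasts and errors on missing stages", {
    cohort <- makeCohortFixture(nGenes = 15, seed = 3)
    bs <- selectBiomarkers(cohort, "early", maxK = 10)
    expect_s4_class(bs, "BiomarkerSet")
    expect_equal(contrastStages(bs), c("A", "B"))
    expect_true(all(optimalGenes(bs) %in% rownames(cohort)))

    noD <- makeCohortFixture(nPerStage = c(A = 4, B = 4, C = 4, D = 1), seed = 3)
    expect_error(selectBiomarkers(noD, "late"), "stage-D")
})
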