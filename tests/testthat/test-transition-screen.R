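# a hand-built instance: 2 early, 2 late genes, one planted pair E1-L1
# joined by a short corridor E1-T1-L1 and strongly co-expressed in B/C
makeScreenFixture <- function(seed = 1, rho = 0.95) {
    set.seed(seed)
    nPer <- c(A = 6, B = 12, C = 12, D = 6)
    n <- sum(nPer)
    genes <- c("E1", "E2", "L1", "L2", "T1", "X1", "X2")
    m <- matrix(rnorm(length(genes) * n, 8, 1), length(genes), n,
                dimnames = list(genes, sprintf("s%02d", 1:n)))
    stages <- rep(names(nPer), nPer)
    bc <- stages %in% c("B", "C")
    m["L1", bc] <- 8 + rho * (m["E1", bc] - mean(m["E1", bc])) /
        sd(m["E1", bc]) + sqrt(1 - rho^2) * rnorm(sum(bc))
    cohort <- StageCohort(m, stages)
    net <- buildGraph(data.frame(
        protein1 = c("E1", "T1", "E2", "X1", "L2", "E1"),
        protein2 = c("T1", "L1", "X1", "X2", "X2", "E2"),
        score = c(0.95, 0.95, 0.3, 0.3, 0.3, 0.2)))
    list(cohort = cohort, net = net)
}

test_that("mapBiomarkers keeps order and reports losses", {
    net <- makeTriangleNet()
    expect_equal(mapBiomarkers(c("C", "A"), net), c("C", "A"))
    expect_message(m <- mapBiomarkers(c("A", "Z1", "B"), net), "1 of 3")
    expect_equal(m, c("A", "B"))
    expect_warning(expect_message(mapBiomarkers(c("Z1", "Z2"), net)),
                   "no biomarkers")
})

test_that("pearsonTest agrees with cor.test and handles degenerate input", {
    x <- 1:10
    pt <- pearsonTest(x, 2 * x + 1)
    expect_equal(pt$r, 1)
    expect_lt(pt$p, 1e-12)

    set.seed(2)
    a <- rnorm(30)
    resid <- rnorm(30)
    ac <- a - mean(a)
    b <- resid - ac * sum(ac * resid) / sum(ac * ac)  # orthogonalized residual
    ptOrth <- pearsonTest(a, b)
    expect_equal(ptOrth$r, 0, tolerance = 1e-10)
    expect_equal(ptOrth$p, 1, tolerance = 1e-8)

    y <- rnorm(30)
    ct <- cor.test(a, y)
    mine <- pearsonTest(a, y)
    expect_equal(mine$r, unname(ct$estimate))
    expect_equal(mine$p, ct$p.value)
    # the closed form used by the vectorized screen matches cor.test
    expect_equal(pearsonPFromR(mine$r, 30), ct$p.value)

    expect_warning(out <- pearsonTest(rep(1, 5), rnorm(5)), "constant")
    expect_true(is.na(out$r))
})

test_that("BH adjustment matches the hand-applied step-up oracle", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_equal(bhAdjust(rep(0.05, 4)), rep(0.05, 4))
    expect_equal(bhAdjust(numeric(0)), numeric(0))
    expect_error(bhAdjust(c(0.1, 0)), "0, 1")
    set.seed(9)
    for (i in 1:20) {
        p <- runif(sample(1:40, 1))
        expect_equal(bhAdjust(p), bhOracle(p))
    }
})

test_that("the dual criterion retains exactly the planted pair", {
    fx <- makeScreenFixture()
    paths <- suppressMessages(screenTransitions(
        fx$net, c("E1", "E2"), c("L1", "L2"), fx$cohort))
    expect_equal(nrow(paths), 1)
    expect_equal(paths$early, "E1")
    expect_equal(paths$late, "L1")
    expect_equal(paths$length, 100)   # two 0.95 edges
    expect_equal(paths$path, paste(c("E1", "T1", "L1"), collapse = ARROW))
    expect_gt(paths$r, 0.8)
    expect_lt(paths$fdr, 0.001)
    expect_equal(transitionGenes(paths), list("T1"))

    sm <- S4Vectors::metadata(paths)$summary
    expect_equal(sm$nPairsTested, 4L)
    expect_equal(sm$nPathsRetained, 1L)
    expect_equal(sm$nEarlyLinked, 1L)
    expect_equal(sm$nLateLinked, 1L)
})

test_that("a zero length cutoff retains nothing", {
    fx <- makeScreenFixture()
    paths <- suppressMessages(screenTransitions(
        fx$net, c("E1", "E2"), c("L1", "L2"), fx$cohort, lengthCutoff = 0))
    expect_equal(nrow(paths), 0)
})

test_that("screening is monotone in both cutoffs and order-invariant", {
    cfg <- simulationConfig(nGenes = 60, nPerStage = c(A = 8, B = 15, C = 15, D = 8),
                            nEarlyMarkers = 6, nLateMarkers = 6, effectSize = 2,
                            nPlantedPaths = 3, pathRho = 0.8,
                            networkNNodes = 60, networkMeanDegree = 5,
                            unmappedFraction = 0, seed = 21)
    sim <- simulateCohort(cfg)
    net <- simulateNetwork(cfg, sim$truth)
    e <- intersect(earlyMarkers(sim$truth), nodeNames(net))
    l <- intersect(lateMarkers(sim$truth), nodeNames(net))
    strict <- suppressMessages(screenTransitions(net, e, l, sim$cohort,
                                                 300, 0.001))
    loose <- suppressMessages(screenTransitions(net, e, l, sim$cohort,
                                                500, 0.05))
    expect_true(all(pairKey(strict$early, strict$late) %in%
                    pairKey(loose$early, loose$late)))

    shuffled <- suppressMessages(screenTransitions(net, rev(e), sample(l),
                                                   sim$cohort, 300, 0.001))
    expect_setequal(pairKey(strict$early, strict$late),
                    pairKey(shuffled$early, shuffled$late))
})

test_that("BH is applied once across the whole tested family", {
    fx <- makeScreenFixture()
    # retain-all cutoffs expose the full family in the output table
    all <- suppressMessages(screenTransitions(
        fx$net, c("E1", "E2"), c("L1", "L2"), fx$cohort,
        lengthCutoff = Inf, fdrCutoff = 1.1))
    reachable <- is.finite(all$length)
    expect_equal(all$fdr, bhOracle(all$p))
    expect_true(all(all$fdr >= all$p))
})

test_that("self-pairs and missing stages are handled", {
    fx <- makeScreenFixture()
    # a gene sitting in both biomarker sets is never paired with itself
    both <- suppressMessages(screenTransitions(
        fx$net, c("E1", "L1"), c("L1", "L2"), fx$cohort,
        lengthCutoff = Inf, fdrCutoff = 1.1))
    expect_false(any(both$early == both$late))
    expect_equal(S4Vectors::metadata(both)$summary$nPairsTested, 3L)

    onlyAB <- makeCohortFixture(nPerStage = c(A = 6, B = 6, C = 6, D = 6))
    m <- exprValues(onlyAB)[, stageOf(onlyAB) %in% c("A", "B")]
    noBC <- StageCohort(m, rep(c("A", "D"), each = 6))
    expect_error(screenTransitions(fx$net, "E1", "L1", noBC), "stage-B")
})

test_that("interior nodes always exclude the endpoints", {
    cfg <- simulationConfig(nGenes = 60, nPerStage = c(A = 8, B = 15, C = 15, D = 8),
                            nEarlyMarkers = 6, nLateMarkers = 6, effectSize = 2,
                            nPlantedPaths = 3, pathRho = 0.9,
                            networkNNodes = 60, networkMeanDegree = 5,
                            unmappedFraction = 0, seed = 4)
    sim <- simulateCohort(cfg)
    net <- simulateNetwork(cfg, sim$truth)
    paths <- suppressMessages(screenTransitions(
        net, intersect(earlyMarkers(sim$truth), nodeNames(net)),
        intersect(lateMarkers(sim$truth), nodeNames(net)),
        sim$cohort, lengthCutoff = Inf, fdrCutoff = 1.1))
    tg <- transitionGenes(paths)
    for (i in seq_len(nrow(paths))) {
        expect_false(paths$early[i] %in% tg[[i]])
        expect_false(paths$late[i] %in% tg[[i]])
    }
})
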