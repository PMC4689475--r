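test_that("phi edges match hand-computed 2x2-table values", {
    # perfect inhibition
    x <- makeReports(cbind(joy = c(1, 1, 0, 0), anxiety = c(0, 0, 1, 1)))
    W <- as.matrix(phiMatrix(x))
    expect_equal(W["joy", "anxiety"], -1)
    # n11*n00 - n10*n01 = 1 - 1 = 0
    x2 <- makeReports(cbind(joy = c(1, 0, 1, 0), anxiety = c(1, 0, 0, 1)))
    expect_equal(as.matrix(phiMatrix(x2))["joy", "anxiety"], 0)
    expect_error(phiMatrix(makeReports(cbind(joy = 1))), "at least 2")
})

test_that("constant indicators are masked, not propagated as NA", {
    x <- makeReports(cbind(joy = c(1, 0, 1), anxiety = c(1, 1, 1)))
    W <- phiMatrix(x)
    expect_equal(as.matrix(W)["anxiety", "joy"], 0)
    expect_true(edgeMask(W)["anxiety", "joy"])
    expect_false(edgeMask(W)["joy", "anxiety"] &&
                 !edgeMask(W)["anxiety", "joy"])  # mask symmetric
    dc <- degreeCentrality(W)
    expect_true(all(is.finite(dc)))
})

test_that("phi matrix equals the 2x2-table oracle on random datasets", {
    set.seed(19)
    for (rep in 1:50) {
        x <- randomReports(n = sample(10:40, 1), p = runif(1, 0.1, 0.6))
        W <- as.matrix(phiMatrix(x))
        ind <- indicators(x)
        for (pair in list(c(1, 2), c(3, 17), c(6, 11))) {
            o <- phi2x2(ind[, pair[1]], ind[, pair[2]])
            if (is.na(o)) o <- 0
            expect_equal(W[pair[1], pair[2]], o, tolerance = 1e-12)
        }
    }
})

test_that("phi matrix is invariant under report permutation", {
    set.seed(23)
    x <- randomReports(n = 40, p = 0.3)
    perm <- sample(nReports(x))
    expect_equal(as.matrix(phiMatrix(x)), as.matrix(phiMatrix(x[, perm])))
})

test_that("degree centrality sums absolute incident weights", {
    tax3 <- emotionTaxonomy(positive = c("A", "B"), negative = "C")
    W3 <- matrix(c(0, 0.5, -0.3,
                   0.5, 0, 0,
                   -0.3, 0, 0), 3, 3, byrow = TRUE,
                 dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    dc <- degreeCentrality(weightMatrix(W3, tax3))
    expect_equal(unname(dc), c(0.8, 0.5, 0.3))
    expect_equal(unname(degreeCentrality(weightMatrix(matrix(0, 18, 18)))),
                 rep(0, 18))
})

test_that("degree centrality equals a double-loop oracle and respects its bound", {
    set.seed(29)
    for (rep in 1:20) {
        x <- randomReports(n = 30, p = runif(1, 0.2, 0.5))
        W <- phiMatrix(x)
        dc <- degreeCentrality(W)
        expect_equal(dc, dcDoubleLoop(as.matrix(W)), tolerance = 1e-12)
        expect_true(all(dc <= 17 + 1e-12))
    }
})

test_that("typology follows the strong-edge rule on the 4-emotion toy", {
    W <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    W["A", "B"] <- W["B", "A"] <- 0.4
    W["A", "C"] <- W["C", "A"] <- -0.3
    W["C", "D"] <- W["D", "C"] <- 0.3
    typ <- classifyTypology(weightMatrix(W, tax4()), tau = 0.1)
    expect_equal(unname(typologyLabels(typ)[LETTERS[1:4]]),
                 c("connector", "provincial", "connector", "provincial"))
    # zero matrix: everything distal
    typ0 <- classifyTypology(weightMatrix(matrix(0, 4, 4), tax4()))
    expect_true(all(typologyLabels(typ0) == "distal"))
    expect_error(classifyTypology(weightMatrix(W, tax4()), tau = 0),
                 "positive")
    # an emotion with only opposite-valence strong edges files as distal
    W2 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    W2["A", "C"] <- W2["C", "A"] <- -0.5
    expect_message(t2 <- classifyTypology(weightMatrix(W2, tax4()), 0.1),
                   "opposite-valence")
    expect_equal(unname(typologyLabels(t2)["A"]), "distal")
})

test_that("typology is invariant under within-valence relabelling", {
    set.seed(41)
    x <- randomReports(n = 200, p = 0.3)
    W <- as.matrix(phiMatrix(x))
    typ <- typologyLabels(classifyTypology(phiMatrix(x), tau = 0.08))
    tax <- emotionTaxonomy()
    permPos <- sample(positiveEmotions(tax))
    permNeg <- sample(negativeEmotions(tax))
    perm <- c(permPos, permNeg)
    Wp <- W[perm, perm]
    typP <- typologyLabels(classifyTypology(
        weightMatrix(Wp, emotionTaxonomy(permPos, permNeg)), tau = 0.08))
    expect_identical(typP[perm], typ[perm])
})

test_that("generator-built couplings produce the expected types", {
    tax <- emotionTaxonomy()
    R <- diag(18); dimnames(R) <- list(emotions(tax), emotions(tax))
    R["joy", "satisfaction"] <- R["satisfaction", "joy"] <- 0.6
    R["joy", "sadness"] <- R["sadness", "joy"] <- -0.5
    cfg <- syntheticConfig(nParticipants = 1500, promptMean = 20,
                           latentCorr = R, sigmaU = 0, seed = 37)
    x <- generateDataset(cfg)
    typ <- typologyLabels(classifyTypology(phiMatrix(x), tau = 0.1))
    expect_equal(unname(typ["joy"]), "connector")
    expect_equal(unname(typ["satisfaction"]), "provincial")
    expect_equal(unname(typ["contempt"]), "distal")
})

test_that("paired centrality comparison matches hand computation", {
    eq <- setNames(c(1, 2, 3), c("a", "b", "c"))
    cmp0 <- compareCentrality(eq, eq)
    expect_equal(cmp0$t, 0); expect_equal(cmp0$cohens_d, 0)
    # diffs (1,1,2): t = (4/3)/(sd/sqrt(3)) = 4, df = 2, d = 2.309
    cmp <- compareCentrality(setNames(c(2, 3, 5), c("a", "b", "c")), eq)
    expect_equal(cmp$t, 4, tolerance = 1e-6)
    expect_equal(cmp$df, 2)
    expect_equal(cmp$cohens_d, 4 / sqrt(3), tolerance = 1e-6)
    # constant nonzero difference is degenerate
    cmpD <- compareCentrality(eq + 1, eq)
    expect_true(cmpD$degenerate)
})

test_that("group comparison sign tracks the constructed difference", {
    tax <- emotionTaxonomy()
    mk <- function(within, seed) generateDataset(syntheticConfig(
        nParticipants = 800, promptMean = 15,
        latentCorr = defaultLatentCorr(tax, within = within, between = -0.1),
        sigmaU = 0, seed = seed))
    dcStrong <- degreeCentrality(phiMatrix(mk(0.55, 71)))
    dcWeak <- degreeCentrality(phiMatrix(mk(0.15, 72)))
    cmp <- compareCentrality(dcStrong, dcWeak)
    expect_gt(cmp$t, 0)
    expect_lt(cmp$p, 0.05)
})

test_that("frequency-centrality correlation uses the Fisher z interval", {
    dc <- setNames(seq(0.5, 2.2, length.out = 18), emotions(emotionTaxonomy()))
    cor1 <- frequencyCentralityCorrelation(3 * dc, dc)
    expect_equal(cor1$r, 1)
    corm <- frequencyCentralityCorrelation(-2 * dc + 5, dc)
    expect_equal(corm$r, -1)
    # construct vectors with cor exactly 0.39 and check the closed-form CI
    set.seed(13)
    xs <- as.numeric(scale(1:18))
    e <- residuals(lm(rnorm(18) ~ xs))
    ys <- 0.39 * xs + sqrt(1 - 0.39^2) * as.numeric(scale(e))
    fc <- frequencyCentralityCorrelation(setNames(ys, names(dc)),
                                         setNames(xs, names(dc)))
    expect_equal(fc$r, 0.39, tolerance = 1e-10)
    zci <- tanh(atanh(0.39) + c(-1, 1) * qnorm(0.975) / sqrt(15))
    expect_equal(c(fc$ci_low, fc$ci_high), zci, tolerance = 1e-6)
    expect_warning(frequencyCentralityCorrelation(dc * 0 + 1, dc),
                   "constant")
})

test_that("co-occurrence counts and opposite-valence rates are correct", {
    ind <- cbind(joy = c(1, 1, 1, 1, 0, 0, 0, 0, 1, 0),
                 anxiety = c(1, 1, 0, 0, 1, 0, 0, 0, 0, 0))
    x <- makeReports(ind)
    co <- cooccurrenceTable(x)
    expect_equal(co$counts["joy", "anxiety"], 2L)
    expect_equal(co$counts["joy", "joy"], 5L)
    # joy endorsed 5 times, 2 of them with an opposite-valence emotion
    expect_equal(unname(co$opposite_valence_rate["joy"]), 2 / 5)
    expect_equal(unname(co$opposite_valence_rate["anxiety"]), 2 / 3)
    expect_true(all(co$counts["contempt", ] == 0L))
    expect_true(is.nan(co$opposite_valence_rate[["contempt"]]))
})

test_that("positively coupled pairs co-occur above the independence expectation", {
    tax <- emotionTaxonomy()
    R <- diag(18); dimnames(R) <- list(emotions(tax), emotions(tax))
    R["joy", "anxiety"] <- R["anxiety", "joy"] <- 0.5
    cfg <- syntheticConfig(nParticipants = 1000, promptMean = 20,
                           latentCorr = R, sigmaU = 0, seed = 43)
    x <- generateDataset(cfg)
    co <- cooccurrenceTable(x)
    n <- nReports(x)
    p <- defaultPrevalence()
    expected <- n * p["joy"] * p["anxiety"]
    sdInd <- sqrt(expected * (1 - p["joy"] * p["anxiety"]))
    expect_gt(co$counts["joy", "anxiety"], expected + 3 * sdInd)
})
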