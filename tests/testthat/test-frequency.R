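test_that("balanced two-participant design recovers the grand mean", {
    x <- makeReports(cbind(joy = c(1, 1, 1, 0)),
                     pid = c("a", "a", "b", "b"))
    est <- estimateFrequency(x, "joy")
    expect_equal(est$estimate, 75, tolerance = 1e-6)
    expect_equal(est$n_participants, 2L)
    expect_true(est$ci_low <= 75 && est$ci_high >= 75)
})

test_that("degenerate and single-participant inputs are handled and flagged", {
    # every report endorses an emotion -> any = 100%, CI pinned at 100
    x <- makeReports(cbind(joy = rep(1, 6)), pid = rep(c("a", "b", "c"), 2))
    est <- estimateFrequency(x, "any")
    expect_equal(est$estimate, 100)
    expect_equal(est$ci_high, 100)
    # single participant: binomial fallback CI, flagged
    x1 <- makeReports(cbind(joy = c(1, 0, 1, 1)), pid = rep("solo", 4))
    est1 <- estimateFrequency(x1, "joy")
    expect_match(est1$ci_method, "single-participant")
    expect_equal(est1$estimate, 75)
    expect_true(est1$ci_low < 75 && est1$ci_high > 75)
})

test_that("frequency table has 22 rows in the conventional layout", {
    set.seed(12)
    x <- randomReports(n = 80, p = 0.2)
    tab <- frequencyTable(x, method = "pooled")
    expect_equal(nrow(tab), 22L)            # 18 emotions + 3 categories + any
    expect_equal(sum(tab$type == "emotion"), 18L)
    emoRows <- tab$estimate[tab$type == "emotion"]
    expect_true(all(diff(emoRows) <= 1e-12)) # descending
    expect_identical(tab$target[19:22],
                     c("positive_only", "negative_only", "mixed", "any"))
})

test_that("an all-zero dataset yields zero frequencies everywhere", {
    x <- makeReports(cbind(joy = rep(0, 8)), pid = rep(c("a", "b"), 4))
    tab <- frequencyTable(x, method = "pooled")
    expect_true(all(tab$estimate == 0))
    expect_true(all(categorizeReports(x) == "none"))
})

test_that("any-emotion frequency matches independence closed form", {
    p <- defaultPrevalence()
    cfg <- syntheticConfig(nParticipants = 5000, promptMean = 20,
                           promptDispersion = Inf, latentCorr = diag(18),
                           sigmaU = 0, seed = 31)
    x <- generateDataset(cfg)                    # ~1e5 reports
    anyHat <- mean(.rowSums(indicators(x), nReports(x), 18) > 0)
    expect_lt(abs(anyHat - (1 - prod(1 - p))), 0.005)
})

test_that("positive/negative ratio matches hand-built category counts", {
    ind <- cbind(joy = rep(c(1, 0, 1, 0), c(41, 16, 33, 10)),
                 anxiety = rep(c(0, 1, 1, 0), c(41, 16, 33, 10)))
    x <- makeReports(ind, pid = sprintf("p%02d", rep(1:10, 10)))
    expect_equal(positiveNegativeRatio(x), 41 / 16)   # 2.5625
    ind2 <- cbind(joy = c(1, 0), anxiety = c(0, 1))
    expect_equal(positiveNegativeRatio(makeReports(ind2)), 1.0)
    x0 <- makeReports(cbind(joy = c(1, 0)))
    expect_warning(r <- positiveNegativeRatio(x0), "undefined")
    expect_true(is.na(r))
})

test_that("temporal profiles bin, filter and warn as specified", {
    x <- makeReports(cbind(joy = rep(1, 5)), hours = rep(9, 5))
    prof <- temporalProfile(x, "joy", "hour", minReports = 1)
    expect_equal(prof$bin, 9L)
    expect_equal(prof$frequency, 1.0)
    # reports at 3 AM only fall outside the default 6-22 window
    x3 <- makeReports(cbind(joy = rep(1, 5)), hours = rep(3, 5))
    expect_warning(p3 <- temporalProfile(x3, "joy", "hour", minReports = 1),
                   "no bins")
    expect_equal(nrow(p3), 0L)
    # bins below the report floor are absent
    xm <- makeReports(cbind(joy = rep(1, 10)),
                      hours = rep(c(9, 10), c(8, 2)))
    pm <- temporalProfile(xm, "joy", "hour", minReports = 5)
    expect_identical(pm$bin, 9L)
})

test_that("evening-elevated emission shows up as an evening peak", {
    tax <- emotionTaxonomy()
    he <- matrix(0, 24, 18, dimnames = list(NULL, emotions(tax)))
    he[19:23, "joy"] <- 1.2                    # hours 18-22
    hw <- rep(1e-6, 24); hw[c(10, 21)] <- c(1, 1.2)  # hours 9 and 20
    cfg <- syntheticConfig(nParticipants = 800, promptMean = 10,
                           hourWeights = hw, hourEffect = he, seed = 14)
    x <- generateDataset(cfg)
    prof <- temporalProfile(x, "joy", "hour", minReports = 50)
    expect_equal(prof$bin[which.max(prof$frequency)], 20L)
})

test_that("fluctuation magnitude is the mean hourly sample SD", {
    mk <- function(vals) data.frame(bin = seq_along(vals) + 5L,
                                    n = rep(10L, length(vals)),
                                    frequency = vals)
    expect_equal(fluctuationMagnitude(list(a = mk(rep(0.2, 5)))), 0)
    expect_equal(fluctuationMagnitude(list(a = mk(c(0.1, 0.2, 0.3)))), 0.1)
    expect_error(fluctuationMagnitude(list(a = mk(0.1))), "2 bins")
    expect_error(fluctuationMagnitude(list(a = mk(c(.1, .2)),
                                           b = mk(c(.1, .2, .3)))),
                 "same bins")
})

test_that("sinusoidal positive emission fluctuates more than flat negative", {
    tax <- emotionTaxonomy()
    he <- matrix(0, 24, 18, dimnames = list(NULL, emotions(tax)))
    hrs <- 0:23
    for (e in positiveEmotions(tax))
        he[, e] <- 0.6 * sin(2 * pi * (hrs - 6) / 24)
    cfg <- syntheticConfig(nParticipants = 1500, promptMean = 15,
                           hourEffect = he, seed = 26)
    x <- generateDataset(cfg)
    profiles <- lapply(setNames(emotions(tax), emotions(tax)),
                       temporalProfile, x = x, by = "hour", minReports = 100)
    bins <- lapply(profiles, `[[`, "bin")
    common <- Reduce(intersect, bins)
    profiles <- lapply(profiles, function(p) p[p$bin %in% common, ])
    sdPos <- fluctuationMagnitude(profiles, positiveEmotions(tax))
    sdNeg <- fluctuationMagnitude(profiles, negativeEmotions(tax))
    expect_gt(sdPos, sdNeg)
})

test_that("category frequencies are coherent (pooled exact, model close)", {
    set.seed(3)
    for (rep in 1:5) {
        x <- randomReports(n = 60, p = runif(1, 0.05, 0.4))
        cat <- categorizeReports(x)
        pooled <- 100 * c(mean(cat == "positive_only"),
                          mean(cat == "negative_only"),
                          mean(cat == "mixed"), mean(cat == "none"))
        expect_equal(sum(pooled), 100)
        anyP <- estimateFrequency(x, "any", method = "pooled")$pooled
        expect_equal(anyP, 100 - pooled[4])
        # every per-emotion frequency bounded by the any-emotion frequency
        perEmo <- colMeans(indicators(x)) * 100
        expect_true(all(perEmo <= anyP + 1e-12))
    }
    # model-based category estimates stay within 0.5 pp of partitioning
    # (assessed at a scale where the variance components are well estimated)
    x <- generateDataset(syntheticConfig(nParticipants = 3000,
                                         promptMean = 8, seed = 52))
    ests <- vapply(c("positive_only", "negative_only", "mixed", "none"),
                   function(tg) estimateFrequency(x, tg)$estimate, 0)
    expect_lt(abs(sum(ests) - 100), 0.5)
})

test_that("estimates recover generator prevalences within 3 SEs", {
    cfg <- syntheticConfig(nParticipants = 500, promptMean = 20,
                           promptDispersion = Inf, seed = 61)
    x <- generateDataset(cfg)
    p <- defaultPrevalence()
    for (e in c("joy", "anxiety", "contempt")) {
        est <- estimateFrequency(x, e)
        se <- sqrt(p[e] * (1 - p[e]) / nReports(x))
        expect_lt(abs(est$estimate / 100 - p[e]), 3 * se + 0.01)
    }
})
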