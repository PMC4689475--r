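.CATEGORIES <- c("positive_only", "negative_only", "mixed", "none")

#' Categorise each report by the valence of its endorsed emotions
#'
#' A report is \code{none} if no emotion is endorsed, \code{positive_only}
#' if it endorses at least one positive and no negative emotion,
#' \code{negative_only} symmetrically, and \code{mixed} if it endorses at
#' least one emotion of each valence simultaneously. The four labels are
#' mutually exclusive and exhaustive.
#'
#' @param x an [EmotionReportSet-class].
#' @param ... unused.
#' @return Factor of length \code{nReports(x)} with levels
#'   \code{positive_only, negative_only, mixed, none}.
#' @name categorizeReports
#' @aliases categorizeReports,EmotionReportSet-method
#' @export
setMethod("categorizeReports", "EmotionReportSet", function(x, ...) {
    tax <- taxonomy(x)
    ind <- assay(x, "indicators")
    pos <- colSums(ind[positiveEmotions(tax), , drop = FALSE]) > 0
    neg <- colSums(ind[negativeEmotions(tax), , drop = FALSE]) > 0
    lab <- ifelse(pos & neg, "mixed",
           ifelse(pos, "positive_only",
           ifelse(neg, "negative_only", "none")))
    factor(lab, levels = .CATEGORIES)
})

.targetVector <- function(x, target) {
    emo <- emotions(taxonomy(x))
    if (target == "any")
        return(as.integer(colSums(assay(x, "indicators")) > 0))
    if (target %in% emo)
        return(as.integer(assay(x, "indicators")[target, ]))
    if (target %in% .CATEGORIES)
        return(as.integer(categorizeReports(x) == target))
    stop("unknown target '", target, "': not an emotion, category or 'any'")
}

.clusterRobustSE <- function(y, pid, phat) {
    # CR0 variance of the pooled mean with a G/(G-1) small-sample factor
    e <- tapply(y - phat, pid, sum)
    G <- length(e)
    sqrt(sum(e^2) / length(y)^2 * G / (G - 1))
}

#' Estimate the frequency of an emotion, category or any emotion
#'
#' Point estimate and 95\% CI of the percentage of reports on which the
#' target is present, honouring the nesting of reports within participants.
#' The default is a random-intercept linear-probability model (equivalently
#' a compound-symmetry / exchangeable working-correlation model) fitted with
#' \pkg{lme4}; Wald CIs on the percentage scale, truncated to [0, 100]. When
#' the participant variance component is estimated at zero the estimate
#' falls back to the pooled proportion with a cluster-robust CI, and with a
#' single participant to an exact binomial CI (flagged in \code{ci_method}).
#' A logit link (\code{glmer}) is available as an option; its estimate is the
#' population-median (conditional) percentage.
#'
#' @param x an [EmotionReportSet-class].
#' @param target an emotion name, one of
#'   \code{"positive_only","negative_only","mixed","none"}, or \code{"any"}.
#' @param method \code{"mixed"} (multilevel model, default) or
#'   \code{"pooled"} (pooled proportion, cluster-robust CI).
#' @param link \code{"identity"} (default) or \code{"logit"}.
#' @param conf confidence level (default 0.95).
#' @return One-row \code{data.frame}: \code{target}, \code{estimate} (pct),
#'   \code{ci_low}, \code{ci_high}, \code{n_reports}, \code{n_participants},
#'   \code{pooled} (pct), \code{ci_method}.
#' @examples
#' cfg <- syntheticConfig(nParticipants = 40, promptMean = 6, seed = 3)
#' x <- generateDataset(cfg)
#' estimateFrequency(x, "joy")
#' @export
estimateFrequency <- function(x, target = "any",
                              method = c("mixed", "pooled"),
                              link = c("identity", "logit"), conf = 0.95) {
    method <- match.arg(method)
    link <- match.arg(link)
    y <- .targetVector(x, target)
    pid <- participantId(x)
    n <- length(y)
    G <- length(unique(pid))
    phat <- mean(y)
    zq <- stats::qnorm(1 - (1 - conf) / 2)
    est <- phat; lo <- hi <- NA_real_; ciMethod <- "pooled-cluster-robust"

    if (G < 2L) {
        bt <- stats::binom.test(sum(y), n, conf.level = conf)
        lo <- bt$conf.int[1]; hi <- bt$conf.int[2]
        ciMethod <- "binomial-single-participant"
    } else if (method == "pooled" || stats::var(y) == 0) {
        if (stats::var(y) == 0) {
            lo <- hi <- phat
            ciMethod <- "degenerate-constant-outcome"
        } else {
            se <- .clusterRobustSE(y, pid, phat)
            lo <- phat - zq * se; hi <- phat + zq * se
        }
    } else if (link == "identity") {
        fit <- suppressMessages(lme4::lmer(
            y ~ 1 + (1 | pid), data = data.frame(y = y, pid = pid),
            REML = TRUE,
            control = lme4::lmerControl(check.conv.singular = "ignore",
                                        calc.derivs = FALSE)))
        if (lme4::isSingular(fit, tol = 1e-5)) {
            se <- .clusterRobustSE(y, pid, phat)
            lo <- phat - zq * se; hi <- phat + zq * se
        } else {
            est <- unname(lme4::fixef(fit)[1])
            se <- sqrt(as.numeric(stats::vcov(fit)[1, 1]))
            lo <- est - zq * se; hi <- est + zq * se
            ciMethod <- "mixed-compound-symmetry"
        }
    } else {
        fit <- suppressMessages(lme4::glmer(
            y ~ 1 + (1 | pid), data = data.frame(y = y, pid = pid),
            family = stats::binomial()))
        b <- unname(lme4::fixef(fit)[1])
        se <- sqrt(as.numeric(stats::vcov(fit)[1, 1]))
        est <- stats::plogis(b)
        lo <- stats::plogis(b - zq * se); hi <- stats::plogis(b + zq * se)
        ciMethod <- "mixed-logit"
    }
    data.frame(target = target,
               estimate = min(100, max(0, 100 * est)),
               ci_low = min(100, max(0, 100 * lo)),
               ci_high = min(100, max(0, 100 * hi)),
               n_reports = n, n_participants = G,
               pooled = 100 * phat, ci_method = ciMethod,
               stringsAsFactors = FALSE)
}

#' Frequency table for all emotions, categories and any-emotion
#'
#' One [estimateFrequency()] row per emotion (18 for the canonical
#' taxonomy), per category (\code{positive_only}, \code{negative_only},
#' \code{mixed}) and for \code{"any"} - 22 rows in all. Emotions are sorted
#' by descending estimate (canonical order breaks ties), followed by the
#' three categories and the any-emotion row, mirroring the conventional
#' table layout for such studies. Both model-based and pooled percentages
#' are reported.
#'
#' @inheritParams estimateFrequency
#' @return \code{data.frame} with a \code{type} column
#'   (\code{emotion}/\code{category}/\code{any}) plus the
#'   [estimateFrequency()] columns.
#' @export
frequencyTable <- function(x, method = c("mixed", "pooled"),
                           link = c("identity", "logit"), conf = 0.95) {
    method <- match.arg(method)
    emo <- emotions(taxonomy(x))
    targets <- c(emo, setdiff(.CATEGORIES, "none"), "any")
    rows <- lapply(targets, estimateFrequency, x = x, method = method,
                   link = link, conf = conf)
    tab <- do.call(rbind, rows)
    tab$type <- rep(c("emotion", "category", "any"),
                    c(length(emo), 3L, 1L))
    iEmo <- seq_along(emo)
    ord <- iEmo[order(-tab$estimate[iEmo], iEmo)]
    tab <- tab[c(ord, length(emo) + 1:4), ]
    rownames(tab) <- NULL
    tab[, c("target", "type", "estimate", "ci_low", "ci_high", "pooled",
            "n_reports", "n_participants", "ci_method")]
}

#' Ratio of positive-only to negative-only report frequencies
#'
#' How many times more often reports are purely positive than purely
#' negative (pooled proportions). Undefined (NA, with a warning) when no
#' report is negative-only.
#'
#' @param x an [EmotionReportSet-class].
#' @return A single number (or \code{NA} if undefined).
#' @export
positiveNegativeRatio <- function(x) {
    cat <- categorizeReports(x)
    posf <- mean(cat == "positive_only")
    negf <- mean(cat == "negative_only")
    if (negf == 0) {
        warning("no negative-only reports: ratio undefined")
        return(NA_real_)
    }
    posf / negf
}

#' Temporal frequency profile by hour of day or weekday
#'
#' Pooled frequency of a target per local-hour bin (floor of the clock hour)
#' or ISO weekday (Monday = 1). Hour bins outside \code{hourRange} and bins
#' with fewer than \code{minReports} reports are excluded: sparsely sampled
#' night hours give unstable estimates, so the default window is 6:00-22:00
#' with a 1,000-report floor (lower the floor for small datasets).
#'
#' @param x an [EmotionReportSet-class].
#' @param target as in [estimateFrequency()].
#' @param by \code{"hour"} or \code{"weekday"}.
#' @param hourRange inclusive hour window, default \code{c(6, 22)}.
#' @param minReports minimum reports per retained bin, default 1000.
#' @return \code{data.frame(bin, n, frequency)} with attributes
#'   \code{target} and \code{by}; empty (with a warning) if no bin survives
#'   filtering.
#' @seealso [fluctuationMagnitude()]
#' @export
temporalProfile <- function(x, target = "any", by = c("hour", "weekday"),
                            hourRange = c(6, 22), minReports = 1000) {
    by <- match.arg(by)
    y <- .targetVector(x, target)
    ts <- reportTime(x)
    bin <- if (by == "hour") as.POSIXlt(ts)$hour
           else as.integer(format(ts, "%u"))
    keep <- rep(TRUE, length(bin))
    if (by == "hour")
        keep <- bin >= hourRange[1] & bin <= hourRange[2]
    n <- tapply(y[keep], bin[keep], length)
    f <- tapply(y[keep], bin[keep], mean)
    ok <- !is.na(n) & n >= minReports
    prof <- data.frame(bin = as.integer(names(n))[ok],
                       n = as.integer(n[ok]),
                       frequency = as.numeric(f[ok]))
    if (nrow(prof) == 0L)
        warning("no bins remain after hour-range/min-report filtering")
    prof <- prof[order(prof$bin), , drop = FALSE]
    rownames(prof) <- NULL
    attr(prof, "target") <- target
    attr(prof, "by") <- by
    prof
}

#' Mean temporal fluctuation magnitude over a set of emotions
#'
#' For each emotion, the sample standard deviation (denominator n-1) of its
#' per-bin frequencies; the statistic is the mean SD over the given emotion
#' set. Used to contrast the diurnal variability of positive vs negative
#' emotions. All profiles must be non-empty and span the same bins.
#'
#' @param profiles named list of [temporalProfile()] outputs, one per
#'   emotion.
#' @param emotionSet character vector naming which profiles to average
#'   (default: all).
#' @return Mean SD (a single number).
#' @export
fluctuationMagnitude <- function(profiles, emotionSet = names(profiles)) {
    profiles <- profiles[emotionSet]
    if (any(vapply(profiles, nrow, 0L) == 0L))
        stop("all profiles must be non-empty")
    bins <- lapply(profiles, `[[`, "bin")
    if (!all(vapply(bins, identical, TRUE, y = bins[[1]])))
        stop("all profiles must span the same bins")
    if (length(bins[[1]]) < 2L)
        stop("at least 2 bins are required to compute an SD")
    mean(vapply(profiles, function(p) stats::sd(p$frequency), 0))
}
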