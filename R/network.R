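#' Construct a WeightMatrix from a plain matrix
#'
#' Wraps a symmetric signed weight matrix (diagonal forced to 0) into a
#' validated [WeightMatrix-class]. Mostly useful for toy networks and for
#' importing externally computed weights; networks estimated from data come
#' from [phiMatrix()].
#'
#' @param W symmetric numeric matrix, |entries| <= 1, one row per taxonomy
#'   emotion (dimnames optional; taxonomy order assumed if absent).
#' @param taxonomy an [EmotionTaxonomy-class].
#' @param nReports number of reports behind the weights (NA if unknown).
#' @param mask optional logical matrix flagging undefined edges.
#' @return A [WeightMatrix-class].
#' @export
weightMatrix <- function(W, taxonomy = emotionTaxonomy(),
                         nReports = NA_integer_, mask = NULL) {
    emo <- emotions(taxonomy)
    if (is.null(dimnames(W))) dimnames(W) <- list(emo, emo)
    W <- W[emo, emo]
    diag(W) <- 0
    if (is.null(mask))
        mask <- matrix(FALSE, nrow(W), ncol(W), dimnames = dimnames(W))
    new("WeightMatrix", W = W, mask = mask,
        nReports = as.integer(nReports), taxonomy = taxonomy)
}

#' Signed phi-correlation network of emotions
#'
#' Builds the weighted undirected emotion network: each edge weight is the
#' Pearson correlation of the two emotions' pooled binary indicator vectors
#' across all reports (the phi coefficient). Positive weights mark emotions
#' that co-occur, negative weights emotions that inhibit one another. The
#' diagonal is 0 by convention; a correlation that is undefined because an
#' indicator is constant in the sample (a rare emotion never endorsed) is
#' stored as 0 and flagged in the mask so centrality remains defined.
#'
#' Weights deliberately pool between- and within-person variation (all
#' reports enter one correlation); \code{centered = TRUE} subtracts each
#' participant's mean indicator first, giving a within-person sensitivity
#' variant. With \code{nPerm > 0}, edges whose |phi| is not exceeded in at
#' most \code{alpha} of report-label permutations are set to 0 (an optional
#' sparsification filter, off by default).
#'
#' @param x an [EmotionReportSet-class] with at least 2 reports.
#' @param centered subtract participant means before correlating
#'   (default \code{FALSE}).
#' @param nPerm number of permutations for the optional edge filter
#'   (default 0 = no filter).
#' @param alpha permutation-filter significance level.
#' @param ... unused.
#' @return A [WeightMatrix-class].
#' @examples
#' x <- generateDataset(syntheticConfig(nParticipants = 100, seed = 2))
#' W <- phiMatrix(x)
#' degreeCentrality(W)
#' @name phiMatrix
#' @aliases phiMatrix,EmotionReportSet-method
#' @export
setMethod("phiMatrix", "EmotionReportSet",
    function(x, centered = FALSE, nPerm = 0, alpha = 0.05, ...) {
    if (nReports(x) < 2L)
        stop("at least 2 reports are required to correlate indicators")
    tax <- taxonomy(x)
    m <- indicators(x) * 1.0
    if (centered) {
        pm <- apply(m, 2, function(col) stats::ave(col, participantId(x)))
        m <- m - pm
    }
    W <- suppressWarnings(stats::cor(m))
    mask <- is.na(W)
    W[mask] <- 0
    diag(W) <- 0
    diag(mask) <- FALSE
    if (nPerm > 0) {
        n <- nrow(m)
        exceed <- matrix(0L, ncol(m), ncol(m))
        for (b in seq_len(nPerm)) {
            mp <- apply(m, 2, sample, size = n)
            Wp <- suppressWarnings(stats::cor(mp))
            Wp[is.na(Wp)] <- 0
            exceed <- exceed + (abs(Wp) >= abs(W))
        }
        keep <- (exceed + 1) / (nPerm + 1) <= alpha
        W[!keep] <- 0
        diag(W) <- 0
    }
    new("WeightMatrix", W = W, mask = mask, nReports = nReports(x),
        taxonomy = tax)
})

#' WeightMatrix accessors
#'
#' \code{as.matrix} extracts the weight matrix; \code{edgeMask} the logical
#' matrix flagging undefined correlations; \code{nReports} the number of
#' reports used; \code{taxonomy} the taxonomy.
#'
#' @param x a [WeightMatrix-class].
#' @param ... unused.
#' @return See description.
#' @name WeightMatrix-accessors
#' @aliases edgeMask as.matrix,WeightMatrix-method
#'   edgeMask,WeightMatrix-method nReports,WeightMatrix-method
#'   taxonomy,WeightMatrix-method
NULL

#' @rdname WeightMatrix-accessors
#' @export
as.matrix.WeightMatrix <- function(x, ...) x@W

setMethod("as.matrix", "WeightMatrix", function(x, ...) x@W)

#' @rdname WeightMatrix-accessors
setMethod("edgeMask", "WeightMatrix", function(x) x@mask)

#' @rdname WeightMatrix-accessors
setMethod("nReports", "WeightMatrix", function(x) x@nReports)

#' @rdname WeightMatrix-accessors
setMethod("taxonomy", "WeightMatrix", function(x) x@taxonomy)

setMethod("show", "WeightMatrix", function(object) {
    k <- nrow(object@W)
    cat("WeightMatrix:", k, "emotions,", k * (k - 1) / 2, "edges, from",
        object@nReports, "reports\n")
    w <- object@W[upper.tri(object@W)]
    cat(sprintf("  weight range: [%.3f, %.3f]; masked edges: %d\n",
                min(w), max(w),
                sum(object@mask[upper.tri(object@mask)])))
})

#' Degree centrality of each emotion
#'
#' The degree centrality (DC) of an emotion is the sum of the absolute
#' weights of all its connections to the other emotions. For a k-emotion
#' network DC is bounded by k-1 (17 for the canonical taxonomy), attained
#' only when the emotion perfectly co-occurs with or perfectly inhibits
#' every other emotion. A high-DC emotion co-occurs with or inhibits other
#' emotions systematically; a low-DC emotion is experienced in relative
#' isolation.
#'
#' @param x a [WeightMatrix-class].
#' @param ... unused.
#' @return Named non-negative numeric vector, one value per emotion.
#' @name degreeCentrality
#' @aliases degreeCentrality,WeightMatrix-method
#' @export
setMethod("degreeCentrality", "WeightMatrix", function(x, ...) {
    rowSums(abs(x@W))
})

#' Classify emotions as connector, provincial or distal
#'
#' Thresholds edge strengths at \code{tau} (an edge is strong iff
#' |weight| >= tau) and labels each emotion: \emph{connector} if it has at
#' least one strong same-valence and one strong opposite-valence edge,
#' \emph{provincial} if it has strong same-valence edges only, and
#' \emph{distal} if it has no strong same-valence edge. An emotion whose
#' only strong edges are opposite-valence is filed as distal and reported
#' via a message. The threshold makes explicit a judgement that is
#' otherwise made by visual inspection of the network; tau = 0.1 by
#' default.
#'
#' @param x a [WeightMatrix-class].
#' @param tau strictly positive edge-strength threshold (default 0.1).
#' @param ... unused.
#' @return An [EmotionTypology-class].
#' @name classifyTypology
#' @aliases classifyTypology,WeightMatrix-method
#' @export
setMethod("classifyTypology", "WeightMatrix", function(x, tau = 0.1, ...) {
    if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
        stop("tau must be a single positive number")
    emo <- emotions(x@taxonomy)
    val <- valence(x@taxonomy)
    strong <- abs(x@W) >= tau
    diag(strong) <- FALSE
    same <- outer(val, val, "==")
    hasSame <- rowSums(strong & same) > 0
    hasOpp <- rowSums(strong & !same) > 0
    lab <- ifelse(hasSame & hasOpp, "connector",
           ifelse(hasSame, "provincial", "distal"))
    onlyOpp <- !hasSame & hasOpp
    if (any(onlyOpp))
        message("emotion(s) with only opposite-valence strong edges filed ",
                "as distal: ", paste(emo[onlyOpp], collapse = ", "))
    new("EmotionTypology", labels = setNames(lab, emo), tau = tau)
})

#' EmotionTypology accessors
#'
#' @param x an [EmotionTypology-class].
#' @return \code{typologyLabels}: named character vector;
#'   \code{typologyTau}: the threshold used.
#' @name EmotionTypology-accessors
#' @aliases typologyLabels typologyTau
#'   typologyLabels,EmotionTypology-method typologyTau,EmotionTypology-method
NULL

#' @rdname EmotionTypology-accessors
setMethod("typologyLabels", "EmotionTypology", function(x) x@labels)

#' @rdname EmotionTypology-accessors
setMethod("typologyTau", "EmotionTypology", function(x) x@tau)

setMethod("show", "EmotionTypology", function(object) {
    cat("EmotionTypology (tau =", object@tau, ")\n")
    for (l in c("connector", "provincial", "distal"))
        cat(sprintf("  %-10s: %s\n", l,
                    paste(names(object@labels)[object@labels == l],
                          collapse = ", ")))
})

#' Paired comparison of two centrality profiles
#'
#' Paired t-test across emotions of two degree-centrality profiles (e.g.,
#' men vs women), with Cohen's d for paired data
#' (mean(diff) / SD(diff)). With 18 emotions the test has 17 degrees of
#' freedom. If every difference is zero the comparison is degenerate and
#' t = d = 0 with p = 1 is returned; a nonzero constant difference is
#' flagged (\code{degenerate = TRUE}, unbounded t).
#'
#' @param dcA,dcB named numeric centrality profiles over the same emotions
#'   (as returned by [degreeCentrality()]).
#' @return List with \code{t}, \code{df}, \code{p}, \code{cohens_d},
#'   \code{degenerate}.
#' @export
compareCentrality <- function(dcA, dcB) {
    if (!setequal(names(dcA), names(dcB)))
        stop("profiles must cover the same emotions")
    dcB <- dcB[names(dcA)]
    d <- dcA - dcB
    n <- length(d)
    sdd <- stats::sd(d)
    if (sdd == 0) {
        if (all(d == 0))
            return(list(t = 0, df = n - 1L, p = 1, cohens_d = 0,
                        degenerate = FALSE))
        return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0,
                    cohens_d = sign(mean(d)) * Inf, degenerate = TRUE))
    }
    tt <- stats::t.test(dcA, dcB, paired = TRUE)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, cohens_d = mean(d) / sdd, degenerate = FALSE)
}

#' Correlation between emotion frequency and centrality
#'
#' Pearson correlation across emotions between how often each emotion is
#' experienced and its degree centrality, with a Fisher z-transform 95\% CI
#' (via [stats::cor.test()]).
#'
#' @param freq named numeric of per-emotion frequencies, or a
#'   [frequencyTable()] data.frame (its emotion rows are used).
#' @param dc named numeric centrality profile.
#' @param conf confidence level.
#' @return List with \code{r}, \code{ci_low}, \code{ci_high}, \code{n}.
#' @export
frequencyCentralityCorrelation <- function(freq, dc, conf = 0.95) {
    if (is.data.frame(freq)) {
        rows <- freq$type == "emotion"
        freq <- setNames(freq$estimate[rows], freq$target[rows])
    }
    if (!setequal(names(freq), names(dc)))
        stop("frequency and centrality must cover the same emotions")
    f <- freq[names(dc)]
    if (stats::sd(f) == 0 || stats::sd(dc) == 0) {
        warning("constant input: correlation undefined")
        return(list(r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    n = length(dc)))
    }
    ct <- stats::cor.test(f, dc, conf.level = conf)
    list(r = unname(ct$estimate), ci_low = ct$conf.int[1],
         ci_high = ct$conf.int[2], n = length(dc))
}

#' Pairwise co-occurrence counts and opposite-valence co-occurrence rates
#'
#' Counts, for every emotion pair, the number of reports endorsing both
#' emotions (the diagonal holds each emotion's endorsement count), and for
#' each emotion the proportion of its endorsements that co-occur with at
#' least one emotion of the opposite valence — the emotions most often
#' involved in mixed emotional states have the highest rates. Rates are
#' \code{NaN} for emotions never endorsed.
#'
#' @param x an [EmotionReportSet-class].
#' @return List with \code{counts} (k x k integer matrix) and
#'   \code{opposite_valence_rate} (named numeric).
#' @export
cooccurrenceTable <- function(x) {
    tax <- taxonomy(x)
    ind <- assay(x, "indicators")          # emotions x reports
    counts <- ind %*% t(ind)
    storage.mode(counts) <- "integer"
    pos <- colSums(ind[positiveEmotions(tax), , drop = FALSE]) > 0
    neg <- colSums(ind[negativeEmotions(tax), , drop = FALSE]) > 0
    val <- valence(tax)
    rate <- vapply(emotions(tax), function(e) {
        endorsed <- ind[e, ] == 1L
        if (!any(endorsed)) return(NaN)
        other <- if (val[[e]] == "positive") neg else pos
        mean(other[endorsed])
    }, 0)
    list(counts = counts, opposite_valence_rate = rate)
}
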