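#' Default marginal prevalences for the 18-emotion taxonomy
#'
#' Per-emotion probabilities that a report endorses each emotion, matching
#' the marginal frequencies observed in large-scale smartphone experience
#' sampling (joy 0.35 down to contempt 0.01).
#'
#' @param taxonomy an [EmotionTaxonomy-class] (the canonical 18).
#' @return Named numeric vector in taxonomy order.
#' @export
defaultPrevalence <- function(taxonomy = emotionTaxonomy()) {
    p <- c(alertness = 0.24, amusement = 0.16, awe = 0.05, gratitude = 0.09,
           hope = 0.22, joy = 0.35, love = 0.30, pride = 0.13,
           satisfaction = 0.27, anger = 0.10, anxiety = 0.29,
           contempt = 0.01, disgust = 0.11, embarrassment = 0.05,
           fear = 0.05, guilt = 0.05, offense = 0.05, sadness = 0.20)
    p[emotions(taxonomy)]
}

#' Default valence-structured latent correlation matrix
#'
#' Compound-symmetric blocks: \code{within} (default +0.4) between emotions
#' of the same valence, \code{between} (default -0.3) across valences —
#' same-valence emotions co-occur, opposite-valence emotions inhibit one
#' another. The default is positive definite (block eigenvalues 7.3, 1.9,
#' 0.6 for the 9+9 taxonomy).
#'
#' @param taxonomy an [EmotionTaxonomy-class].
#' @param within latent correlation within a valence class.
#' @param between latent correlation across valence classes.
#' @return Correlation matrix in taxonomy order.
#' @export
defaultLatentCorr <- function(taxonomy = emotionTaxonomy(), within = 0.4,
                              between = -0.3) {
    val <- valence(taxonomy)
    same <- outer(val, val, "==")
    R <- ifelse(same, within, between)
    diag(R) <- 1
    dimnames(R) <- list(names(val), names(val))
    R
}

#' Default prompt-hour sampling weights
#'
#' Relative weights for the local hour of a prompt: essentially zero at
#' night, a morning peak at 9 AM (the modal response time in smartphone ESM
#' with a default 9 AM - 10 PM prompting window), and sustained waking-hour
#' sampling through the evening.
#'
#' @return Numeric vector of length 24 (hours 0-23).
#' @export
defaultHourWeights <- function() {
    c(rep(0.05, 6),          # 00-05: night
      0.3, 0.6, 1.5,         # 06-08: morning ramp
      3.0,                   # 09: modal hour
      rep(2.2, 3),           # 10-12
      rep(2.4, 5),           # 13-17
      rep(2.6, 4),           # 18-21: evening
      1.0, 0.1)              # 22-23
}

#' Construct a synthetic-generator configuration
#'
#' Defaults reproduce the design of a large francophone smartphone ESM study:
#' 11,572 participants, report counts max(1, NegBin(mean 5.7, size 0.3758))
#' (mean/SD 5.7/9.6), 75% female, marginal prevalences from
#' [defaultPrevalence()], latent correlations +0.4 within / -0.3 between
#' valence, participant random-intercept SD 0.5 on the latent scale, and
#' waking-hour prompt times peaked at 9 AM.
#'
#' @param nParticipants,promptMean,promptDispersion,prevalence,latentCorr,sigmaU,propFemale,hourWeights,hourEffect,seed
#'   see [SyntheticConfig-class].
#' @param taxonomy an [EmotionTaxonomy-class].
#' @return A validated [SyntheticConfig-class].
#' @examples
#' cfg <- syntheticConfig(nParticipants = 50, promptMean = 4, seed = 7)
#' x <- generateDataset(cfg)
#' @export
syntheticConfig <- function(nParticipants = 11572, promptMean = 5.7,
                            promptDispersion = 0.3758,
                            prevalence = defaultPrevalence(taxonomy),
                            latentCorr = defaultLatentCorr(taxonomy),
                            sigmaU = 0.5, propFemale = 0.75,
                            hourWeights = defaultHourWeights(),
                            hourEffect = NULL, seed = 1L,
                            taxonomy = emotionTaxonomy()) {
    emo <- emotions(taxonomy)
    if (is.null(names(prevalence))) names(prevalence) <- emo
    prevalence <- prevalence[emo]
    if (is.null(dimnames(latentCorr)))
        dimnames(latentCorr) <- list(emo, emo)
    if (is.null(hourEffect))
        hourEffect <- matrix(0, 24L, length(emo),
                             dimnames = list(NULL, emo))
    new("SyntheticConfig", nParticipants = as.integer(nParticipants),
        promptMean = promptMean, promptDispersion = promptDispersion,
        prevalence = prevalence, latentCorr = latentCorr, sigmaU = sigmaU,
        propFemale = propFemale, hourWeights = hourWeights,
        hourEffect = hourEffect, seed = as.integer(seed),
        taxonomy = taxonomy)
}

#' Calibrate latent thresholds to target prevalences
#'
#' Under the probit emission model an emotion is endorsed when
#' u + epsilon > c with u ~ N(0, sigmaU^2) (participant intercept) and
#' epsilon ~ N(0, 1), so the threshold achieving marginal prevalence p is
#' c = sqrt(1 + sigmaU^2) * qnorm(1 - p).
#'
#' @param prevalence named numeric of target prevalences in (0, 1).
#' @param sigmaU random-intercept SD (>= 0).
#' @return Named numeric vector of thresholds on the latent scale.
#' @examples
#' calibrateThresholds(c(joy = 0.5), 0)        # 0
#' calibrateThresholds(c(joy = 0.35), 0)       # qnorm(0.65) ~ 0.3853
#' @export
calibrateThresholds <- function(prevalence, sigmaU = 0) {
    if (any(prevalence <= 0 | prevalence >= 1))
        stop("all prevalences must be strictly inside (0, 1)")
    if (sigmaU < 0) stop("sigmaU must be >= 0")
    sqrt(1 + sigmaU^2) * stats::qnorm(1 - prevalence)
}

.corrSqrt <- function(R) {
    # symmetric square root; tolerates PSD-but-singular correlation matrices
    e <- eigen(R, symmetric = TRUE)
    if (min(e$values) < -1e-8)
        stop(sprintf(
            "latent correlation is not positive semi-definite (smallest eigenvalue %.6g)",
            min(e$values)))
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Generate a synthetic experience-sampling dataset
#'
#' Draws a full [EmotionReportSet-class] from a [SyntheticConfig-class]:
#' participant random intercepts, correlated latent Gaussian vectors
#' thresholded into binary indicators, negative-binomial report counts,
#' hour-weighted prompt times over a multi-week calendar, and Bernoulli
#' gender. Fully reproducible: identical configs (including seed) give
#' identical datasets.
#'
#' @param config a [SyntheticConfig-class].
#' @param ... unused.
#' @return An [EmotionReportSet-class].
#' @seealso [impliedPhi()] for the phi correlations the config implies.
#' @name generateDataset
#' @aliases generateDataset,SyntheticConfig-method
#' @export
setMethod("generateDataset", "SyntheticConfig", function(config, ...) {
    validObject(config)
    emo <- emotions(config@taxonomy)
    k <- length(emo)
    thr <- calibrateThresholds(config@prevalence, config@sigmaU)
    set.seed(config@seed)
    nP <- config@nParticipants
    counts <- if (is.infinite(config@promptDispersion))
        stats::rpois(nP, config@promptMean)
    else
        stats::rnbinom(nP, size = config@promptDispersion,
                       mu = config@promptMean)
    counts <- pmax(1L, counts)
    u <- stats::rnorm(nP, 0, config@sigmaU)
    gender <- ifelse(stats::runif(nP) < config@propFemale, "female", "male")
    total <- sum(counts)
    pid <- rep(seq_len(nP), counts)
    A <- .corrSqrt(config@latentCorr)
    Z <- matrix(stats::rnorm(total * k), total, k) %*% A
    # calendar: participant enrolment day + report day within a 5-week span
    startDay <- sample(0:420, nP, replace = TRUE)
    day <- startDay[pid] + sample(0:34, total, replace = TRUE)
    hour <- sample(0:23, total, replace = TRUE, prob = config@hourWeights)
    ts <- as.POSIXct("2013-02-01 00:00:00", tz = "UTC") +
        day * 86400 + hour * 3600 +
        sample(0:59, total, replace = TRUE) * 60 +
        sample(0:59, total, replace = TRUE)
    latent <- u[pid] + Z + config@hourEffect[hour + 1L, , drop = FALSE]
    ind <- matrix(as.integer(latent > rep(thr, each = total)), total, k,
                  dimnames = list(NULL, emo))
    EmotionReportSet(ind, sprintf("P%05d", pid), ts, gender[pid],
                     config@taxonomy)
})

.bvnUpper <- function(a, b, rho) {
    # P(Z1 > a, Z2 > b) for standard bivariate normal with correlation rho
    if (rho >= 1 - 1e-12)
        return(stats::pnorm(max(a, b), lower.tail = FALSE))
    if (rho <= -1 + 1e-12)
        return(max(0, stats::pnorm(-b) - stats::pnorm(a)))
    s <- sqrt(1 - rho^2)
    stats::integrate(function(z)
        stats::dnorm(z) * stats::pnorm((rho * z - b) / s),
        lower = a, upper = Inf, rel.tol = 1e-10,
        abs.tol = 1e-12)$value
}

.bvnUpperMC <- function(a, b, rho, n = 1e6) {
    # Monte-Carlo cross-check of .bvnUpper (used by the test suite)
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
    mean(z1 > a & z2 > b)
}

#' Population phi correlations implied by a generator configuration
#'
#' Closed-form (up to quadrature) Pearson correlations of the binary
#' indicators under the probit model, used as the independent oracle for
#' network parameter recovery. With a shared random intercept, the total
#' latent correlation between emotions a and b is
#' rho* = (rho_ab + sigmaU^2) / (1 + sigmaU^2); the joint endorsement
#' probability P11 is the bivariate-normal upper-orthant probability above
#' the standardized thresholds, and
#' phi = (P11 - pa*pb) / sqrt(pa(1-pa) pb(1-pb)). Defined for configurations
#' without hour-varying emission (\code{hourEffect} all zero).
#'
#' @param config a [SyntheticConfig-class].
#' @param ... unused.
#' @return Symmetric matrix with unit diagonal, entries in [-1, 1].
#' @name impliedPhi
#' @aliases impliedPhi,SyntheticConfig-method
#' @export
setMethod("impliedPhi", "SyntheticConfig", function(config, ...) {
    validObject(config)
    if (any(config@hourEffect != 0))
        warning("impliedPhi assumes zero hourEffect; results ignore it")
    p <- config@prevalence
    emo <- names(p)
    k <- length(p)
    a <- stats::qnorm(1 - p)               # standardized total-scale thresholds
    s2 <- config@sigmaU^2
    rhoTot <- (config@latentCorr + s2) / (1 + s2)
    phi <- diag(k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        p11 <- .bvnUpper(a[i], a[j], rhoTot[i, j])
        phi[i, j] <- phi[j, i] <-
            (p11 - p[i] * p[j]) /
            sqrt(p[i] * (1 - p[i]) * p[j] * (1 - p[j]))
    }
    dimnames(phi) <- list(emo, emo)
    phi
})

setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig:", object@nParticipants, "participants,",
        sprintf("mean %.1f prompts (NB size %.3g), sigmaU = %.2f, seed = %d\n",
                object@promptMean, object@promptDispersion, object@sigmaU,
                object@seed))
    cat("  prevalence:", sprintf("%s=%.2f", names(object@prevalence),
                                 object@prevalence)[1:4], "...\n")
})
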