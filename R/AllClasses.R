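#' @import methods
#' @import SummarizedExperiment
NULL

#' EmotionTaxonomy: a fixed, ordered set of valenced emotions
#'
#' An \code{EmotionTaxonomy} holds an ordered list of emotion names together
#' with a valence label (\code{"positive"} or \code{"negative"}) for each.
#' The ordering is canonical: it is preserved in every matrix, table and file
#' the package produces, so that outputs are comparable across runs.
#'
#' The default taxonomy ([emotionTaxonomy()]) is the 18-item checklist used in
#' smartphone experience sampling of discrete emotions (adapted from the
#' modified Differential Emotions Scale): nine positive emotions followed by
#' nine negative ones, each block alphabetical.
#'
#' @slot emotions character vector of unique emotion names, in canonical order.
#' @slot valence named character vector mapping each emotion to
#'   \code{"positive"} or \code{"negative"}, in the same order.
#'
#' @seealso [emotionTaxonomy()], [positiveEmotions()], [negativeEmotions()]
#' @exportClass EmotionTaxonomy
setClass("EmotionTaxonomy",
    slots = c(emotions = "character", valence = "character"))

setValidity("EmotionTaxonomy", function(object) {
    msg <- NULL
    e <- object@emotions
    v <- object@valence
    if (length(e) < 2L)
        msg <- c(msg, "taxonomy must contain at least 2 emotions")
    if (anyDuplicated(e))
        msg <- c(msg, "emotion names must be unique")
    if (!identical(names(v), e))
        msg <- c(msg, "'valence' must be named by 'emotions', in the same order")
    if (!all(v %in% c("positive", "negative")))
        msg <- c(msg, "valence labels must be 'positive' or 'negative'")
    if (length(unique(v)) < 2L)
        msg <- c(msg, "taxonomy must contain both valences")
    if (is.null(msg)) TRUE else msg
})

#' EmotionReportSet: a collection of binary emotion reports
#'
#' \code{EmotionReportSet} extends
#' \code{\link[SummarizedExperiment]{SummarizedExperiment}}. The single assay
#' \code{"indicators"} is an emotions-by-reports 0/1 matrix (rows follow the
#' taxonomy's canonical order); \code{colData} carries per-report metadata:
#' \code{participant_id}, \code{timestamp} (POSIXct, local clock time) and
#' \code{gender} (\code{"female"}, \code{"male"} or \code{"unknown"});
#' \code{rowData} carries the valence of each emotion. An all-zero indicator
#' column is legal and encodes a report of no emotion.
#'
#' @seealso [EmotionReportSet()] (constructor), [readReports()],
#'   [generateDataset()]
#' @exportClass EmotionReportSet
setClass("EmotionReportSet", contains = "SummarizedExperiment")

setValidity("EmotionReportSet", function(object) {
    msg <- NULL
    if (!"indicators" %in% assayNames(object))
        return("assay 'indicators' is required")
    ind <- assay(object, "indicators")
    if (ncol(ind) < 1L)
        msg <- c(msg, "a report set must contain at least one report")
    if (!all(ind %in% c(0L, 1L)))
        msg <- c(msg, "all indicators must be 0 or 1")
    cd <- colData(object)
    for (f in c("participant_id", "timestamp"))
        if (!f %in% names(cd))
            msg <- c(msg, sprintf("colData field '%s' is required", f))
    if ("participant_id" %in% names(cd)) {
        pid <- cd$participant_id
        if (any(is.na(pid)) || any(!nzchar(pid)))
            msg <- c(msg, "participant ids must be non-empty")
    }
    if ("timestamp" %in% names(cd) && !inherits(cd$timestamp, "POSIXct"))
        msg <- c(msg, "'timestamp' must be POSIXct")
    if (!"valence" %in% names(rowData(object)))
        msg <- c(msg, "rowData field 'valence' is required")
    if (is.null(rownames(object)))
        msg <- c(msg, "rows must be named by emotion")
    if (is.null(msg)) TRUE else msg
})

#' WeightMatrix: a signed emotion co-occurrence network
#'
#' The weighted, undirected emotion network. \code{W} is the symmetric matrix
#' of phi coefficients (Pearson correlations of the binary indicator vectors)
#' between emotions; by convention the diagonal is 0 (no self-edges) and all
#' entries lie in [-1, 1]. Edges whose correlation is undefined because one
#' indicator is constant across reports are stored as 0 and flagged in
#' \code{mask}, so degree centrality remains defined even when a rare emotion
#' is never (or always) endorsed in a sample.
#'
#' @slot W numeric matrix of edge weights, emotions x emotions.
#' @slot mask logical matrix, \code{TRUE} where the correlation was undefined.
#' @slot nReports number of reports the network was estimated from.
#' @slot taxonomy the [EmotionTaxonomy-class] the rows/columns follow.
#'
#' @seealso [phiMatrix()], [degreeCentrality()], [classifyTypology()],
#'   [writeNetwork()]
#' @exportClass WeightMatrix
setClass("WeightMatrix",
    slots = c(W = "matrix", mask = "matrix", nReports = "integer",
              taxonomy = "EmotionTaxonomy"))

setValidity("WeightMatrix", function(object) {
    msg <- NULL
    W <- object@W
    k <- length(object@taxonomy@emotions)
    if (!identical(dim(W), c(k, k)))
        msg <- c(msg, "W must be square with one row per taxonomy emotion")
    if (!identical(rownames(W), object@taxonomy@emotions))
        msg <- c(msg, "W dimnames must equal the taxonomy emotions")
    if (!isTRUE(all.equal(W, t(W), tolerance = 1e-12, check.attributes = FALSE)))
        msg <- c(msg, "W must be symmetric")
    if (any(abs(diag(W)) > 0))
        msg <- c(msg, "diagonal of W must be 0 (self-edges are excluded)")
    if (any(abs(W) > 1 + 1e-12))
        msg <- c(msg, "all |weights| must be <= 1")
    if (!identical(dim(object@mask), dim(W)))
        msg <- c(msg, "mask must have the same dimensions as W")
    if (is.null(msg)) TRUE else msg
})

#' EmotionTypology: connector / provincial / distal labels
#'
#' The node typology of the emotion network, obtained by thresholding edge
#' strengths at \code{tau}: a \emph{connector} emotion has at least one strong
#' same-valence and one strong opposite-valence edge, a \emph{provincial}
#' emotion has strong same-valence edges only, and a \emph{distal} emotion has
#' no strong same-valence edge (emotions with only opposite-valence strong
#' edges are filed as distal and reported via a message).
#'
#' @slot labels named character vector, one of \code{"connector"},
#'   \code{"provincial"}, \code{"distal"} per emotion.
#' @slot tau the edge-strength threshold used.
#'
#' @seealso [classifyTypology()]
#' @exportClass EmotionTypology
setClass("EmotionTypology",
    slots = c(labels = "character", tau = "numeric"))

setValidity("EmotionTypology", function(object) {
    msg <- NULL
    if (!all(object@labels %in% c("connector", "provincial", "distal")))
        msg <- c(msg, "labels must be connector/provincial/distal")
    if (is.null(names(object@labels)))
        msg <- c(msg, "labels must be named by emotion")
    if (length(object@tau) != 1L || !is.finite(object@tau) || object@tau <= 0)
        msg <- c(msg, "tau must be a single positive number")
    if (is.null(msg)) TRUE else msg
})

#' SyntheticConfig: parameters of the synthetic ESM generator
#'
#' Configuration of the multivariate-probit (thresholded Gaussian copula)
#' report generator. Each participant i receives a latent random intercept
#' u_i ~ N(0, sigmaU^2) shared across emotions; each report draws a latent
#' vector z ~ MVN(0, latentCorr); emotion e is endorsed iff
#' u_i + z_e + hourEffect[hour, e] exceeds a threshold calibrated so that the
#' marginal endorsement probability equals \code{prevalence[e]} (see
#' [calibrateThresholds()]). Report counts per participant are
#' max(1, NegBin(promptMean, promptDispersion)); prompt times are drawn from
#' \code{hourWeights} over a simulated multi-week calendar.
#'
#' @slot nParticipants number of participants.
#' @slot promptMean mean reports per participant (negative-binomial mean).
#' @slot promptDispersion negative-binomial size parameter; \code{Inf} gives
#'   Poisson counts.
#' @slot prevalence named numeric, target marginal endorsement probability per
#'   emotion, strictly inside (0, 1).
#' @slot latentCorr correlation matrix of the latent Gaussian layer
#'   (symmetric, unit diagonal, positive semi-definite).
#' @slot sigmaU participant random-intercept SD on the latent scale (>= 0).
#' @slot propFemale probability a participant is female.
#' @slot hourWeights non-negative sampling weights for prompt hour (length 24).
#' @slot hourEffect 24 x n-emotion matrix of additive latent shifts by local
#'   hour (all zero by default; nonzero values create hour-varying emission).
#' @slot seed integer master seed; all randomness derives from it.
#' @slot taxonomy the [EmotionTaxonomy-class] used.
#'
#' @seealso [syntheticConfig()], [generateDataset()], [impliedPhi()]
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
    slots = c(nParticipants = "integer", promptMean = "numeric",
              promptDispersion = "numeric", prevalence = "numeric",
              latentCorr = "matrix", sigmaU = "numeric", propFemale = "numeric",
              hourWeights = "numeric", hourEffect = "matrix", seed = "integer",
              taxonomy = "EmotionTaxonomy"))

setValidity("SyntheticConfig", function(object) {
    msg <- NULL
    emo <- object@taxonomy@emotions
    k <- length(emo)
    if (object@nParticipants < 1L)
        msg <- c(msg, "nParticipants must be >= 1")
    if (object@promptMean <= 0)
        msg <- c(msg, "promptMean must be positive")
    if (object@promptDispersion <= 0)
        msg <- c(msg, "promptDispersion must be positive")
    p <- object@prevalence
    if (!identical(names(p), emo))
        msg <- c(msg, "prevalence must be named by the taxonomy emotions, in order")
    if (any(p <= 0 | p >= 1))
        msg <- c(msg, "all prevalences must be strictly inside (0, 1)")
    R <- object@latentCorr
    if (!identical(dim(R), c(k, k)))
        msg <- c(msg, "latentCorr must be k x k for a k-emotion taxonomy")
    else {
        if (!isTRUE(all.equal(R, t(R), tolerance = 1e-10,
                              check.attributes = FALSE)))
            msg <- c(msg, "latentCorr must be symmetric")
        if (any(abs(diag(R) - 1) > 1e-10))
            msg <- c(msg, "latentCorr must have unit diagonal")
        ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
        if (ev < -1e-8)
            msg <- c(msg, sprintf(
                "latentCorr is not positive semi-definite (smallest eigenvalue %.6g)",
                ev))
    }
    if (object@sigmaU < 0)
        msg <- c(msg, "sigmaU must be >= 0")
    if (object@propFemale < 0 || object@propFemale > 1)
        msg <- c(msg, "propFemale must be in [0, 1]")
    hw <- object@hourWeights
    if (length(hw) != 24L || any(hw < 0) || all(hw == 0))
        msg <- c(msg, "hourWeights must be 24 non-negative values, not all zero")
    if (!identical(dim(object@hourEffect), c(24L, k)))
        msg <- c(msg, "hourEffect must be a 24 x k matrix")
    if (is.null(msg)) TRUE else msg
})
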