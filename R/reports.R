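#' Construct an EmotionReportSet
#'
#' Assembles binary emotion reports into an [EmotionReportSet-class]. The
#' indicator matrix may be given reports-in-rows (one column per emotion,
#' the natural layout of a wide CSV) or emotions-in-rows; orientation is
#' resolved against the taxonomy.
#'
#' @param indicators 0/1 matrix, reports x emotions (columns named by
#'   emotion, or unnamed and taken in taxonomy order) or its transpose.
#' @param participantId character vector of non-empty participant ids, one
#'   per report.
#' @param timestamp POSIXct vector of report times (participant-local clock
#'   time), one per report.
#' @param gender optional per-report gender (\code{"female"}, \code{"male"},
#'   \code{"unknown"}); \code{NA} is recoded to \code{"unknown"}.
#' @param taxonomy an [EmotionTaxonomy-class]; default the canonical 18.
#' @return An [EmotionReportSet-class].
#' @examples
#' tax <- emotionTaxonomy()
#' ind <- matrix(0L, nrow = 2, ncol = 18, dimnames = list(NULL, emotions(tax)))
#' ind[1, "joy"] <- 1L
#' x <- EmotionReportSet(ind, c("p1", "p2"),
#'                       as.POSIXct("2013-03-01 09:15:00", tz = "UTC") + c(0, 60))
#' nReports(x)
#' @export
EmotionReportSet <- function(indicators, participantId, timestamp,
                             gender = NULL, taxonomy = emotionTaxonomy()) {
    emo <- emotions(taxonomy)
    k <- length(emo)
    if (!is.matrix(indicators))
        indicators <- as.matrix(indicators)
    if (is.null(colnames(indicators)) && is.null(rownames(indicators))) {
        if (ncol(indicators) == k) colnames(indicators) <- emo
        else if (nrow(indicators) == k) rownames(indicators) <- emo
        else stop("cannot align an unnamed ", nrow(indicators), " x ",
                  ncol(indicators), " indicator matrix to a ", k,
                  "-emotion taxonomy")
    }
    if (!is.null(rownames(indicators)) && setequal(rownames(indicators), emo) &&
        !(identical(nrow(indicators), k) && identical(ncol(indicators), k) &&
          !is.null(colnames(indicators)) && setequal(colnames(indicators), emo)))
        indicators <- t(indicators)
    if (is.null(colnames(indicators)) || !setequal(colnames(indicators), emo))
        stop("indicator columns do not match the taxonomy emotions")
    ind <- t(indicators[, emo, drop = FALSE])
    storage.mode(ind) <- "integer"
    n <- ncol(ind)
    if (is.null(gender)) gender <- rep("unknown", n)
    gender <- as.character(gender)
    gender[is.na(gender)] <- "unknown"
    if (!all(gender %in% c("female", "male", "unknown")))
        stop("gender must be 'female', 'male' or 'unknown'")
    colnames(ind) <- NULL
    se <- SummarizedExperiment(
        assays = list(indicators = ind),
        rowData = S4Vectors::DataFrame(valence = valence(taxonomy),
                                       row.names = emo),
        colData = S4Vectors::DataFrame(
            participant_id = as.character(participantId),
            timestamp = timestamp, gender = gender))
    S4Vectors::metadata(se)$taxonomy <- taxonomy
    new("EmotionReportSet", se)
}

#' Accessors for EmotionReportSet
#'
#' \code{indicators} returns the reports-by-emotions 0/1 matrix;
#' \code{participantId}, \code{reportTime} and \code{reportGender} the
#' per-report metadata; \code{taxonomy} the [EmotionTaxonomy-class];
#' \code{nReports} the number of reports.
#'
#' @param x an [EmotionReportSet-class].
#' @return See description.
#' @name EmotionReportSet-accessors
#' @aliases taxonomy indicators participantId reportTime reportGender nReports
NULL

#' @rdname EmotionReportSet-accessors
setMethod("taxonomy", "EmotionReportSet", function(x) {
    tax <- S4Vectors::metadata(x)$taxonomy
    if (is.null(tax))
        tax <- new("EmotionTaxonomy", emotions = rownames(x),
                   valence = setNames(rowData(x)$valence, rownames(x)))
    tax
})

#' @rdname EmotionReportSet-accessors
setMethod("indicators", "EmotionReportSet",
    function(x) t(assay(x, "indicators")))

#' @rdname EmotionReportSet-accessors
setMethod("participantId", "EmotionReportSet",
    function(x) colData(x)$participant_id)

#' @rdname EmotionReportSet-accessors
setMethod("reportTime", "EmotionReportSet", function(x) colData(x)$timestamp)

#' @rdname EmotionReportSet-accessors
setMethod("reportGender", "EmotionReportSet", function(x) colData(x)$gender)

#' @rdname EmotionReportSet-accessors
setMethod("nReports", "EmotionReportSet", function(x) ncol(x))

setMethod("show", "EmotionReportSet", function(object) {
    cat("EmotionReportSet:", ncol(object), "reports from",
        length(unique(participantId(object))), "participants,",
        nrow(object), "emotions\n")
    rng <- range(reportTime(object))
    cat("  time range:", format(rng[1]), "to", format(rng[2]), "\n")
    endorse <- mean(colSums(assay(object, "indicators")) > 0)
    cat(sprintf("  reports with >=1 emotion: %.1f%%\n", 100 * endorse))
})
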