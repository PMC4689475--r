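.POSITIVE_18 <- c("alertness", "amusement", "awe", "gratitude", "hope",
                  "joy", "love", "pride", "satisfaction")
.NEGATIVE_18 <- c("anger", "anxiety", "contempt", "disgust", "embarrassment",
                  "fear", "guilt", "offense", "sadness")

#' Construct an emotion taxonomy
#'
#' With no arguments, returns the canonical 18-emotion taxonomy used
#' throughout the package: nine positive emotions (alertness, amusement, awe,
#' gratitude, hope, joy, love, pride, satisfaction) followed by nine negative
#' ones (anger, anxiety, contempt, disgust, embarrassment, fear, guilt,
#' offense, sadness), each block alphabetical. This ordering is canonical and
#' stable across all package outputs.
#'
#' @param positive character vector of positive emotion names.
#' @param negative character vector of negative emotion names.
#' @return An [EmotionTaxonomy-class] with positives first.
#' @examples
#' tax <- emotionTaxonomy()
#' length(emotions(tax))        # 18
#' table(valence(tax))          # 9 positive, 9 negative
#' @export
emotionTaxonomy <- function(positive = .POSITIVE_18, negative = .NEGATIVE_18) {
    emo <- c(positive, negative)
    val <- setNames(rep(c("positive", "negative"),
                        c(length(positive), length(negative))), emo)
    new("EmotionTaxonomy", emotions = emo, valence = val)
}

#' Taxonomy accessors
#'
#' \code{emotions} returns the emotion names in canonical order;
#' \code{valence} the named valence vector; \code{positiveEmotions} and
#' \code{negativeEmotions} the two valence classes.
#'
#' @param x an [EmotionTaxonomy-class] (or, for \code{valence}, any object
#'   with a taxonomy).
#' @return Character vectors.
#' @name emotions
#' @aliases emotions,EmotionTaxonomy-method valence,EmotionTaxonomy-method
#'   positiveEmotions,EmotionTaxonomy-method
#'   negativeEmotions,EmotionTaxonomy-method
NULL

#' @rdname emotions
setMethod("emotions", "EmotionTaxonomy", function(x) x@emotions)

#' @rdname emotions
setMethod("valence", "EmotionTaxonomy", function(x) x@valence)

#' @rdname emotions
setMethod("positiveEmotions", "EmotionTaxonomy",
    function(x) x@emotions[x@valence == "positive"])

#' @rdname emotions
setMethod("negativeEmotions", "EmotionTaxonomy",
    function(x) x@emotions[x@valence == "negative"])

setMethod("show", "EmotionTaxonomy", function(object) {
    cat("EmotionTaxonomy with", length(object@emotions), "emotions\n")
    cat("  positive:", paste(positiveEmotions(object), collapse = ", "), "\n")
    cat("  negative:", paste(negativeEmotions(object), collapse = ", "), "\n")
})
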