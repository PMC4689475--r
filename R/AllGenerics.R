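#' @rdname emotions
#' @export
setGeneric("emotions", function(x) standardGeneric("emotions"))

#' @rdname emotions
#' @export
setGeneric("valence", function(x) standardGeneric("valence"))

#' @rdname emotions
#' @export
setGeneric("positiveEmotions", function(x) standardGeneric("positiveEmotions"))

#' @rdname emotions
#' @export
setGeneric("negativeEmotions", function(x) standardGeneric("negativeEmotions"))

#' @rdname EmotionReportSet-accessors
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @rdname EmotionReportSet-accessors
#' @export
setGeneric("indicators", function(x) standardGeneric("indicators"))

#' @rdname EmotionReportSet-accessors
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))

#' @rdname EmotionReportSet-accessors
#' @export
setGeneric("reportTime", function(x) standardGeneric("reportTime"))

#' @rdname EmotionReportSet-accessors
#' @export
setGeneric("reportGender", function(x) standardGeneric("reportGender"))

#' @rdname EmotionReportSet-accessors
#' @export
setGeneric("nReports", function(x) standardGeneric("nReports"))

#' @rdname categorizeReports
#' @export
setGeneric("categorizeReports", function(x, ...)
    standardGeneric("categorizeReports"))

#' @rdname phiMatrix
#' @export
setGeneric("phiMatrix", function(x, ...) standardGeneric("phiMatrix"))

#' @rdname degreeCentrality
#' @export
setGeneric("degreeCentrality", function(x, ...)
    standardGeneric("degreeCentrality"))

#' @rdname classifyTypology
#' @export
setGeneric("classifyTypology", function(x, ...)
    standardGeneric("classifyTypology"))

#' @rdname generateDataset
#' @export
setGeneric("generateDataset", function(config, ...)
    standardGeneric("generateDataset"))

#' @rdname impliedPhi
#' @export
setGeneric("impliedPhi", function(config, ...) standardGeneric("impliedPhi"))

#' @rdname WeightMatrix-accessors
#' @export
setGeneric("edgeMask", function(x) standardGeneric("edgeMask"))

#' @rdname EmotionTypology-accessors
#' @export
setGeneric("typologyLabels", function(x) standardGeneric("typologyLabels"))

#' @rdname EmotionTypology-accessors
#' @export
setGeneric("typologyTau", function(x) standardGeneric("typologyTau"))
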