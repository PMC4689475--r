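.parseTimestamp <- function(x) {
    out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
    alt <- is.na(out)
    if (any(alt))
        out[alt] <- as.POSIXct(strptime(x[alt], "%Y-%m-%d %H:%M:%S",
                                        tz = "UTC"))
    out
}

.checkBinaryColumn <- function(values, colname) {
    bad <- which(!(values %in% c(0, 1)) | is.na(values))
    if (length(bad))
        stop(sprintf(
            "non-binary indicator value '%s' at row %d, column '%s'",
            as.character(values[bad[1]]), bad[1], colname), call. = FALSE)
    as.integer(values)
}

#' Read emotion reports from CSV
#'
#' Reads an experience-sampling dataset from a wide CSV (one 0/1 column per
#' emotion) or a long CSV with columns
#' \code{participant_id, timestamp, emotion, present}. Long input is pivoted
#' to one indicator vector per prompt (a prompt is a unique
#' participant/timestamp pair); emotions absent from a prompt's rows are
#' imputed as 0, so a long file listing only endorsed emotions is equivalent
#' to the wide file. Timestamps are ISO-8601 in the participant's local clock
#' time; rows with unparseable timestamps are rejected and logged in
#' \code{metadata(x)$rejected} with a warning. Non-binary indicator values
#' are a fatal error naming the offending row and column; a missing required
#' column, an unknown emotion name or an empty file are fatal. Duplicate
#' (participant, timestamp) rows are kept with a warning (delayed prompts are
#' legitimate).
#'
#' @param path CSV file path.
#' @param schema \code{"wide"} or \code{"long"}.
#' @param taxonomy an [EmotionTaxonomy-class]; default the canonical 18.
#' @return An [EmotionReportSet-class].
#' @seealso [writeReports()]
#' @export
readReports <- function(path, schema = c("wide", "long"),
                        taxonomy = emotionTaxonomy()) {
    schema <- match.arg(schema)
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
    if (nrow(df) == 0L) stop("empty file: ", path)
    emo <- emotions(taxonomy)
    required <- c(participant_id = "participant_id", timestamp = "timestamp",
                  if (schema == "long") c(emotion = "emotion",
                                          present = "present"))
    for (col in required)
        if (!col %in% names(df))
            stop(sprintf("missing required column '%s'", col), call. = FALSE)

    if (schema == "wide") {
        missing_emo <- setdiff(emo, names(df))
        if (length(missing_emo))
            stop("missing required column(s): ",
                 paste(missing_emo, collapse = ", "), call. = FALSE)
        ind <- sapply(emo, function(e) .checkBinaryColumn(df[[e]], e))
        ind <- matrix(ind, ncol = length(emo),
                      dimnames = list(NULL, emo))
        ts <- .parseTimestamp(df$timestamp)
        keep <- !is.na(ts)
        rejected <- data.frame(row = which(!keep),
                               reason = rep("unparseable timestamp",
                                            sum(!keep)))
        if (any(!keep))
            warning(sum(!keep), " row(s) rejected (unparseable timestamp); ",
                    "see metadata(x)$rejected")
        if (!any(keep)) stop("no valid reports after validation")
        gender <- if ("gender" %in% names(df)) df$gender[keep] else NULL
        pid <- as.character(df$participant_id[keep])
        ts <- ts[keep]
        ind <- ind[keep, , drop = FALSE]
        if (anyDuplicated(paste(pid, format(ts))))
            warning("duplicate (participant, timestamp) rows kept")
        x <- EmotionReportSet(ind, pid, ts, gender, taxonomy)
        S4Vectors::metadata(x)$rejected <- rejected
        return(x)
    }

    unknown <- setdiff(unique(df$emotion), emo)
    if (length(unknown))
        stop("unknown emotion name(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    df$present <- .checkBinaryColumn(df$present, "present")
    ts_all <- .parseTimestamp(df$timestamp)
    keep <- !is.na(ts_all)
    rejected <- data.frame(row = which(!keep),
                           reason = rep("unparseable timestamp", sum(!keep)))
    if (any(!keep))
        warning(sum(!keep), " row(s) rejected (unparseable timestamp); ",
                "see metadata(x)$rejected")
    df <- df[keep, , drop = FALSE]
    ts_all <- ts_all[keep]
    if (nrow(df) == 0L) stop("no valid reports after validation")
    key <- paste(df$participant_id, format(ts_all, "%Y-%m-%dT%H:%M:%S"))
    first <- !duplicated(key)
    prompt <- match(key, key[first])
    ind <- matrix(0L, nrow = sum(first), ncol = length(emo),
                  dimnames = list(NULL, emo))
    ind[cbind(prompt, match(df$emotion, emo))] <- df$present
    gender <- if ("gender" %in% names(df)) df$gender[first] else NULL
    x <- EmotionReportSet(ind, as.character(df$participant_id[first]),
                          ts_all[first], gender, taxonomy)
    S4Vectors::metadata(x)$rejected <- rejected
    x
}

#' Write emotion reports to CSV
#'
#' Writes an [EmotionReportSet-class] as a wide CSV (one 0/1 column per
#' emotion, canonical order) or a long CSV with explicit
#' \code{present} values for every emotion of every prompt, so that
#' \code{readReports(writeReports(x))} is the identity on indicators,
#' participant ids and timestamps (to second resolution).
#'
#' @param x an [EmotionReportSet-class].
#' @param path output CSV path.
#' @param schema \code{"wide"} or \code{"long"}.
#' @return \code{path}, invisibly.
#' @export
writeReports <- function(x, path, schema = c("wide", "long")) {
    schema <- match.arg(schema)
    emo <- emotions(taxonomy(x))
    ts <- format(reportTime(x), "%Y-%m-%dT%H:%M:%S")
    if (schema == "wide") {
        df <- data.frame(participant_id = participantId(x), timestamp = ts,
                         gender = reportGender(x), check.names = FALSE)
        df <- cbind(df, as.data.frame(indicators(x)))
    } else {
        n <- nReports(x)
        k <- length(emo)
        df <- data.frame(
            participant_id = rep(participantId(x), each = k),
            timestamp = rep(ts, each = k),
            gender = rep(reportGender(x), each = k),
            emotion = rep(emo, times = n),
            present = as.integer(t(indicators(x))))
    }
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
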