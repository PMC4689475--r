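.pipelineLog <- function(con, ...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(line)
    if (!is.null(con)) writeLines(line, con)
}

.configHash <- function(obj) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                force = TRUE), f)
    unname(tools::md5sum(f))
}

#' Run the full emotion-analysis pipeline
#'
#' Orchestrates load/simulate, frequency estimation, temporal profiles,
#' network construction, centrality/typology and (optionally) a group
#' comparison, writing a reproducible bundle to \code{outDir}:
#' \code{frequency_table.csv}, \code{temporal_hour.csv},
#' \code{temporal_weekday.csv}, \code{edges.csv}, \code{network.graphml},
#' \code{centrality_typology.csv}, \code{group_comparison.json},
#' \code{pipeline.log} and \code{manifest.json} (versions, seed, config
#' hash, per-stage warnings and timings). The same input/config and seed
#' give byte-identical CSV outputs.
#'
#' @param input path to a wide-schema reports CSV (exclusive with
#'   \code{synthetic}).
#' @param synthetic a [SyntheticConfig-class] to simulate from (exclusive
#'   with \code{input}).
#' @param outDir output directory (created if needed).
#' @param tau typology edge-strength threshold.
#' @param hourRange,minReports see [temporalProfile()].
#' @param groupCol per-report grouping column for the centrality comparison
#'   (\code{"gender"}, or \code{NULL} to skip); if the column is absent or
#'   has fewer than two groups the stage is skipped with a warning.
#' @param seed overrides the synthetic config's seed when simulating.
#' @param freqMethod \code{"mixed"} or \code{"pooled"} (see
#'   [estimateFrequency()]).
#' @return Invisibly, a list with the in-memory results (\code{dataset},
#'   \code{frequency}, \code{network}, \code{centrality}, \code{typology},
#'   \code{comparison}, \code{manifest}).
#' @export
runPipeline <- function(input = NULL, synthetic = NULL, outDir,
                        tau = 0.1, hourRange = c(6, 22), minReports = 1000,
                        groupCol = "gender", seed = NULL,
                        freqMethod = c("mixed", "pooled")) {
    freqMethod <- match.arg(freqMethod)
    if (is.null(input) == is.null(synthetic))
        stop("exactly one of 'input' and 'synthetic' must be given")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    logCon <- file(file.path(outDir, "pipeline.log"), "w")
    on.exit(close(logCon))
    manifest <- list(
        package = as.character(utils::packageVersion("emonet")),
        r_version = R.version.string,
        seed = if (!is.null(seed)) seed
               else if (!is.null(synthetic)) synthetic@seed else NA,
        tau = tau, hour_range = hourRange, min_reports = minReports,
        group_col = if (is.null(groupCol)) NA else groupCol,
        warnings = list(), timings = list())
    stage <- function(name, expr) {
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch(withCallingHandlers(expr,
            warning = function(w) {
                manifest$warnings[[name]] <<-
                    c(manifest$warnings[[name]], conditionMessage(w))
                invokeRestart("muffleWarning")
            }),
            error = function(e) stop("stage '", name, "' failed: ",
                                     conditionMessage(e), call. = FALSE))
        manifest$timings[[name]] <<-
            round(proc.time()[["elapsed"]] - t0, 3)
        .pipelineLog(logCon, sprintf("stage %-12s done (%.2fs)", name,
                                     manifest$timings[[name]]))
        res
    }

    x <- if (!is.null(input)) {
        manifest$input <- normalizePath(input)
        stage("load", readReports(input, "wide"))
    } else {
        if (!is.null(seed)) synthetic@seed <- as.integer(seed)
        manifest$config_hash <- .configHash(list(
            n = synthetic@nParticipants, mean = synthetic@promptMean,
            disp = synthetic@promptDispersion,
            prevalence = synthetic@prevalence,
            corr = synthetic@latentCorr, sigma_u = synthetic@sigmaU,
            prop_female = synthetic@propFemale,
            hour_weights = synthetic@hourWeights, seed = synthetic@seed))
        stage("simulate", generateDataset(synthetic))
    }

    freq <- stage("frequencies",
                  frequencyTable(x, method = freqMethod))
    utils::write.csv(freq, file.path(outDir, "frequency_table.csv"),
                     row.names = FALSE, quote = FALSE)

    emo <- emotions(taxonomy(x))
    targets <- c(emo, "positive_only", "negative_only", "mixed", "any")
    tempo <- stage("temporal", {
        lapply(c(hour = "hour", weekday = "weekday"), function(by) {
            do.call(rbind, lapply(targets, function(tg) {
                p <- temporalProfile(x, tg, by, hourRange, minReports)
                if (nrow(p)) cbind(target = tg, p) else NULL
            }))
        })
    })
    for (by in names(tempo)) {
        out <- tempo[[by]]
        if (is.null(out))
            out <- data.frame(target = character(), bin = integer(),
                              n = integer(), frequency = numeric())
        utils::write.csv(out,
                         file.path(outDir, sprintf("temporal_%s.csv", by)),
                         row.names = FALSE, quote = FALSE)
    }

    W <- stage("network", phiMatrix(x))
    maskedPairs <- sum(edgeMask(W)[upper.tri(edgeMask(W))])
    if (maskedPairs > 0)
        manifest$warnings$network <-
            c(manifest$warnings$network,
              sprintf("%d masked (undefined) edges", maskedPairs))
    freqProp <- setNames(freq$pooled[freq$type == "emotion"] / 100,
                         freq$target[freq$type == "emotion"])
    writeNetwork(W, file.path(outDir, "edges.csv"), "edge_list_csv")
    writeNetwork(W, file.path(outDir, "network.graphml"), "graphml",
                 frequencies = freqProp)

    dc <- stage("centrality", degreeCentrality(W))
    typ <- stage("typology", classifyTypology(W, tau = tau))
    utils::write.csv(
        data.frame(emotion = emo, valence = unname(valence(taxonomy(x))),
                   degree_centrality = unname(dc[emo]),
                   typology = unname(typologyLabels(typ)[emo])),
        file.path(outDir, "centrality_typology.csv"),
        row.names = FALSE, quote = FALSE)

    comparison <- NULL
    if (!is.null(groupCol)) {
        grp <- if (groupCol == "gender") reportGender(x)
               else colData(x)[[groupCol]]
        levs <- if (is.null(grp)) character(0)
                else setdiff(unique(grp), "unknown")
        if (length(levs) < 2L) {
            warning("group column '", groupCol,
                    "' absent or has < 2 groups; comparison skipped")
            manifest$warnings$compare <- c(manifest$warnings$compare,
                                           "comparison skipped")
            .pipelineLog(logCon, "stage compare      skipped")
        } else {
            comparison <- stage("compare", {
                levs <- sort(levs)[1:2]
                dcs <- lapply(levs, function(l)
                    degreeCentrality(phiMatrix(x[, grp == l])))
                cmp <- compareCentrality(dcs[[1]], dcs[[2]])
                c(list(group_a = levs[1], group_b = levs[2]), cmp,
                  list(dc_a = as.list(dcs[[1]]), dc_b = as.list(dcs[[2]])))
            })
            jsonlite::write_json(comparison,
                                 file.path(outDir, "group_comparison.json"),
                                 auto_unbox = TRUE, digits = NA)
        }
    }

    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    invisible(list(dataset = x, frequency = freq, temporal = tempo,
                   network = W, centrality = dc, typology = typ,
                   comparison = comparison, manifest = manifest))
}
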