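.fmtDouble <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NaN"
    out
}

.pairIndex <- function(k) {
    ij <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
}

#' Write an emotion network to disk
#'
#' Serialises a [WeightMatrix-class] either as an edge-list CSV with columns
#' \code{emotion_a, emotion_b, weight} covering every unordered pair (153
#' rows for the 18-emotion taxonomy), or as GraphML in which nodes carry
#' \code{valence} and \code{frequency} attributes and edges carry
#' \code{weight} (plus a \code{masked} flag for undefined correlations).
#' Weights are written with 17 significant digits so that
#' [readNetwork()] reproduces the matrix exactly.
#'
#' @param W a [WeightMatrix-class].
#' @param path output file path.
#' @param format \code{"edge_list_csv"} or \code{"graphml"}.
#' @param frequencies optional named numeric of per-emotion frequencies
#'   (proportions) stored as node attributes in GraphML.
#' @return \code{path}, invisibly.
#' @seealso [readNetwork()], [phiMatrix()]
#' @export
writeNetwork <- function(W, path, format = c("edge_list_csv", "graphml"),
                         frequencies = NULL) {
    stopifnot(is(W, "WeightMatrix"))
    format <- match.arg(format)
    emo <- emotions(W@taxonomy)
    ij <- .pairIndex(length(emo))
    if (format == "edge_list_csv") {
        lines <- c("emotion_a,emotion_b,weight",
                   sprintf("%s,%s,%s", emo[ij[, 1]], emo[ij[, 2]],
                           .fmtDouble(W@W[ij])))
        con <- tryCatch(suppressWarnings(file(path, "w")),
                        error = function(e) stop("cannot write '", path,
                                                 "': ", conditionMessage(e)))
        on.exit(close(con))
        writeLines(lines, con)
        return(invisible(path))
    }
    freq <- setNames(rep(NA_real_, length(emo)), emo)
    if (!is.null(frequencies))
        freq[names(frequencies)] <- frequencies
    doc <- xml2::xml_new_root("graphml",
        xmlns = "http://graphml.graphdrawing.org/xmlns")
    for (key in list(
        c(id = "d0", `for` = "node", attr.name = "valence",
          attr.type = "string"),
        c(id = "d1", `for` = "node", attr.name = "frequency",
          attr.type = "double"),
        c(id = "d2", `for` = "edge", attr.name = "weight",
          attr.type = "double"),
        c(id = "d3", `for` = "edge", attr.name = "masked",
          attr.type = "boolean"),
        c(id = "d4", `for` = "graph", attr.name = "n_reports",
          attr.type = "long"))) {
        kn <- xml2::xml_add_child(doc, "key")
        for (a in names(key)) xml2::xml_set_attr(kn, a, key[[a]])
    }
    g <- xml2::xml_add_child(doc, "graph", id = "emotions",
                             edgedefault = "undirected")
    dn <- xml2::xml_add_child(g, "data", key = "d4")
    xml2::xml_set_text(dn, as.character(W@nReports))
    val <- valence(W@taxonomy)
    for (e in emo) {
        nd <- xml2::xml_add_child(g, "node", id = e)
        d <- xml2::xml_add_child(nd, "data", key = "d0")
        xml2::xml_set_text(d, val[[e]])
        d <- xml2::xml_add_child(nd, "data", key = "d1")
        xml2::xml_set_text(d, .fmtDouble(freq[[e]]))
    }
    for (r in seq_len(nrow(ij))) {
        i <- ij[r, 1]; j <- ij[r, 2]
        ed <- xml2::xml_add_child(g, "edge", source = emo[i],
                                  target = emo[j])
        d <- xml2::xml_add_child(ed, "data", key = "d2")
        xml2::xml_set_text(d, .fmtDouble(W@W[i, j]))
        d <- xml2::xml_add_child(ed, "data", key = "d3")
        xml2::xml_set_text(d, if (W@mask[i, j]) "true" else "false")
    }
    tryCatch(xml2::write_xml(doc, path),
             error = function(e) stop("cannot write '", path, "': ",
                                      conditionMessage(e)))
    invisible(path)
}

#' Read an emotion network from disk
#'
#' Inverse of [writeNetwork()]. GraphML files are self-describing (node order
#' and valence define the taxonomy); for edge-list CSVs the taxonomy must be
#' supplied.
#'
#' @param path file path.
#' @param format \code{"edge_list_csv"} or \code{"graphml"}.
#' @param taxonomy an [EmotionTaxonomy-class], required for the edge-list
#'   format.
#' @return A [WeightMatrix-class].
#' @export
readNetwork <- function(path, format = c("edge_list_csv", "graphml"),
                        taxonomy = emotionTaxonomy()) {
    format <- match.arg(format)
    if (format == "edge_list_csv") {
        df <- utils::read.csv(path, stringsAsFactors = FALSE)
        emo <- emotions(taxonomy)
        W <- matrix(0, length(emo), length(emo), dimnames = list(emo, emo))
        i <- match(df$emotion_a, emo); j <- match(df$emotion_b, emo)
        if (anyNA(i) || anyNA(j))
            stop("edge list names emotions absent from the taxonomy")
        W[cbind(i, j)] <- df$weight
        W[cbind(j, i)] <- df$weight
        return(new("WeightMatrix", W = W,
                   mask = matrix(FALSE, length(emo), length(emo),
                                 dimnames = list(emo, emo)),
                   nReports = NA_integer_, taxonomy = taxonomy))
    }
    doc <- xml2::read_xml(path)
    ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
    keys <- xml2::xml_find_all(doc, ".//g:key", ns)
    keymap <- setNames(xml2::xml_attr(keys, "attr.name"),
                       xml2::xml_attr(keys, "id"))
    nodes <- xml2::xml_find_all(doc, ".//g:node", ns)
    emo <- xml2::xml_attr(nodes, "id")
    nodeAttr <- function(nd, name) {
        d <- xml2::xml_find_all(nd, "./g:data", ns)
        ids <- xml2::xml_attr(d, "key")
        hit <- which(keymap[ids] == name)
        if (!length(hit)) NA_character_ else xml2::xml_text(d[[hit[1]]])
    }
    val <- vapply(nodes, nodeAttr, "", name = "valence")
    freq <- as.numeric(vapply(nodes, nodeAttr, "", name = "frequency"))
    tax <- new("EmotionTaxonomy", emotions = emo,
               valence = setNames(val, emo))
    k <- length(emo)
    W <- matrix(0, k, k, dimnames = list(emo, emo))
    mask <- matrix(FALSE, k, k, dimnames = list(emo, emo))
    edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
    for (ed in edges) {
        i <- match(xml2::xml_attr(ed, "source"), emo)
        j <- match(xml2::xml_attr(ed, "target"), emo)
        w <- as.numeric(nodeAttr(ed, "weight"))
        m <- identical(nodeAttr(ed, "masked"), "true")
        W[i, j] <- W[j, i] <- w
        mask[i, j] <- mask[j, i] <- m
    }
    gn <- xml2::xml_find_first(doc, ".//g:graph/g:data", ns)
    nrep <- suppressWarnings(as.integer(xml2::xml_text(gn)))
    res <- new("WeightMatrix", W = W, mask = mask,
               nReports = if (is.na(nrep)) NA_integer_ else nrep,
               taxonomy = tax)
    attr(res, "frequencies") <- setNames(freq, emo)
    res
}
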