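# Tab-separated, header-row, UTF-8 readers and writers for the pipeline's
# interchange formats, plus network exports (SIF, GraphML).

#' Read and write long score / peptide / label tables
#'
#' All files are tab-separated with a header row. A score table has columns
#' `protein_id`, `sample_id`, `score`, `score_type`; a peptide table
#' `protein_id`, `sample_id`, `observed_peptides`, `observable_peptides`; a
#' label table `sample_id`, `class` and optionally `subject`.
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return readers return a data.frame; writers return `path` invisibly.
#' @name table-io
NULL

.readTSV <- function(path, required) {
    d <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
    miss <- setdiff(required, names(d))
    if (length(miss))
        stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
    d
}

#' @rdname table-io
#' @export
readPeptideTable <- function(path) {
    .readTSV(path, c("protein_id", "sample_id", "observed_peptides",
                     "observable_peptides"))
}

#' @rdname table-io
#' @export
readScoreTable <- function(path) {
    .readTSV(path, c("protein_id", "sample_id", "score"))
}

#' @rdname table-io
#' @export
readLabels <- function(path) {
    .readTSV(path, c("sample_id", "class"))
}

#' @rdname table-io
#' @export
writeTable <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Write / read a QuantMatrix as a wide TSV with a JSON sidecar
#'
#' The wide TSV has one row per feature (first column `feature_id`,
#' `"accession|score_type"`) and one column per sample; the JSON sidecar
#' (`<path>.json`) records sample classes, subjects and provenance.
#'
#' @param x a [QuantMatrix-class].
#' @param path TSV path; the sidecar is written next to it.
#' @return `writeQuantMatrix()`: `path` invisibly; `readQuantMatrix()`: a
#'   [QuantMatrix-class].
#' @export
writeQuantMatrix <- function(x, path) {
    stopifnot(is(x, "QuantMatrix"))
    wide <- data.frame(feature_id = rownames(x), scoreMatrix(x),
                       check.names = FALSE)
    writeTable(wide, path)
    side <- list(classes = as.list(sampleClasses(x)),
                 provenance = metadata(x)$provenance)
    if ("subject" %in% colnames(colData(x)))
        side$subjects <- as.list(stats::setNames(colData(x)$subject,
                                                 colnames(x)))
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeQuantMatrix
#' @export
readQuantMatrix <- function(path) {
    wide <- .readTSV(path, "feature_id")
    side <- jsonlite::read_json(paste0(path, ".json"))
    fid <- wide$feature_id
    m <- as.matrix(wide[, -1, drop = FALSE])
    parts <- regmatches(fid, regexec("^(.*)\\|(empai|probability)$", fid))
    if (any(lengths(parts) != 3L))
        stop("malformed feature_id(s); expected 'accession|score_type'")
    rownames(m) <- vapply(parts, `[[`, character(1), 2L)
    classes <- unlist(side$classes)
    subjects <- if (!is.null(side$subjects)) unlist(side$subjects) else NULL
    QuantMatrix(m, vapply(parts, `[[`, character(1), 3L),
                classes = classes[colnames(m)], subjects = subjects,
                provenance = if (is.null(side$provenance)) ""
                             else side$provenance)
}

#' Export a pair network
#'
#' `writeSIF()` writes one line per edge, `featureA  pair_<class>  featureB`
#' (tab-separated). `writeGraphML()` writes a GraphML document whose edges
#' carry `class`, `count` and a display `colour` attribute: blue for the
#' IL-1β class, red for carprofen, green for IL-1β + carprofen, grey
#' otherwise.
#'
#' @param net a [buildNetwork()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSIF <- function(net, path) {
    stopifnot(inherits(net, "PairNetwork"))
    lines <- sprintf("%s\tpair_%s\t%s", net$edges$a, net$edges$class,
                     net$edges$b)
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

.classColour <- function(class) {
    cols <- c(IL1b = "blue", carprofen = "red", IL1b_carprofen = "green")
    ifelse(class %in% names(cols), cols[class], "grey")
}

.xmlEscape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
}

#' @rdname writeSIF
#' @export
writeGraphML <- function(net, path) {
    stopifnot(inherits(net, "PairNetwork"))
    e <- net$edges
    lines <- c(
        "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
        "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
        "  <key id=\"class\" for=\"edge\" attr.name=\"class\" attr.type=\"string\"/>",
        "  <key id=\"count\" for=\"edge\" attr.name=\"count\" attr.type=\"int\"/>",
        "  <key id=\"colour\" for=\"edge\" attr.name=\"colour\" attr.type=\"string\"/>",
        "  <graph id=\"pairs\" edgedefault=\"undirected\">",
        sprintf("    <node id=\"%s\"/>", .xmlEscape(net$nodes)))
    if (nrow(e)) {
        lines <- c(lines, sprintf(paste0(
            "    <edge source=\"%s\" target=\"%s\">",
            "<data key=\"class\">%s</data>",
            "<data key=\"count\">%d</data>",
            "<data key=\"colour\">%s</data></edge>"),
            .xmlEscape(e$a), .xmlEscape(e$b), .xmlEscape(e$class),
            as.integer(e$count), .classColour(e$class)))
    }
    lines <- c(lines, "  </graph>", "</graphml>")
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' Write per-class protein rankings as TSV
#'
#' One file per class, `<dir>/ranking_<class>.tsv`, with columns `rank`,
#' `feature`, `count`, `share`.
#'
#' @param ranking a [rankProteins()] result.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
writeRankingTSV <- function(ranking, dir) {
    stopifnot(inherits(ranking, "ProteinRanking"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- character()
    for (cls in names(ranking$perClass)) {
        d <- ranking$perClass[[cls]]
        out <- data.frame(rank = seq_len(nrow(d)), d)
        p <- file.path(dir, sprintf("ranking_%s.tsv", cls))
        writeTable(out, p)
        paths <- c(paths, p)
    }
    invisible(paths)
}
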