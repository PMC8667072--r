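#' Read a STRING-links edge file
#'
#' Parses the STRING protein-links dialect: whitespace-separated columns
#' \code{protein1 protein2 combined_score}, an optional single header line,
#' plain text or gzip. Directed duplicates are collapsed to one undirected
#' edge (conflicting scores resolved to the maximum and reported); self-loops
#' are dropped with a warning. The node universe is every identifier
#' appearing on a retained edge — there is no external node roster.
#'
#' @param path path to the links file (\code{.gz} accepted).
#' @param minConfidence integer in [1, 999]; edges with a lower combined
#'   score are discarded before the node universe is formed. Default 1
#'   (keep everything).
#' @return a [PPINetwork-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("protein1 protein2 combined_score",
#'              "a b 700", "b a 700", "b c 950"), f)
#' readStringLinks(f)
#' @export
readStringLinks <- function(path, minConfidence = 1L) {
    stopifnot(length(path) == 1L)
    if (!file.exists(path))
        stop("file not found: ", path)
    .assertScalar(minConfidence, "minConfidence", 1, 999)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    keep <- nzchar(trimws(lines))
    lineNo <- seq_along(lines)[keep]
    lines <- lines[keep]
    if (length(lines) == 0L)
        stop("empty links file: ", path)
    fields <- strsplit(trimws(lines), "[ \t]+")
    # optional single header: first line whose third column is not a number
    if (length(fields[[1]]) >= 3L &&
        is.na(suppressWarnings(as.numeric(fields[[1]][3])))) {
        fields <- fields[-1L]
        lineNo <- lineNo[-1L]
    }
    if (length(fields) == 0L)
        stop("no data lines in links file: ", path)
    bad <- which(lengths(fields) < 3L)
    if (length(bad))
        stop("malformed line ", lineNo[bad[1]],
             ": expected 'protein1 protein2 combined_score'")
    from <- vapply(fields, `[`, "", 1L)
    to <- vapply(fields, `[`, "", 2L)
    score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    bad <- which(is.na(score) | score != round(score))
    if (length(bad))
        stop("malformed line ", lineNo[bad[1]],
             ": combined_score is not an integer")
    bad <- which(score < 1 | score > 999)
    if (length(bad))
        stop("invalid score ", score[bad[1]], " on line ", lineNo[bad[1]],
             ": combined scores range from 1 to 999")
    self <- from == to
    if (any(self)) {
        warning(sum(self), " self-loop line(s) dropped")
        from <- from[!self]; to <- to[!self]; score <- score[!self]
    }
    # collapse directed duplicates before confidence filtering so that the
    # max-score rule acts on the full input
    a <- pmin(from, to); b <- pmax(from, to)
    key <- paste(a, b, sep = "\r")
    first <- !duplicated(key)
    mx <- tapply(score, key, max)[key[first]]
    mn <- tapply(score, key, min)[key[first]]
    nconf <- sum(mx != mn)
    if (nconf > 0L)
        message(nconf, " edge(s) with conflicting duplicate scores; ",
                "maximum kept")
    a <- a[first]; b <- b[first]; score <- as.numeric(mx)
    keep <- score >= minConfidence
    if (!any(keep))
        stop("no edges left after filtering at minConfidence = ",
             minConfidence)
    PPINetwork(data.frame(from = a[keep], to = b[keep],
                          confidence = score[keep]))
}

#' Write a network in the STRING-links dialect
#'
#' One line per undirected edge, space-separated, with the standard header.
#' Reloading with [readStringLinks()] reproduces the network exactly.
#'
#' @param network a [PPINetwork-class].
#' @param path output path; a \code{.gz} suffix triggers gzip compression.
#' @return \code{path}, invisibly.
#' @export
writeStringLinks <- function(network, path) {
    et <- edgeTable(network)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    writeLines(c("protein1 protein2 combined_score",
                 paste(et$from, et$to, et$confidence)), con)
    invisible(path)
}

#' Read a disease seed-gene list
#'
#' One gene ID per line; blank lines and \code{#} comment lines are skipped.
#' The list is intersected with the network's nodes; identifiers that do not
#' map are counted and reported, and an error is raised if none map.
#'
#' @param path path to the gene list.
#' @param network the [PPINetwork-class] the seeds must resolve against.
#' @return character vector of seed genes present in the network (sorted);
#'   the number of unmapped IDs is attached as attribute \code{"unmapped"}.
#' @export
readGeneList <- function(path, network) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    ids <- unique(lines)
    found <- intersect(ids, nodes(network))
    nUnmapped <- length(ids) - length(found)
    if (length(found) == 0L)
        stop("no seed genes found in network")
    if (nUnmapped > 0L)
        message(nUnmapped, " seed gene(s) not present in the network; dropped")
    structure(.lexSort(found), unmapped = nUnmapped)
}

#' Read / write an annotation corpus in GMT format
#'
#' Standard gene-set format: one term per line, tab-separated
#' \code{term-id <TAB> description <TAB> gene1 <TAB> gene2 ...}. The first
#' whitespace-delimited token of the description field is taken as the
#' namespace tag (\code{BP}, \code{CC}, \code{MF} or \code{KEGG}).
#'
#' @param path path to a GMT file.
#' @return for \code{readGMT}, an [AnnotationCorpus-class].
#' @export
readGMT <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 3L)
    if (length(bad))
        stop("malformed GMT line ", bad[1],
             ": need term, description and at least one gene")
    ids <- vapply(fields, `[`, "", 1L)
    ns <- vapply(strsplit(vapply(fields, `[`, "", 2L), "[ \t]+"), `[`, "", 1L)
    sets <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(sets) <- ids
    AnnotationCorpus(sets, ns)
}

#' @rdname readGMT
#' @param corpus an [AnnotationCorpus-class] to write.
#' @return for \code{writeGMT}, \code{path} invisibly.
#' @export
writeGMT <- function(corpus, path) {
    lines <- vapply(seq_along(corpus@sets), function(k) {
        paste(c(names(corpus@sets)[k], corpus@namespace[k],
                corpus@sets[[k]]), collapse = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}
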