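#' Construct a PPINetwork from an edge table
#'
#' Builds the undirected weighted network used throughout the screen. Nodes
#' are taken from the edges (plus any extra isolated nodes passed in
#' \code{nodes}) and stored in lexicographic order. Duplicate edges (in either
#' orientation) are collapsed to a single undirected edge; when duplicates
#' disagree on the confidence the maximum is kept and the conflict is
#' reported. Self-loops are dropped with a warning.
#'
#' @param edges data.frame with columns \code{from}, \code{to},
#'   \code{confidence} (integer scores in [1, 999]).
#' @param nodes optional character vector of additional node IDs to include
#'   (they may end up isolated).
#' @return a [PPINetwork-class] object.
#' @examples
#' net <- PPINetwork(data.frame(from = c("a", "b"), to = c("b", "c"),
#'                              confidence = c(700, 950)))
#' numEdges(net)
#' @export
PPINetwork <- function(edges, nodes = NULL) {
    stopifnot(is.data.frame(edges),
              all(c("from", "to", "confidence") %in% names(edges)))
    from <- as.character(edges$from)
    to <- as.character(edges$to)
    conf <- as.numeric(edges$confidence)
    if (anyNA(conf) || any(conf != round(conf)) ||
        any(conf < 1) || any(conf > 999))
        stop("edge confidences must be integers in [1, 999]")
    self <- from == to
    if (any(self)) {
        warning(sum(self), " self-loop(s) dropped")
        from <- from[!self]; to <- to[!self]; conf <- conf[!self]
    }
    ids <- .lexSort(unique(c(from, to, as.character(nodes))))
    if (length(ids) == 0L)
        stop("network is empty")
    i <- match(from, ids)
    j <- match(to, ids)
    # canonical orientation, then collapse duplicates to the max confidence
    lo <- pmin(i, j); hi <- pmax(i, j)
    key <- (lo - 1) * length(ids) + hi
    if (anyDuplicated(key)) {
        mx <- tapply(conf, key, max)
        mn <- tapply(conf, key, min)
        nconf <- sum(mx != mn)
        if (nconf > 0L)
            message(nconf, " duplicate edge(s) with conflicting scores; ",
                    "maximum kept")
        ukey <- as.numeric(names(mx))
        lo <- (ukey - 1) %/% length(ids) + 1
        hi <- (ukey - 1) %% length(ids) + 1
        conf <- as.numeric(mx)
    }
    A <- Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo),
                              x = c(conf, conf),
                              dims = c(length(ids), length(ids)),
                              dimnames = list(ids, ids), use.last.ij = TRUE)
    new("PPINetwork", nodes = ids, adjacency = A)
}

#' @describeIn PPINetwork node identifiers, in the fixed lexicographic order
#' @param x a \code{PPINetwork}
#' @param ... unused
#' @export
setMethod("nodes", "PPINetwork", function(x, ...) x@nodes)

#' @describeIn PPINetwork number of nodes
#' @export
setMethod("numNodes", "PPINetwork", function(x) length(x@nodes))

#' @describeIn PPINetwork number of undirected edges
#' @export
setMethod("numEdges", "PPINetwork",
    function(x) length(x@adjacency@x) %/% 2L)

#' @describeIn PPINetwork symmetric sparse confidence (adjacency) matrix
#' @export
setMethod("adjacencyMatrix", "PPINetwork", function(x) x@adjacency)

#' @describeIn PPINetwork undirected edge list as a data.frame
#'   (\code{from} < \code{to} in node order) with confidences
#' @export
setMethod("edgeTable", "PPINetwork", function(x) {
    A <- as(Matrix::triu(x@adjacency), "TsparseMatrix")
    o <- .lexOrder(x@nodes[A@i + 1L], x@nodes[A@j + 1L])
    data.frame(from = x@nodes[A@i + 1L][o], to = x@nodes[A@j + 1L][o],
               confidence = as.integer(A@x[o]))
})

#' @describeIn PPINetwork vectorised confidence lookup Q(from, to); 0 when no
#'   edge exists
#' @param from,to character vectors of gene IDs (recycled to equal length)
#' @export
setMethod("confidence", "PPINetwork", function(x, from, to) {
    i <- match(from, x@nodes); j <- match(to, x@nodes)
    if (anyNA(i) || anyNA(j))
        stop("gene(s) not in network: ",
             paste(unique(c(from[is.na(i)], to[is.na(j)])), collapse = ", "))
    as.integer(x@adjacency[cbind(i, j)])
})

#' @describeIn PPINetwork a gene's network neighbourhood: the gene itself plus
#'   all direct interactors, at any confidence
#' @param gene a single gene ID
#' @export
setMethod("neighborhood", "PPINetwork", function(x, gene) {
    stopifnot(length(gene) == 1L)
    k <- match(gene, x@nodes)
    if (is.na(k))
        stop("gene not in network: ", gene)
    .lexSort(unique(c(gene, x@nodes[x@adjacency[, k] > 0])))
})

#' Column-stochastic transition operator of a network
#'
#' Entry (i, j) is \code{Q(i, j) / weighted-degree(j)}: a walker at node j
#' moves to neighbour i with probability proportional to the edge confidence.
#' Every column sums to one, so applying the operator to a probability vector
#' conserves total mass. Isolated nodes (possible after confidence filtering)
#' get a self-transition of 1 to keep the operator stochastic; they can only
#' hold mass if seeded.
#'
#' @param x a [PPINetwork-class]
#' @return a sparse column-stochastic matrix aligned to \code{nodes(x)}.
#' @export
setMethod("transitionMatrix", "PPINetwork", function(x) {
    A <- x@adjacency
    d <- Matrix::colSums(A)
    iso <- which(d == 0)
    if (length(iso)) {
        A <- A + Matrix::sparseMatrix(i = iso, j = iso,
                                      x = rep(1, length(iso)),
                                      dims = dim(A), dimnames = dimnames(A))
        d[iso] <- 1
    }
    P <- A %*% Matrix::Diagonal(x = 1 / d, names = FALSE)
    dimnames(P) <- dimnames(A)
    P
})

setMethod("show", "PPINetwork", function(object) {
    cat("PPINetwork with", numNodes(object), "nodes and",
        numEdges(object), "edges\n")
    rng <- range(object@adjacency@x)
    if (numEdges(object) > 0L)
        cat("  confidence range:", rng[1], "-", rng[2], "\n")
    cat("  nodes:", paste(utils::head(object@nodes, 5L), collapse = ", "),
        if (numNodes(object) > 5L) "..." else "", "\n")
})
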