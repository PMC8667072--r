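# upper-tail hypergeometric -log10 p, vectorised, computed in log space.
# k = observed overlap, K = term size, n = neighbourhood size, N = universe.
.negLog10HyperTail <- function(k, K, n, N, cap = 300) {
    lp <- phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
    pmin(-lp / log(10), cap)
}

#' Hypergeometric association between a neighbourhood and a term
#'
#' One-sided over-representation tail: the probability that a random
#' neighbourhood-sized draw from the universe contains at least the observed
#' number of the term's genes. Returned as \code{-log10 p}, capped at 300 and
#' evaluated in log space so extreme enrichments do not underflow. An overlap
#' of zero gives p = 1 and value 0.
#'
#' @param neighborhood character vector of genes (a gene plus its direct
#'   interactors).
#' @param termSet character vector of genes annotated by the term.
#' @param universe character vector, the reference gene universe (all network
#'   nodes, by default, in the pipeline).
#' @return a single non-negative number, \code{-log10 p}.
#' @examples
#' # universe 10, term 5, neighbourhood 4, all 4 in the term:
#' # p = choose(5,4)/choose(10,4) = 5/210
#' hyperGeomScore(letters[1:4], letters[1:5], letters[1:10])
#' @export
hyperGeomScore <- function(neighborhood, termSet, universe) {
    if (length(universe) == 0L)
        stop("universe must be non-empty")
    nb <- intersect(unique(neighborhood), universe)
    ts <- intersect(unique(termSet), universe)
    if (length(nb) == 0L || length(ts) == 0L) {
        warning("empty neighbourhood or term set; association set to 0")
        return(0)
    }
    .negLog10HyperTail(length(intersect(nb, ts)), length(ts), length(nb),
                       length(unique(universe)))
}

#' Enrichment vectors of genes over an annotation corpus
#'
#' For each gene, the vector V(g) of \code{-log10} hypergeometric tail
#' p-values of its network neighbourhood against every corpus term, in the
#' corpus' fixed term order. Two genes with similar functional context have
#' similar vectors, which is what the maximum function score exploits.
#'
#' @param network a [PPINetwork-class].
#' @param genes character vector of genes to profile.
#' @param corpus an [AnnotationCorpus-class].
#' @param universe reference universe; default all network nodes.
#' @return numeric matrix, genes x terms; \code{enrichmentVector} returns the
#'   single row as a named vector.
#' @export
enrichmentVectors <- function(network, genes, corpus,
                              universe = nodes(network)) {
    genes <- as.character(genes)
    idx <- match(genes, nodes(network))
    if (anyNA(idx))
        stop("gene(s) not in network: ",
             paste(genes[is.na(idx)], collapse = ", "))
    uni <- .lexSort(unique(universe))
    N <- length(uni)
    # neighbourhood indicator rows (gene itself + interactors), restricted to
    # the universe; the universe may extend beyond the network (annotated
    # genes without interactions), in which case the extra columns are empty
    A <- adjacencyMatrix(network)
    NH <- Matrix::t(A[, idx, drop = FALSE] != 0)
    NH[cbind(seq_along(idx), idx)] <- TRUE
    cols <- match(uni, nodes(network))
    present <- which(!is.na(cols))
    NHu <- Matrix::Matrix(FALSE, nrow(NH), N, sparse = TRUE)
    NHu[, present] <- NH[, cols[present], drop = FALSE]
    NH <- NHu
    TM <- .termIndicator(corpus, uni)
    overlap <- as.matrix(NH %*% Matrix::t(TM))
    nNb <- Matrix::rowSums(NH)
    K <- Matrix::rowSums(TM)
    V <- .negLog10HyperTail(overlap,
                            matrix(K, nrow(overlap), ncol(overlap),
                                   byrow = TRUE),
                            matrix(nNb, nrow(overlap), ncol(overlap)),
                            N)
    dimnames(V) <- list(genes, termIds(corpus))
    V
}

#' @rdname enrichmentVectors
#' @param gene a single gene ID.
#' @export
enrichmentVector <- function(network, gene, corpus,
                             universe = nodes(network)) {
    stopifnot(length(gene) == 1L)
    enrichmentVectors(network, gene, corpus, universe)[1L, ]
}

#' Cosine similarity of two enrichment vectors
#'
#' \deqn{\Lambda(g, g') = V(g) \cdot V(g') / (\|V(g)\| \|V(g')\|)}
#' Lies in [0, 1] because enrichment vectors are non-negative; defined as 0
#' when either vector has zero norm.
#'
#' @param v1,v2 numeric vectors over the same term ordering.
#' @return cosine similarity in [0, 1].
#' @export
cosineSimilarity <- function(v1, v2) {
    if (length(v1) != length(v2))
        stop("enrichment vectors have different lengths")
    if (!is.null(names(v1)) && !is.null(names(v2)) &&
        !identical(names(v1), names(v2)))
        stop("enrichment vectors are over different term orderings")
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 == 0 || n2 == 0)
        return(0)
    min(1, sum(v1 * v2) / (n1 * n2))
}

#' Maximum function score (MFS)
#'
#' For each candidate, the largest cosine similarity between its enrichment
#' vector and that of any validated gene. Candidates functionally close to at
#' least one known disease gene score near 1.
#'
#' @param candidates character vector of candidate genes.
#' @param validated character vector of validated genes.
#' @param vectors numeric matrix of enrichment vectors (rows named by gene),
#'   covering all candidates and validated genes; see [enrichmentVectors()].
#' @return named numeric vector of MFS values in [0, 1]; 0 for a candidate
#'   with an all-zero vector.
#' @export
maxFunctionScore <- function(candidates, validated, vectors) {
    need <- unique(c(candidates, validated))
    miss <- setdiff(need, rownames(vectors))
    if (length(miss))
        stop("no enrichment vector for gene(s): ", paste(miss, collapse = ", "))
    if (length(candidates) == 0L)
        return(stats::setNames(numeric(0), character(0)))
    norm <- sqrt(rowSums(vectors^2))
    U <- vectors / ifelse(norm > 0, norm, 1)
    S <- U[candidates, , drop = FALSE] %*% t(U[validated, , drop = FALSE])
    stats::setNames(pmin(1, apply(S, 1L, max)), candidates)
}

#' Over-representation test of a gene set against a corpus
#'
#' Classic per-term one-sided hypergeometric test (no graph decorrelation, no
#' ancestry propagation, no multiple-testing correction): for each term, the
#' probability that a random gene set of the same size contains at least the
#' observed number of the term's genes. Terms with uncorrected p strictly
#' below \code{pCutoff} are returned sorted by p ascending, with their
#' namespace so results can be partitioned into BP/CC/MF.
#'
#' @param genes non-empty character vector (e.g. the putative genes).
#' @param corpus an [AnnotationCorpus-class].
#' @param universe the background gene universe.
#' @param pCutoff reporting threshold on the raw p-value; default 0.001.
#' @return a [S4Vectors::DataFrame] with columns \code{term},
#'   \code{namespace}, \code{pValue}, \code{overlap}, \code{size}.
#' @export
goEnrichment <- function(genes, corpus, universe, pCutoff = 0.001) {
    genes <- unique(as.character(genes))
    if (length(genes) == 0L)
        stop("gene set is empty")
    uni <- unique(universe)
    if (!all(genes %in% uni))
        stop("gene(s) outside the universe: ",
             paste(setdiff(genes, uni), collapse = ", "))
    sets <- lapply(geneSets(corpus), intersect, uni)
    K <- lengths(sets)
    k <- vapply(sets, function(s) length(intersect(s, genes)), 0L)
    p <- phyper(k - 1, K, length(uni) - K, length(genes),
                lower.tail = FALSE)
    # strict "<" mirrors the reporting rule "p-value less than the cutoff";
    # a cutoff of 1 disables filtering (every term is returned)
    keep <- which((p < pCutoff | pCutoff >= 1) & K > 0L)
    o <- keep[.lexOrder(p[keep], termIds(corpus)[keep])]
    DataFrame(term = termIds(corpus)[o],
              namespace = unname(termNamespace(corpus)[o]),
              pValue = unname(p[o]), overlap = unname(k[o]),
              size = unname(as.integer(K[o])))
}
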