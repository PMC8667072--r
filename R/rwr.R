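#' Build the initial probability vector from a seed set
#'
#' Each of the k seed genes receives probability 1/k, all other nodes 0; the
#' vector is renormalised so it sums to exactly 1.
#'
#' @param network a [PPINetwork-class].
#' @param seeds character vector of seed genes, all present in the network.
#' @return named numeric vector aligned to \code{nodes(network)}.
#' @export
seedVector <- function(network, seeds) {
    seeds <- unique(as.character(seeds))
    if (length(seeds) == 0L)
        stop("seed set is empty")
    idx <- match(seeds, nodes(network))
    if (anyNA(idx))
        stop("seed gene(s) not in network: ",
             paste(seeds[is.na(idx)], collapse = ", "))
    p0 <- numeric(numNodes(network))
    names(p0) <- nodes(network)
    p0[idx] <- 1 / length(seeds)
    p0 / sum(p0)
}

#' Random walk with restart
#'
#' Iterates \deqn{P_{t+1} = (1 - r) A P_t + r P_0} where \code{A} is the
#' column-stochastic transition operator and \code{r} the restart
#' probability, until the L1 change between successive iterates falls below
#' \code{tol}. Because the walker either moves along an edge or teleports
#' back to the seed distribution, every iterate is itself a probability
#' vector (total mass 1). The converged vector scores each node's proximity
#' to the seeds; a higher restart probability keeps mass closer to them.
#'
#' @param operator column-stochastic sparse matrix from
#'   [transitionMatrix()].
#' @param p0 initial probability vector (non-negative, sums to 1) aligned to
#'   the operator.
#' @param restart restart probability r in (0, 1]; default 0.8.
#' @param tol L1 convergence tolerance; default 1e-6.
#' @param maxIter iteration cap; exceeding it is an error, not a warning.
#' @return named numeric probability vector, with attributes
#'   \code{iterations} and \code{delta} (final L1 change).
#' @examples
#' net <- PPINetwork(data.frame(from = c("a", "b"), to = c("b", "c"),
#'                              confidence = c(500, 500)))
#' p <- randomWalk(transitionMatrix(net), seedVector(net, "a"))
#' round(p, 4)  # close to (49, 10, 1)/60
#' @export
randomWalk <- function(operator, p0, restart = 0.8, tol = 1e-6,
                       maxIter = 10000L) {
    .assertScalar(restart, "restart", 1e-12, 1)
    .assertScalar(tol, "tol", .Machine$double.xmin, Inf)
    n <- length(p0)
    if (!identical(dim(operator), c(n, n)))
        stop("operator and p0 are not dimensionally aligned")
    if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-9)
        stop("p0 must be a probability vector (non-negative, sum 1)")
    p <- as.numeric(p0)
    for (it in seq_len(maxIter)) {
        pNext <- (1 - restart) * as.numeric(operator %*% p) + restart * p0
        delta <- sum(abs(pNext - p))
        p <- pNext
        if (delta < tol) {
            names(p) <- names(p0)
            attr(p, "iterations") <- it
            attr(p, "delta") <- delta
            return(p)
        }
    }
    stop("random walk did not converge in ", maxIter,
         " iterations (last L1 change ", format(delta), ")")
}

#' Convenience wrapper: RWR from a seed set on a network
#'
#' @inheritParams randomWalk
#' @inheritParams seedVector
#' @return as [randomWalk()].
#' @export
rwr <- function(network, seeds, restart = 0.8, tol = 1e-6, maxIter = 10000L) {
    randomWalk(transitionMatrix(network), seedVector(network, seeds),
               restart = restart, tol = tol, maxIter = maxIter)
}

#' Select raw candidate genes from a converged probability vector
#'
#' Nodes whose probability is strictly greater than the cutoff become raw
#' candidates; seed genes are excluded by default because the screen targets
#' novel genes (set \code{includeSeeds = TRUE} for diagnostics). Candidates
#' are sorted by probability descending, ties broken lexicographically.
#'
#' @param p named probability vector from [randomWalk()].
#' @param seeds character vector of seed genes to exclude.
#' @param cutoff probability cutoff, strict ">"; default 1e-5.
#' @param includeSeeds keep seed genes in the candidate list?
#' @return a [S4Vectors::DataFrame] with columns \code{gene},
#'   \code{probability}.
#' @export
selectCandidates <- function(p, seeds = character(), cutoff = 1e-5,
                             includeSeeds = FALSE) {
    .assertScalar(cutoff, "cutoff", 0, Inf)
    stopifnot(!is.null(names(p)))
    keep <- p > cutoff
    if (!includeSeeds)
        keep <- keep & !(names(p) %in% seeds)
    gene <- names(p)[keep]
    prob <- unname(p[keep])
    o <- .lexOrder(-prob, gene)
    if (length(gene) == 0L)
        message("no raw candidates above cutoff ", format(cutoff))
    DataFrame(gene = gene[o], probability = prob[o])
}

#' Export a probability vector as TSV
#'
#' Two columns (\code{gene_id}, \code{probability}), probabilities printed
#' with fixed 10-significant-digit formatting so output is byte-reproducible.
#'
#' @param p named probability vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProbabilities <- function(p, path) {
    df <- data.frame(gene_id = names(p), probability = .fmtNum(as.numeric(p)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
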