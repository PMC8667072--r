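# Independent oracles and small fixture builders used across the suite.

# dense closed-form RWR: P = r (I - (1 - r) M)^{-1} P0, with M the
# column-stochastic normalisation of the dense adjacency. Never shares code
# with the iterative implementation.
rwrDense <- function(adj, p0, r) {
    d <- colSums(adj)
    d[d == 0] <- 1
    M <- sweep(adj, 2, d, "/")
    M[, colSums(adj) == 0] <- 0
    diag(M)[colSums(adj) == 0] <- 1
    as.numeric(solve(diag(nrow(adj)) - (1 - r) * M, r * p0))
}

# exact hypergeometric upper tail P(X >= k) by direct combinatorial sum
hyperTailExact <- function(k, K, n, N) {
    hi <- min(K, n)
    if (k > hi) return(0)
    j <- max(k, 0):hi
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# tiny deterministic networks
pathNet <- function(w1 = 500, w2 = 500) {
    PPINetwork(data.frame(from = c("a", "b"), to = c("b", "c"),
                          confidence = c(w1, w2)))
}

starNet <- function() {
    PPINetwork(data.frame(from = "h", to = c("x", "y", "z"),
                          confidence = 999))
}

# connected random weighted network for property tests
randomNet <- function(nNodes, seed, pEdge = 0.25) {
    set.seed(seed)
    ids <- sprintf("n%03d", seq_len(nNodes))
    pairs <- combn(ids, 2L)
    keep <- runif(ncol(pairs)) < pEdge
    # always keep the chain n001-n002, n002-n003, ... so the graph is
    # connected (isolate-free), which the mass-conservation property assumes
    keep <- keep | (paste(pairs[1, ], pairs[2, ]) %in%
                        paste(ids[-nNodes], ids[-1]))
    PPINetwork(data.frame(from = pairs[1, keep], to = pairs[2, keep],
                          confidence = sample(1:999, sum(keep),
                                              replace = TRUE)))
}

# tiny annotation corpus over a fixed gene universe
toyCorpus <- function() {
    AnnotationCorpus(list(T1 = c("a", "b", "c"),
                          T2 = c("c", "d"),
                          T3 = c("a", "e", "f", "g"),
                          T4 = c("h", "i"),
                          T5 = c("b", "c", "d", "e")),
                     c("BP", "CC", "MF", "BP", "CC"))
}

fixturePath <- function(name) {
    system.file("extdata", name, package = "NetScreen", mustWork = TRUE)
}
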