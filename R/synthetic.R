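#' Specification of a synthetic planted-module benchmark
#'
#' Describes the generative model used for testing without database
#' downloads: a scale-free background network grown by preferential
#' attachment (emulating the heavy-tailed degree distribution of
#' protein-interaction networks), a planted disease module wired as a
#' near-clique at high confidence and attached sparsely to the background,
#' and an annotation corpus in which a fraction of terms preferentially
#' annotate module members.
#'
#' @param nBackground number of background genes; default 500.
#' @param moduleSize planted-module size (>= 2); default 20.
#' @param seedFraction fraction of module members designated seeds, in
#'   (0, 1); \code{ceiling(seedFraction * moduleSize)} members become seeds;
#'   default 0.5.
#' @param intraConfidence integer range of intra-module edge confidences;
#'   default \code{c(900, 999)} (STRING's highest-confidence tier).
#' @param backgroundConfidence integer range for background and
#'   module-to-background edges; default \code{c(150, 700)}.
#' @param attachment preferential-attachment parameter (edges added per new
#'   node, >= 1); default 2, giving a mean degree near 4 as in sparse PPI
#'   networks.
#' @param moduleDensity probability that an intra-module gene pair is
#'   connected; default 0.9 (near-clique).
#' @param nTerms number of annotation terms; default 60.
#' @param termModuleBias fraction of terms biased toward module members, in
#'   [0, 1]; default 0.8.
#' @param rngSeed integer RNG seed; the whole benchmark is deterministic
#'   given this value.
#' @return a validated list of class \code{"SyntheticSpec"}.
#' @export
syntheticSpec <- function(nBackground = 500L, moduleSize = 20L,
                          seedFraction = 0.5,
                          intraConfidence = c(900L, 999L),
                          backgroundConfidence = c(150L, 700L),
                          attachment = 2L, moduleDensity = 0.9,
                          nTerms = 60L, termModuleBias = 0.8, rngSeed = 1L) {
    .assertScalar(nBackground, "nBackground", 2, Inf)
    .assertScalar(moduleSize, "moduleSize", 2, Inf)
    .assertScalar(seedFraction, "seedFraction", 1e-9, 1 - 1e-9)
    .assertScalar(attachment, "attachment", 1, Inf)
    .assertScalar(moduleDensity, "moduleDensity", 0, 1)
    .assertScalar(nTerms, "nTerms", 1, Inf)
    .assertScalar(termModuleBias, "termModuleBias", 0, 1)
    stopifnot(length(intraConfidence) == 2L,
              length(backgroundConfidence) == 2L,
              all(intraConfidence >= 1), all(intraConfidence <= 999),
              all(backgroundConfidence >= 1),
              all(backgroundConfidence <= 999),
              diff(intraConfidence) >= 0, diff(backgroundConfidence) >= 0)
    if (ceiling(seedFraction * moduleSize) >= moduleSize)
        stop("seedFraction leaves no latent targets in the module")
    structure(list(nBackground = as.integer(nBackground),
                   moduleSize = as.integer(moduleSize),
                   seedFraction = seedFraction,
                   intraConfidence = as.integer(intraConfidence),
                   backgroundConfidence = as.integer(backgroundConfidence),
                   attachment = as.integer(attachment),
                   moduleDensity = moduleDensity,
                   nTerms = as.integer(nTerms),
                   termModuleBias = termModuleBias,
                   rngSeed = as.integer(rngSeed)),
              class = "SyntheticSpec")
}

.sampleConf <- function(range, n) {
    if (range[1] == range[2]) rep(range[1], n)
    else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate a synthetic network with a planted disease module
#'
#' The background is grown by preferential attachment, giving the heavy-
#' tailed degree distribution typical of protein-interaction networks. A
#' module of \code{moduleSize} extra genes is planted as a near-clique with
#' confidences drawn from \code{intraConfidence}, each module gene also
#' attached to one random background gene at background confidence. If the
#' assembled graph is disconnected, bridge edges to the largest component are
#' added (and reported). A fraction of module members becomes the seed set;
#' the rest are the latent targets a screen should recover.
#'
#' @param spec a [syntheticSpec()].
#' @return list with elements \code{network} (a [PPINetwork-class]) and
#'   \code{truth} (a [SyntheticTruth-class]).
#' @examples
#' sim <- simulateNetwork(syntheticSpec(nBackground = 50, moduleSize = 6,
#'                                      rngSeed = 7))
#' sim$truth
#' @export
simulateNetwork <- function(spec) {
    stopifnot(inherits(spec, "SyntheticSpec"))
    set.seed(spec$rngSeed)
    bg <- sprintf("g%05d", seq_len(spec$nBackground))
    mod <- sprintf("m%03d", seq_len(spec$moduleSize))
    g <- igraph::sample_pa(spec$nBackground, power = 1,
                           m = spec$attachment, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    # sample_pa can emit duplicate pairs; the constructor collapses them
    edges <- data.frame(from = bg[el[, 1]], to = bg[el[, 2]],
                        confidence = .sampleConf(spec$backgroundConfidence,
                                                 nrow(el)))
    pairs <- utils::combn(mod, 2L)
    keep <- stats::runif(ncol(pairs)) < spec$moduleDensity
    if (sum(keep) < spec$moduleSize - 1L)  # degenerate density: keep a path
        keep[seq_len(ncol(pairs))] <- TRUE
    modEdges <- data.frame(from = pairs[1, keep], to = pairs[2, keep],
                           confidence = .sampleConf(spec$intraConfidence,
                                                    sum(keep)))
    anchor <- data.frame(from = mod,
                         to = sample(bg, spec$moduleSize, replace = TRUE),
                         confidence = .sampleConf(spec$backgroundConfidence,
                                                  spec$moduleSize))
    edges <- rbind(edges, modEdges, anchor)
    edges <- edges[edges$from != edges$to, ]
    # guarantee one connected component
    ig <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                        vertices = c(bg, mod))
    comp <- igraph::components(ig)
    if (comp$no > 1L) {
        giant <- which.max(comp$csize)
        deg <- igraph::degree(ig)
        inGiant <- names(comp$membership)[comp$membership == giant]
        hub <- inGiant[which.max(deg[inGiant])]
        outside <- split(names(comp$membership)[comp$membership != giant],
                         comp$membership[comp$membership != giant])
        bridge <- vapply(outside, `[`, "", 1L)
        message(length(bridge), " bridge edge(s) added to connect the graph")
        edges <- rbind(edges,
                       data.frame(from = bridge, to = hub,
                                  confidence = .sampleConf(
                                      spec$backgroundConfidence,
                                      length(bridge))))
    }
    network <- PPINetwork(edges, nodes = c(bg, mod))
    nSeeds <- ceiling(spec$seedFraction * spec$moduleSize)
    seeds <- .lexSort(sample(mod, nSeeds))
    truth <- new("SyntheticTruth", moduleMembers = mod, seeds = seeds,
                 latentTargets = setdiff(mod, seeds))
    list(network = network, truth = truth)
}

#' Generate a synthetic annotation corpus
#'
#' Produces \code{nTerms} terms with namespaces cycling BP/CC/MF. The first
#' \code{round(termModuleBias * nTerms)} terms are module-biased: about 70%
#' of their genes are drawn from the planted module, the rest from the
#' background; remaining terms sample uniformly from all nodes. Term sizes
#' are drawn uniformly between 10 and 40 genes (clipped to the network).
#'
#' @param network the [PPINetwork-class] from [simulateNetwork()].
#' @param truth the matching [SyntheticTruth-class].
#' @param spec the [syntheticSpec()] used (supplies \code{nTerms},
#'   \code{termModuleBias} and the RNG seed).
#' @return an [AnnotationCorpus-class]; deterministic given \code{spec}.
#' @export
simulateAnnotations <- function(network, truth, spec) {
    stopifnot(inherits(spec, "SyntheticSpec"))
    set.seed(spec$rngSeed + 1L)
    all <- nodes(network)
    mod <- moduleMembers(truth)
    bg <- setdiff(all, mod)
    nBiased <- round(spec$termModuleBias * spec$nTerms)
    # biased terms are module-centric, so their size scales with the module
    # (0.5x to 1.4x its size): with ~70% of members drawn from the module
    # they always stay module-majority. Unbiased terms use generic GO-like
    # sizes of 10-40 genes.
    lo <- max(3, round(0.5 * spec$moduleSize))
    hi <- max(lo, min(40, round(1.4 * spec$moduleSize)))
    sizes <- c(sample(seq(lo, hi), nBiased, replace = TRUE),
               sample(10:40, spec$nTerms - nBiased, replace = TRUE))
    sizes <- pmin(sizes, length(all))
    sets <- lapply(seq_len(spec$nTerms), function(i) {
        if (i <= nBiased) {
            nMod <- min(length(mod), ceiling(0.7 * sizes[i]))
            c(sample(mod, nMod), sample(bg, sizes[i] - nMod))
        } else {
            sample(all, sizes[i])
        }
    })
    names(sets) <- sprintf("SYN:%04d", seq_len(spec$nTerms))
    AnnotationCorpus(sets, rep_len(c("BP", "CC", "MF"), spec$nTerms))
}

#' @describeIn SyntheticTruth all planted-module gene IDs
#' @param x a \code{SyntheticTruth}
#' @export
setMethod("moduleMembers", "SyntheticTruth", function(x) x@moduleMembers)

#' @describeIn SyntheticTruth the seeded (known) module genes
#' @export
setMethod("seedGenes", "SyntheticTruth", function(x) x@seeds)

#' @describeIn SyntheticTruth the unseeded module genes the screen should
#'   recover
#' @export
setMethod("latentTargets", "SyntheticTruth", function(x) x@latentTargets)

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", length(object@moduleMembers), "module genes;",
        length(object@seeds), "seeds,",
        length(object@latentTargets), "latent targets\n")
})

#' Write / read planted-module ground truth as JSON
#'
#' @param truth a [SyntheticTruth-class].
#' @param path output (input) path.
#' @return \code{writeTruth}: \code{path} invisibly; \code{readTruth}: a
#'   [SyntheticTruth-class].
#' @export
writeTruth <- function(truth, path) {
    write_json(list(module_members = moduleMembers(truth),
                    seeds = seedGenes(truth),
                    latent_targets = latentTargets(truth)),
               path, pretty = TRUE)
    invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
    x <- read_json(path, simplifyVector = TRUE)
    new("SyntheticTruth", moduleMembers = x$module_members,
        seeds = x$seeds, latentTargets = x$latent_targets)
}
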