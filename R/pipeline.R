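#' Run the full latent-gene screening cascade
#'
#' Executes, in order: transition-operator construction, random walk with
#' restart from the validated seed genes, raw-candidate selection at the
#' probability cutoff, the permutation Z-score test, the maximum association
#' score, enrichment-vector construction and the maximum function score for
#' the genes still in play, threshold application, and a final
#' over-representation test of the putative genes. Each stage logs its
#' survivor count and wall time. The whole run is deterministic for a fixed
#' \code{seed}.
#'
#' @param network a [PPINetwork-class].
#' @param seeds character vector of validated disease genes (in the network).
#' @param corpus an [AnnotationCorpus-class] for the function test and the
#'   over-representation step.
#' @param restart restart probability of the walk; default 0.8.
#' @param tol,maxIter convergence control of the walk.
#' @param candidateCutoff raw-candidate probability cutoff (strict ">");
#'   default 1e-5.
#' @param nPermutations random seed sets for the Z-score; default 1000.
#' @param zCutoff,masCutoff,mfsCutoff screening thresholds; defaults 1.96,
#'   900 and 0.9 (see [applyThresholds()]).
#' @param goPCutoff over-representation reporting threshold; default 0.001.
#' @param universe hypergeometric universe; default all network nodes.
#' @param seed integer RNG seed driving the permutation draws.
#' @param selfExclude see [permutationTest()].
#' @param verbose log stage counts and timings? default TRUE.
#' @return a [ScreenResult-class].
#' @examples
#' sim <- simulateNetwork(syntheticSpec(nBackground = 60, moduleSize = 8,
#'                                      nTerms = 15, rngSeed = 3))
#' corp <- simulateAnnotations(sim$network, sim$truth,
#'                             syntheticSpec(nBackground = 60,
#'                                           moduleSize = 8, nTerms = 15,
#'                                           rngSeed = 3))
#' res <- screenGenes(sim$network, seedGenes(sim$truth), corp,
#'                    nPermutations = 100, seed = 11, verbose = FALSE)
#' stageCounts(res)
#' @export
screenGenes <- function(network, seeds, corpus, restart = 0.8, tol = 1e-6,
                        maxIter = 10000L, candidateCutoff = 1e-5,
                        nPermutations = 1000L, zCutoff = 1.96,
                        masCutoff = 900L, mfsCutoff = 0.9,
                        goPCutoff = 0.001, universe = nodes(network),
                        seed = 1L, selfExclude = TRUE, verbose = TRUE) {
    seeds <- .lexSort(unique(as.character(seeds)))
    if (!all(seeds %in% nodes(network)))
        stop("stage rwr: seed gene(s) not in network: ",
             paste(setdiff(seeds, nodes(network)), collapse = ", "))
    log <- function(stage, n, t0) {
        if (verbose)
            message(sprintf("[%s] %d gene(s), %.2fs", stage, n,
                            as.numeric(proc.time()[3] - t0)))
    }

    t0 <- proc.time()[3]
    op <- transitionMatrix(network)
    p <- tryCatch(randomWalk(op, seedVector(network, seeds),
                             restart = restart, tol = tol,
                             maxIter = maxIter),
                  error = function(e) stop("stage rwr: ", conditionMessage(e),
                                           call. = FALSE))
    cand <- selectCandidates(p, seeds, cutoff = candidateCutoff)
    log("rwr", nrow(cand), t0)

    t0 <- proc.time()[3]
    perm <- permutationTest(op, p, k = length(seeds),
                            candidates = cand$gene,
                            nPermutations = nPermutations, seed = seed,
                            selfExclude = selfExclude, restart = restart,
                            tol = tol, maxIter = maxIter)
    log("permutation", sum(perm$zScore > zCutoff), t0)

    t0 <- proc.time()[3]
    mas <- maxAssociationScore(network, cand$gene, seeds)
    records <- DataFrame(gene = cand$gene, probability = cand$probability,
                         zScore = perm$zScore, mas = unname(mas),
                         mfs = NA_real_)
    inPlay <- records$zScore > zCutoff & records$mas >= masCutoff
    log("association", sum(inPlay), t0)

    t0 <- proc.time()[3]
    if (any(inPlay)) {
        prof <- unique(c(records$gene[inPlay], seeds))
        V <- enrichmentVectors(network, prof, corpus, universe)
        mfs <- maxFunctionScore(records$gene[inPlay], seeds, V)
        records$mfs[inPlay] <- unname(mfs)
    }
    thr <- applyThresholds(records, zCutoff = zCutoff,
                           masCutoff = masCutoff, mfsCutoff = mfsCutoff)
    putative <- as.character(
        thr$records$gene[thr$records$stagePassed == "function"])
    log("function", length(putative), t0)

    t0 <- proc.time()[3]
    enriched <- if (length(putative)) {
        goEnrichment(putative, corpus, universe, pCutoff = goPCutoff)
    } else {
        DataFrame(term = character(0), namespace = character(0),
                  pValue = numeric(0), overlap = integer(0),
                  size = integer(0))
    }
    log("enrichment", nrow(enriched), t0)

    new("ScreenResult", records = thr$records, stageCounts = thr$counts,
        putative = putative, enriched = enriched,
        confidenceMatrix = confidenceMatrix(network, putative, seeds),
        seeds = seeds,
        params = list(restart = restart, tol = tol, maxIter = maxIter,
                      candidateCutoff = candidateCutoff,
                      nPermutations = nPermutations, zCutoff = zCutoff,
                      masCutoff = masCutoff, mfsCutoff = mfsCutoff,
                      goPCutoff = goPCutoff, seed = seed,
                      selfExclude = selfExclude))
}

#' Confidence matrix between putative and validated genes
#'
#' Rows are putative genes, columns validated genes, entries the edge
#' confidence Q (0 when no interaction). This is the matrix behind the
#' published putative-vs-validated heat maps; it is exported as TSV, not
#' rendered.
#'
#' @param network a [PPINetwork-class].
#' @param putative,validated character vectors of genes in the network.
#' @return numeric matrix with gene IDs as dimnames; zero rows are allowed
#'   (empty putative set).
#' @export
confidenceMatrix <- function(network, putative, validated) {
    i <- match(putative, nodes(network)); j <- match(validated, nodes(network))
    if (anyNA(i) || anyNA(j))
        stop("gene(s) not in network")
    m <- as.matrix(adjacencyMatrix(network)[i, j, drop = FALSE])
    dimnames(m) <- list(putative, validated)
    m
}

#' Genes shared between two screening results
#'
#' @param resultA,resultB [ScreenResult-class] objects.
#' @return sorted character vector: the intersection of the two putative
#'   gene lists.
#' @export
sharedGenes <- function(resultA, resultB) {
    .lexSort(intersect(putativeGenes(resultA), putativeGenes(resultB)))
}

#' Write, read and run a pipeline configuration file
#'
#' The configuration is a flat key-value YAML file holding the three input
#' paths (\code{edgeFile}, \code{seedFile}, \code{gmtFile}), optionally
#' \code{outDir} and \code{minConfidence}, and any [screenGenes()] parameter
#' (e.g. \code{restart}, \code{nPermutations}, \code{zCutoff}, \code{seed}).
#' A written configuration reloads to an equivalent one.
#'
#' @param config named list of configuration values.
#' @param path path of the YAML file.
#' @return \code{writePipelineConfig}: \code{path}, invisibly;
#'   \code{readPipelineConfig}: the configuration list;
#'   \code{runScreenConfig}: the [ScreenResult-class], invisibly.
#' @export
writePipelineConfig <- function(config, path) {
    stopifnot(is.list(config), !is.null(names(config)),
              all(nzchar(names(config))))
    yaml::write_yaml(config, path)
    invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path))
        stop("config file not found: ", path)
    config <- yaml::read_yaml(path)
    if (!is.list(config) || is.null(names(config)))
        stop("config file must be a flat key-value mapping")
    config
}

#' @rdname writePipelineConfig
#' @export
runScreenConfig <- function(path) {
    config <- readPipelineConfig(path)
    need <- setdiff(c("edgeFile", "seedFile", "gmtFile"), names(config))
    if (length(need))
        stop("config is missing required key(s): ",
             paste(need, collapse = ", "))
    do.call(runScreen, config)
}

#' @describeIn ScreenResult per-stage survivor counts
#' @param x a \code{ScreenResult}
#' @export
setMethod("stageCounts", "ScreenResult", function(x) x@stageCounts)

#' @describeIn ScreenResult the final putative genes, MFS descending
#' @export
setMethod("putativeGenes", "ScreenResult", function(x) x@putative)

#' @describeIn ScreenResult the full candidate record table
#' @export
setMethod("candidateRecords", "ScreenResult", function(x) x@records)

#' @describeIn ScreenResult over-represented terms among the putative genes
#' @export
setMethod("enrichedTerms", "ScreenResult", function(x) x@enriched)

setMethod("show", "ScreenResult", function(object) {
    cat("ScreenResult\n  stage counts:",
        paste(names(object@stageCounts), object@stageCounts, sep = "=",
              collapse = ", "), "\n")
    cat("  putative genes:",
        paste(utils::head(object@putative, 8L), collapse = ", "),
        if (length(object@putative) > 8L) "..." else "", "\n")
    if (nrow(object@enriched)) {
        ns <- table(object@enriched$namespace)
        cat("  enriched terms:", nrow(object@enriched),
            paste0("(", paste(names(ns), ns, sep = ":", collapse = ", "),
                   ")"), "\n")
    } else cat("  enriched terms: none\n")
})

#' Write all screening outputs as TSV
#'
#' Writes \code{candidates.tsv} (the record table), \code{stage_counts.tsv},
#' \code{enriched_terms.tsv} and \code{confidence_matrix.tsv} into a
#' directory. All floating-point values use fixed 10-significant-digit
#' formatting and MAS is printed as an integer, so repeated runs with the
#' same seed produce byte-identical files.
#'
#' @param result a [ScreenResult-class].
#' @param dir output directory (created if missing).
#' @return character vector of the files written, invisibly.
#' @export
writeScreenResult <- function(result, dir) {
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    rec <- as.data.frame(candidateRecords(result))
    out <- data.frame(gene_id = rec$gene,
                      probability = .fmtNum(rec$probability),
                      z_score = .fmtNum(rec$zScore),
                      mas = as.integer(rec$mas),
                      mfs = .fmtNum(rec$mfs),
                      stage_passed = rec$stagePassed)
    f1 <- file.path(dir, "candidates.tsv")
    write.table(out, f1, sep = "\t", quote = FALSE, row.names = FALSE)
    f2 <- file.path(dir, "stage_counts.tsv")
    write.table(data.frame(stage = names(stageCounts(result)),
                           genes = unname(stageCounts(result))),
                f2, sep = "\t", quote = FALSE, row.names = FALSE)
    et <- as.data.frame(enrichedTerms(result))
    if (nrow(et)) et$pValue <- .fmtNum(et$pValue)
    f3 <- file.path(dir, "enriched_terms.tsv")
    write.table(et, f3, sep = "\t", quote = FALSE, row.names = FALSE)
    cm <- result@confidenceMatrix
    f4 <- file.path(dir, "confidence_matrix.tsv")
    write.table(data.frame(gene_id = rownames(cm), cm, check.names = FALSE),
                f4, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(f1, f2, f3, f4))
}

#' File-based end-to-end run
#'
#' Thin orchestration over the loaders and [screenGenes()]: reads a
#' STRING-links edge file, a seed-gene list and a GMT corpus, runs the full
#' cascade and (optionally) writes the TSV outputs.
#'
#' @param edgeFile STRING-links file (optionally gzipped).
#' @param seedFile one-gene-per-line seed list.
#' @param gmtFile GMT annotation corpus.
#' @param outDir output directory for [writeScreenResult()]; NULL to skip
#'   writing.
#' @param minConfidence edge filter for [readStringLinks()].
#' @param seed integer RNG seed, passed to [screenGenes()]. (Kept as an
#'   explicit formal so it can never partially match \code{seedFile}.)
#' @param ... further arguments to [screenGenes()].
#' @return a [ScreenResult-class], invisibly.
#' @export
runScreen <- function(edgeFile, seedFile, gmtFile, outDir = NULL,
                      minConfidence = 1L, seed = 1L, ...) {
    network <- readStringLinks(edgeFile, minConfidence = minConfidence)
    seeds <- readGeneList(seedFile, network)
    corpus <- readGMT(gmtFile)
    result <- screenGenes(network, seeds, corpus, seed = seed, ...)
    if (!is.null(outDir))
        writeScreenResult(result, outDir)
    invisible(result)
}
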