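#' Null ensemble of random-seed random walks
#'
#' Draws \code{nDraws} seed sets of size \code{k} uniformly without
#' replacement from all network nodes, runs the random walk with restart
#' identically for each, and returns the full node-by-draw probability matrix
#' together with a seed-membership indicator. Draw i uses an RNG seed derived
#' deterministically from \code{seed} and i, so any single draw can be
#' reproduced in isolation.
#'
#' @param operator column-stochastic transition matrix (with node dimnames).
#' @param k seed-set size per draw.
#' @param nDraws number of draws.
#' @param seed integer base RNG seed (mandatory, for reproducibility).
#' @param restart,tol,maxIter passed to [randomWalk()].
#' @return list with \code{prob} (nodes x draws numeric matrix) and
#'   \code{seeded} (nodes x draws logical matrix: was the node in that draw's
#'   seed set?).
#' @export
nullEnsemble <- function(operator, k, nDraws, seed, restart = 0.8,
                         tol = 1e-6, maxIter = 10000L) {
    ids <- rownames(operator)
    n <- length(ids)
    if (k > n)
        stop("seed-set size ", k, " exceeds the number of nodes ", n)
    .assertScalar(nDraws, "nDraws", 1, Inf)
    prob <- matrix(0, n, nDraws, dimnames = list(ids, NULL))
    seeded <- matrix(FALSE, n, nDraws, dimnames = list(ids, NULL))
    base <- rep(1 / k, k)
    for (i in seq_len(nDraws)) {
        set.seed(.permSeed(seed, i))
        idx <- sample.int(n, k)
        p0 <- numeric(n)
        p0[idx] <- base
        names(p0) <- ids
        prob[, i] <- randomWalk(operator, p0, restart = restart, tol = tol,
                                maxIter = maxIter)
        seeded[idx, i] <- TRUE
    }
    list(prob = prob, seeded = seeded)
}

#' Permutation test of candidate probabilities
#'
#' Assesses whether a candidate's RWR probability from the true seed set
#' exceeds what the network topology alone would produce: \code{nPermutations}
#' random seed sets of the same size are drawn, the walk is re-run for each,
#' and the candidate's Z-score is
#' \deqn{Z(g) = (P(g) - PM(g)) / PSTD(g)}
#' where PM and PSTD are the mean and standard deviation of the candidate's
#' probabilities across the random sets.
#'
#' By default (\code{selfExclude = TRUE}) the draws in which the candidate
#' itself was sampled into the random seed set are left out of its own null
#' statistics: a seeded node holds the restart mass r/k, orders of magnitude
#' above any diffusion value, and including those draws inflates PSTD so much
#' that no realistic candidate can reach the 1.96 cutoff. The published
#' per-gene Z-scores (2–5 at probabilities near 1e-4) are only reachable with
#' the self-excluded null. Set \code{selfExclude = FALSE} for the literal
#' all-draws statistics.
#'
#' @param operator column-stochastic transition matrix.
#' @param observed named probability vector from the true-seed walk.
#' @param k size of the true seed set (random sets use the same size).
#' @param candidates character vector of candidate genes, or the DataFrame
#'   from [selectCandidates()].
#' @param nPermutations number of random seed sets; default 1000.
#' @param seed integer RNG seed, mandatory.
#' @param selfExclude drop draws containing the candidate from its null?
#' @param sdDenominator \code{"n"} (population, default) or \code{"n-1"}
#'   (sample) denominator for PSTD; with 1000 permutations the difference is
#'   negligible.
#' @param restart,tol,maxIter passed to [randomWalk()].
#' @param ensemble optional pre-computed [nullEnsemble()] result to reuse.
#' @return a [S4Vectors::DataFrame] with columns \code{gene},
#'   \code{probability}, \code{nullMean}, \code{nullSd}, \code{zScore},
#'   \code{nNull} (draws used for that gene). When \code{nullSd} is 0 the
#'   Z-score is +Inf/-Inf/0 according to the sign of the numerator.
#' @export
permutationTest <- function(operator, observed, k, candidates,
                            nPermutations = 1000L, seed,
                            selfExclude = TRUE, sdDenominator = c("n", "n-1"),
                            restart = 0.8, tol = 1e-6, maxIter = 10000L,
                            ensemble = NULL) {
    sdDenominator <- match.arg(sdDenominator)
    if (missing(seed) && is.null(ensemble))
        stop("an RNG seed is required for the permutation test")
    if (is(candidates, "DataFrame") || is.data.frame(candidates))
        candidates <- as.character(candidates$gene)
    if (nPermutations < 2L)
        stop("at least 2 permutations are needed to estimate a null sd")
    if (is.null(ensemble))
        ensemble <- nullEnsemble(operator, k = k, nDraws = nPermutations,
                                 seed = seed, restart = restart, tol = tol,
                                 maxIter = maxIter)
    idx <- match(candidates, rownames(ensemble$prob))
    if (anyNA(idx))
        stop("candidate gene(s) missing from the operator: ",
             paste(candidates[is.na(idx)], collapse = ", "))
    res <- vapply(seq_along(idx), function(j) {
        vals <- ensemble$prob[idx[j], ]
        if (selfExclude)
            vals <- vals[!ensemble$seeded[idx[j], ]]
        if (length(vals) < 2L)
            stop("fewer than 2 usable null draws for gene ", candidates[j])
        m <- mean(vals)
        s <- if (sdDenominator == "n")
            sqrt(mean((vals - m)^2)) else stats::sd(vals)
        c(m, s, length(vals))
    }, numeric(3))
    pg <- unname(observed[candidates])
    nullMean <- res[1, ]
    nullSd <- res[2, ]
    z <- ifelse(nullSd > 0, (pg - nullMean) / nullSd,
                sign(pg - nullMean) * Inf)
    z[nullSd == 0 & pg == nullMean] <- 0
    if (any(nullSd == 0))
        message(sum(nullSd == 0), " candidate(s) with degenerate null sd 0")
    DataFrame(gene = candidates, probability = pg, nullMean = nullMean,
              nullSd = nullSd, zScore = z, nNull = as.integer(res[3, ]))
}

#' Null-on-null calibration of the permutation Z-score
#'
#' Empirically checks how often the permutation Z-score exceeds a cutoff when
#' the "observed" probabilities themselves come from random seed sets. A bank
#' of \code{nBank} random-seed walks defines each gene's null mean and sd;
#' \code{nEval} further independent draws act as observed runs, and the
#' pooled fraction of Z-scores above \code{zCutoff} is returned.
#'
#' Two conventions are supported. The default (\code{selfExclude = FALSE},
#' \code{evalPool = "all"}) is the fully exchangeable null: bank statistics
#' use every draw and every gene is evaluated, including the draws in which
#' it was itself seeded. Under it the exceedance fraction sits near the
#' seed-inclusion probability k/n. With \code{selfExclude = TRUE} and
#' \code{evalPool = "nonseed"} the function instead measures the operational
#' pass rate of the pipeline's first filter (which uses self-excluded nulls
#' and never evaluates a seed): because diffusion scores are right-skewed,
#' that rate runs noticeably above the nominal normal tail at 1.96.
#'
#' @param operator column-stochastic transition matrix.
#' @param k seed-set size per draw.
#' @param nBank draws defining the null statistics; default 1000.
#' @param nEval draws playing the role of observed runs; default 2000.
#' @param seed integer RNG seed (bank and evaluation draws are derived from
#'   it independently).
#' @param zCutoff exceedance cutoff; default 1.96.
#' @param selfExclude drop a gene's own seeded draws from its bank
#'   statistics?
#' @param evalPool \code{"all"} genes per evaluation draw, or only the
#'   \code{"nonseed"} genes of that draw.
#' @param restart,tol,maxIter passed to [randomWalk()].
#' @return list with \code{fraction} (exceedance fraction), \code{nZ}
#'   (number of pooled Z-scores) and \code{zCutoff}.
#' @export
calibrateNull <- function(operator, k, nBank = 1000L, nEval = 2000L, seed,
                          zCutoff = 1.96, selfExclude = FALSE,
                          evalPool = c("all", "nonseed"), restart = 0.8,
                          tol = 1e-6, maxIter = 10000L) {
    evalPool <- match.arg(evalPool)
    bank <- nullEnsemble(operator, k = k, nDraws = nBank, seed = seed,
                         restart = restart, tol = tol, maxIter = maxIter)
    ev <- nullEnsemble(operator, k = k, nDraws = nEval,
                       seed = .permSeed(seed, nBank + 1L), restart = restart,
                       tol = tol, maxIter = maxIter)
    n <- nrow(bank$prob)
    m <- s <- numeric(n)
    for (g in seq_len(n)) {
        v <- bank$prob[g, ]
        if (selfExclude)
            v <- v[!bank$seeded[g, ]]
        m[g] <- mean(v)
        s[g] <- sqrt(mean((v - m[g])^2))
    }
    z <- (ev$prob - m) / s
    use <- if (evalPool == "nonseed") !ev$seeded else
        matrix(TRUE, nrow(z), ncol(z))
    use <- use & s > 0
    list(fraction = mean(z[use] > zCutoff), nZ = sum(use), zCutoff = zCutoff)
}

#' Maximum association score (MAS)
#'
#' For each candidate, the largest edge confidence between it and any
#' validated (seed) gene; 0 when the candidate has no edge to any of them.
#' A high MAS means the candidate interacts at high STRING confidence with at
#' least one known disease gene.
#'
#' @param network a [PPINetwork-class].
#' @param genes character vector of candidate genes (must be in the network).
#' @param validated character vector of validated disease genes.
#' @return named integer vector of MAS values.
#' @export
maxAssociationScore <- function(network, genes, validated) {
    genes <- as.character(genes)
    i <- match(genes, nodes(network))
    j <- match(validated, nodes(network))
    if (anyNA(i))
        stop("candidate gene(s) not in network: ",
             paste(genes[is.na(i)], collapse = ", "))
    if (anyNA(j))
        stop("validated gene(s) not in network: ",
             paste(validated[is.na(j)], collapse = ", "))
    if (length(genes) == 0L)
        return(stats::setNames(integer(0), character(0)))
    sub <- as.matrix(adjacencyMatrix(network)[i, j, drop = FALSE])
    stats::setNames(as.integer(apply(sub, 1L, max)), genes)
}

#' Apply the screening thresholds sequentially
#'
#' Filters the candidate records through the three-stage cascade: Z-score
#' with a strict ">" (the cutoff itself does not pass), then MAS and MFS with
#' an inclusive ">=" (900 is the inclusive lower bound of STRING's
#' highest-confidence tier, and the MFS thresholds are the values at which
#' genes are chosen). Records each gene's furthest stage and the per-stage
#' survivor counts, which are monotone non-increasing by construction.
#'
#' @param records a [S4Vectors::DataFrame] (or data.frame) with columns
#'   \code{gene}, \code{probability}, \code{zScore}, \code{mas}, \code{mfs}
#'   (fields for stages not yet computed may be NA; NA never passes).
#' @param zCutoff Z-score threshold, strict; default 1.96.
#' @param masCutoff MAS threshold in [1, 999], inclusive; default 900.
#' @param mfsCutoff MFS threshold in [0, 1], inclusive; disease-specific
#'   (published screens used 0.9 and 0.96); default 0.9.
#' @return list with \code{records} (input plus a \code{stagePassed} column,
#'   final survivors first sorted by MFS descending) and \code{counts}
#'   (named integer vector of per-stage survivors).
#' @export
applyThresholds <- function(records, zCutoff = 1.96, masCutoff = 900L,
                            mfsCutoff = 0.9) {
    .assertScalar(masCutoff, "masCutoff", 1, 999)
    .assertScalar(mfsCutoff, "mfsCutoff", 0, 1)
    stopifnot(all(c("gene", "zScore", "mas", "mfs") %in% colnames(records)))
    passZ <- !is.na(records$zScore) & records$zScore > zCutoff
    passA <- passZ & !is.na(records$mas) & records$mas >= masCutoff
    passF <- passA & !is.na(records$mfs) & records$mfs >= mfsCutoff
    stage <- rep("rwr", nrow(records))
    stage[passZ] <- "permutation"
    stage[passA] <- "association"
    stage[passF] <- "function"
    records$stagePassed <- stage
    counts <- c(rwr = nrow(records), permutation = sum(passZ),
                association = sum(passA), "function" = sum(passF))
    mfsKey <- ifelse(is.na(records$mfs), -Inf, records$mfs)
    o <- .lexOrder(-passF, -mfsKey, as.character(records$gene))
    list(records = records[o, , drop = FALSE],
         counts = vapply(counts, as.integer, 0L))
}
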