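# small network used across permutation tests
screenNet <- function() randomNet(40, seed = 77)

test_that("Z-score arithmetic follows (P - PM) / PSTD", {
    # hand-built ensemble: candidate n010 gets null values with PM = 0.3 and
    # population PSTD = 0.1, observed 0.5 -> Z = 2
    net <- screenNet()
    ids <- nodes(net)
    prob <- matrix(0, length(ids), 4, dimnames = list(ids, NULL))
    prob["n010", ] <- c(0.2, 0.4, 0.2, 0.4)
    prob["n011", ] <- c(0.1, 0.1, 0.1, 0.1)
    ens <- list(prob = prob,
                seeded = matrix(FALSE, length(ids), 4,
                                dimnames = list(ids, NULL)))
    obs <- c(n010 = 0.5, n011 = 0.1)
    pt <- permutationTest(NULL, obs, k = 3, candidates = c("n010", "n011"),
                          ensemble = ens)
    expect_equal(pt$zScore[pt$gene == "n010"], 2)
    # observed equal to the null mean -> Z = 0
    expect_equal(pt$zScore[pt$gene == "n011"], 0)
    # degenerate PSTD = 0 with a larger observation -> +Inf
    obs2 <- c(n011 = 0.3)
    expect_message(
        pt2 <- permutationTest(NULL, obs2, k = 3, candidates = "n011",
                               ensemble = ens),
        "degenerate")
    expect_identical(pt2$zScore, Inf)
})

test_that("Z-scores reconstruct the observed probability", {
    net <- screenNet()
    op <- transitionMatrix(net)
    seeds <- c("n001", "n005", "n020")
    p <- randomWalk(op, seedVector(net, seeds))
    cand <- selectCandidates(p, seeds, cutoff = 1e-5)
    pt <- permutationTest(op, p, k = 3, candidates = cand,
                          nPermutations = 50, seed = 5)
    fin <- is.finite(pt$zScore)
    expect_lt(max(abs(pt$zScore[fin] * pt$nullSd[fin] + pt$nullMean[fin] -
                          pt$probability[fin])), 1e-9)
})

test_that("the permutation test is deterministic and exchangeable", {
    net <- screenNet()
    op <- transitionMatrix(net)
    seeds <- c("n002", "n014")
    p <- randomWalk(op, seedVector(net, seeds))
    cand <- as.character(selectCandidates(p, seeds)$gene)
    a <- permutationTest(op, p, k = 2, candidates = cand,
                         nPermutations = 40, seed = 99)
    b <- permutationTest(op, p, k = 2, candidates = cand,
                         nPermutations = 40, seed = 99)
    expect_identical(a, b)

    # permuting the candidate list permutes, but never changes, the Z-scores
    shuf <- rev(cand)
    c2 <- permutationTest(op, p, k = 2, candidates = shuf,
                          nPermutations = 40, seed = 99)
    expect_equal(c2$zScore[match(cand, c2$gene)], a$zScore)
})

test_that("population and sample sd conventions are both available", {
    net <- screenNet()
    op <- transitionMatrix(net)
    seeds <- "n001"
    p <- randomWalk(op, seedVector(net, seeds))
    ens <- nullEnsemble(op, k = 1, nDraws = 20, seed = 3)
    g <- "n002"
    popv <- permutationTest(op, p, k = 1, candidates = g, ensemble = ens)
    samv <- permutationTest(op, p, k = 1, candidates = g, ensemble = ens,
                            sdDenominator = "n-1")
    vals <- ens$prob[g, !ens$seeded[g, ]]
    m <- mean(vals)
    expect_equal(popv$nullSd, sqrt(mean((vals - m)^2)))
    expect_equal(samv$nullSd, sd(vals))
    expect_gt(samv$nullSd, popv$nullSd)
})

test_that("permutation draws respect the seed-set size contract", {
    net <- screenNet()
    op <- transitionMatrix(net)
    ens <- nullEnsemble(op, k = 7, nDraws = 25, seed = 8)
    expect_true(all(colSums(ens$seeded) == 7))
    expect_error(nullEnsemble(op, k = 100, nDraws = 2, seed = 1),
                 "exceeds")
    p <- randomWalk(op, seedVector(net, "n001"))
    expect_error(permutationTest(op, p, k = 2, candidates = "n002",
                                 nPermutations = 1L, seed = 1),
                 "at least 2 permutations")
})

test_that("maximum association score takes the best validated edge", {
    edges <- data.frame(from = c("g", "g", "g", "v1", "x"),
                        to = c("v1", "v2", "x", "v2", "v3"),
                        confidence = c(700, 950, 400, 500, 999))
    net <- PPINetwork(edges)
    expect_identical(unname(maxAssociationScore(net, "g",
                                                c("v1", "v2"))), 950L)
    # no edge to any validated gene -> sentinel 0
    expect_identical(unname(maxAssociationScore(net, "v3", c("v1", "v2"))), 0L)
    expect_identical(unname(maxAssociationScore(net, "x", "v3")), 999L)
    expect_error(maxAssociationScore(net, "nope", "v1"), "not in network")
})

test_that("thresholds are strict for Z, inclusive for MAS and MFS", {
    rec <- S4Vectors::DataFrame(
        gene = c("a", "b", "c", "d", "e"),
        probability = c(5, 4, 3, 2, 1) * 1e-4,
        zScore = c(1.96, 1.961, 2.5, 3.0, 2.2),
        mas = c(950L, 899L, 900L, 990L, 920L),
        mfs = c(NA, NA, 0.95, 0.9, 0.89))
    out <- applyThresholds(rec, zCutoff = 1.96, masCutoff = 900,
                           mfsCutoff = 0.9)
    # a fails Z (equality), b fails MAS (899 < 900), e fails MFS (0.89)
    expect_identical(unname(out$counts),
                     c(5L, 4L, 3L, 2L))
    expect_true(all(diff(out$counts) <= 0))
    surv <- out$records[out$records$stagePassed == "function", ]
    # survivors sorted by MFS descending
    expect_identical(as.character(surv$gene), c("c", "d"))
    expect_identical(
        as.character(out$records$gene[out$records$stagePassed == "rwr"]), "a")

    # boundary cases: MAS = 900 survives, Z = cutoff does not
    expect_identical(out$records$stagePassed[out$records$gene == "a"], "rwr")
    expect_identical(out$records$stagePassed[out$records$gene == "c"],
                     "function")
})

test_that("self-excluded and literal null conventions differ as documented", {
    net <- screenNet()
    op <- transitionMatrix(net)
    seeds <- c("n001", "n015", "n030")
    p <- randomWalk(op, seedVector(net, seeds))
    cand <- as.character(selectCandidates(p, seeds)$gene)[1:5]
    ens <- nullEnsemble(op, k = 3, nDraws = 200, seed = 12)
    a <- permutationTest(op, p, k = 3, candidates = cand, ensemble = ens,
                         selfExclude = TRUE)
    b <- permutationTest(op, p, k = 3, candidates = cand, ensemble = ens,
                         selfExclude = FALSE)
    # the literal null includes the candidate's own seeded draws, whose
    # restart mass inflates the null sd by orders of magnitude
    expect_true(all(b$nullSd > a$nullSd))
    expect_true(all(b$nNull == 200L))
    expect_true(all(a$nNull < 200L))
})
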