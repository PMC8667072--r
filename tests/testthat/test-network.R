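test_that("STRING-links loader collapses duplicates and applies filters", {
    f <- withr::local_tempfile(lines = c("protein1 protein2 combined_score",
                                         "a b 700", "b a 700", "b c 950"))
    net <- readStringLinks(f)
    expect_setequal(nodes(net), c("a", "b", "c"))
    expect_equal(numEdges(net), 2L)
    expect_equal(confidence(net, c("a", "b"), c("b", "c")), c(700L, 950L))

    # threshold filtering precedes the node universe
    net9 <- readStringLinks(f, minConfidence = 900)
    expect_setequal(nodes(net9), c("b", "c"))
    expect_equal(numEdges(net9), 1L)

    # conflicting duplicate scores: maximum kept, conflict reported
    g <- withr::local_tempfile(lines = c("a b 100", "b a 300"))
    expect_message(netc <- readStringLinks(g), "conflicting")
    expect_equal(confidence(netc, "a", "b"), 300L)
})

test_that("loader rejects malformed and out-of-range input", {
    f <- withr::local_tempfile(lines = c("a b 1200"))
    expect_error(readStringLinks(f), "1 to 999")
    g <- withr::local_tempfile(lines = c("a b 500", "b c"))
    expect_error(readStringLinks(g), "line 2")
    h <- withr::local_tempfile(lines = c("a b 500", "b c xyz"))
    expect_error(readStringLinks(h), "line 2")
    s <- withr::local_tempfile(lines = c("a a 500", "a b 400"))
    expect_warning(net <- readStringLinks(s), "self-loop")
    expect_equal(numEdges(net), 1L)
    lo <- withr::local_tempfile(lines = c("a b 500"))
    expect_error(readStringLinks(lo, minConfidence = 600), "no edges left")
})

test_that("networks round-trip through the STRING-links dialect", {
    net <- randomNet(30, seed = 11)
    f <- withr::local_tempfile(fileext = ".txt")
    writeStringLinks(net, f)
    back <- readStringLinks(f)
    expect_identical(nodes(back), nodes(net))
    expect_identical(edgeTable(back), edgeTable(net))

    # and through gzip
    gz <- withr::local_tempfile(fileext = ".txt.gz")
    writeStringLinks(net, gz)
    expect_identical(edgeTable(readStringLinks(gz)), edgeTable(net))
})

test_that("gene-list loader intersects with the network and reports drops", {
    net <- pathNet()
    f <- withr::local_tempfile(lines = c("# disease genes", "a", "", "b"))
    s <- readGeneList(f, net)
    expect_equal(as.character(s), c("a", "b"))
    expect_equal(attr(s, "unmapped"), 0L)

    g <- withr::local_tempfile(lines = c("a", "x"))
    expect_message(s2 <- readGeneList(g, net), "1 seed gene")
    expect_equal(as.character(s2), "a")
    expect_equal(attr(s2, "unmapped"), 1L)

    h <- withr::local_tempfile(lines = c("x", "y"))
    expect_error(readGeneList(h, net), "no seed genes found in network")
})

test_that("transition operator is the weighted-degree column normalisation", {
    # path a-b-c, equal weights: column b splits evenly, a and c send all to b
    P <- as.matrix(transitionMatrix(pathNet()))
    expect_equal(P[, "b"], c(a = 0.5, b = 0, c = 0.5))
    expect_equal(P[, "a"], c(a = 0, b = 1, c = 0))
    expect_equal(P[, "c"], c(a = 0, b = 1, c = 0))

    # star: centre column spreads 1/3 to each leaf
    Ps <- as.matrix(transitionMatrix(starNet()))
    expect_equal(unname(Ps[c("x", "y", "z"), "h"]), rep(1 / 3, 3))

    # weight proportionality: a-b:900, b-c:100
    Pw <- as.matrix(transitionMatrix(pathNet(900, 100)))
    expect_equal(Pw[, "b"], c(a = 0.9, b = 0, c = 0.1))
})

test_that("transition operator is column-stochastic, isolates self-restart", {
    for (s in 1:5) {
        net <- randomNet(25, seed = s)
        P <- transitionMatrix(net)
        expect_lt(max(abs(Matrix::colSums(P) - 1)), 1e-12)
    }
    # an isolated node gets a self-transition column
    iso <- PPINetwork(data.frame(from = "a", to = "b", confidence = 500),
                      nodes = "z")
    Pi <- as.matrix(transitionMatrix(iso))
    expect_equal(Pi[, "z"], c(a = 0, b = 0, z = 1))
    expect_lt(max(abs(colSums(Pi) - 1)), 1e-12)
})

test_that("operator application conserves probability mass", {
    for (s in 1:10) {
        net <- randomNet(20, seed = 100 + s)
        P <- transitionMatrix(net)
        set.seed(s)
        v <- runif(numNodes(net))
        v <- v / sum(v)
        expect_lt(abs(sum(P %*% v) - 1), 1e-9)
    }
})

test_that("network constructor validates identifiers and confidences", {
    expect_error(PPINetwork(data.frame(from = "a", to = "b",
                                       confidence = 0.5)), "integers")
    expect_error(PPINetwork(data.frame(from = "a", to = "b",
                                       confidence = 1000)), "integers")
    net <- pathNet()
    expect_equal(nodes(net), sort(nodes(net), method = "radix"))
    expect_setequal(neighborhood(net, "b"), c("a", "b", "c"))
    expect_setequal(neighborhood(starNet(), "h"), c("h", "x", "y", "z"))
    expect_error(neighborhood(net, "nope"), "not in network")
})
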