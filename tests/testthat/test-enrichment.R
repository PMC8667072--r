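test_that("neighbourhoods contain the gene and its direct interactors", {
    expect_setequal(neighborhood(pathNet(), "b"), c("a", "b", "c"))
    iso <- PPINetwork(data.frame(from = "a", to = "b", confidence = 5),
                      nodes = "lone")
    expect_identical(neighborhood(iso, "lone"), "lone")
    expect_length(neighborhood(starNet(), "h"), 4L)
})

test_that("hypergeometric association matches the combinatorial oracle", {
    # worked example: universe 10, term 5, neighbourhood 4, overlap 4
    # p = choose(5,4) * choose(5,0) / choose(10,4) = 5/210
    v <- hyperGeomScore(letters[1:4], letters[1:5], letters[1:10])
    expect_equal(v, -log10(5 / 210), tolerance = 1e-12)
    expect_equal(v, 1.6232, tolerance = 1e-4)

    # overlap 0 -> upper tail P(X >= 0) = 1 -> value 0
    expect_identical(hyperGeomScore(c("f", "g"), c("a", "b"), letters[1:10]),
                     0)
    # term = universe: overlap is forced, p = 1, value 0
    expect_identical(hyperGeomScore(c("a", "b"), letters[1:6], letters[1:6]),
                     0)
    # empty inputs warn and return 0
    expect_warning(z <- hyperGeomScore(character(0), "a", letters[1:4]),
                   "empty")
    expect_identical(z, 0)
})

test_that("log-space tail equals exact rational enumeration (universe <= 12)", {
    for (N in 2:12) {
        for (K in 1:N) {
            for (n in 1:N) {
                for (k in 0:min(K, n)) {
                    pExact <- hyperTailExact(k, K, n, N)
                    got <- NetScreen:::.negLog10HyperTail(k, K, n, N)
                    expect_equal(got, min(300, -log10(pExact)),
                                 tolerance = 1e-10)
                }
            }
        }
    }
})

test_that("-log10 p is monotone in the overlap at fixed sizes", {
    for (K in c(5, 20)) {
        v <- NetScreen:::.negLog10HyperTail(0:K, K, 30, 100)
        expect_true(all(diff(v) >= 0))
    }
})

test_that("enrichment vectors have the corpus dimension and determinism", {
    net <- randomNet(9, seed = 21, pEdge = 0.4)
    corp <- AnnotationCorpus(list(T1 = nodes(net)[1:3], T2 = nodes(net)[4:6],
                                  T3 = nodes(net)[c(1, 7)]),
                             c("BP", "CC", "MF"))
    V <- enrichmentVectors(net, nodes(net)[1:4], corp)
    expect_identical(dim(V), c(4L, 3L))
    expect_identical(colnames(V), c("T1", "T2", "T3"))
    expect_true(all(V >= 0))
    expect_identical(V, enrichmentVectors(net, nodes(net)[1:4], corp))

    # two genes with identical neighbourhoods (a triangle, so each contains
    # the other) get identical vectors, also under a superset universe
    twin <- PPINetwork(data.frame(from = c("u", "v", "u"),
                                  to = c("x", "x", "v"),
                                  confidence = 500))
    ct <- AnnotationCorpus(list(A = c("x", "u"), B = c("v", "q")), "BP")
    Vt <- enrichmentVectors(twin, c("u", "v"), ct,
                            universe = c(nodes(twin), "q"))
    expect_equal(Vt["u", ], Vt["v", ])
})

test_that("a term annotating no neighbour contributes a zero entry", {
    net <- pathNet()
    corp <- AnnotationCorpus(list(Hit = c("a", "b"), Miss = "c"), "BP")
    v <- enrichmentVector(net, "a", corp)   # neighbourhood {a, b}
    expect_identical(unname(v["Miss"]), 0)
    expect_gt(v["Hit"], 0)
})

test_that("cosine similarity obeys the functional-similarity contracts", {
    expect_equal(cosineSimilarity(c(1, 2, 3), c(1, 2, 3)), 1)
    expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
    expect_equal(cosineSimilarity(c(2, 2), c(1, 1)), 1)   # scale invariance
    expect_identical(cosineSimilarity(c(0, 0), c(1, 1)), 0)  # zero-norm rule
    expect_error(cosineSimilarity(1:3, 1:4), "different lengths")

    # symmetry and [0, 1] bounds over a random battery of non-negative pairs
    set.seed(14)
    for (i in 1:50) {
        v1 <- runif(8) * rbinom(8, 1, 0.6)
        v2 <- runif(8) * rbinom(8, 1, 0.6)
        s <- cosineSimilarity(v1, v2)
        expect_identical(s, cosineSimilarity(v2, v1))
        expect_gte(s, 0)
        expect_lte(s, 1)
    }
})

test_that("maximum function score picks the best validated gene", {
    vec <- rbind(cand = c(1, 1, 0), v1 = c(0.3, 1, 4), v2 = c(2, 2, 0),
                 zero = c(0, 0, 0))
    mfs <- maxFunctionScore("cand", c("v1", "v2"), vec)
    expect_equal(unname(mfs), 1)   # identical direction to v2
    expect_equal(unname(maxFunctionScore("zero", c("v1", "v2"), vec)), 0)
    expect_error(maxFunctionScore("cand", "missing", vec),
                 "no enrichment vector for gene")

    lam <- c(0.3, 0.95)
    expect_equal(max(lam), 0.95)
})

test_that("over-representation test ranks an exact annotation set first", {
    corp <- toyCorpus()
    uni <- letters[1:10]
    # the query IS term T3's annotation set; exhaustive p over the toy corpus
    res <- goEnrichment(c("a", "e", "f", "g"), corp, uni, pCutoff = 1)
    expect_identical(as.character(res$term[1]), "T3")
    pAll <- vapply(geneSets(corp), function(s)
        hyperTailExact(length(intersect(s, c("a", "e", "f", "g"))),
                       length(s), 4, 10), 0)
    expect_equal(res$pValue, unname(sort(pAll)))

    # pCutoff 1 returns every term, sorted by p ascending
    expect_identical(nrow(res), 5L)
    expect_true(all(diff(res$pValue) >= 0))

    # a gene set disjoint from all terms is never "enriched"
    resj <- goEnrichment("j", corp, c(uni, "j"), pCutoff = 0.5)
    expect_identical(nrow(resj), 0L)
    expect_error(goEnrichment(character(0), corp, uni), "empty")
})

test_that("over-representation respects the strict p cutoff and namespaces", {
    corp <- toyCorpus()
    uni <- letters[1:10]
    res <- goEnrichment(c("a", "e", "f", "g"), corp, uni, pCutoff = 0.01)
    expect_true(all(res$pValue < 0.01))
    expect_true(all(res$namespace %in% c("BP", "CC", "MF")))
    expect_error(goEnrichment("zzz", corp, uni), "outside the universe")
})
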