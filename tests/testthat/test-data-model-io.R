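test_that("expression TSV parsing validates structure and values", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("neuron\tGlu", "n1\t1", "n2\t0"), path)
    X <- suppressMessages(readExpression(path))
    expect_identical(exprValues(X),
                     namedMatrix(c(1, 0), c("n1", "n2"), "Glu"))

    writeLines("neuron\tGlu", path)
    expect_error(suppressMessages(readExpression(path)), "empty")

    writeLines(c("neuron\tGlu", "n1\t-0.5"), path)
    expect_error(suppressMessages(readExpression(path)), "nonnegative")

    writeLines(c("neuron\tGlu", "n1\tabc"), path)
    expect_error(suppressMessages(readExpression(path)), "malformed")

    writeLines(c("neuron\tGlu", "n1\t1", "n1\t2"), path)
    expect_error(suppressMessages(readExpression(path)), "duplicate")
})

test_that("signed edge lists build consistent connectome, mask and catalog", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("pre\tpost\tcategory\tsign",
                 "n1\tn2\tknown_positive\t1",
                 "n2\tn1\tcomplex\t",
                 "n2\tn3\tunknown\t"), path)
    out <- suppressMessages(readSignedEdges(path, c("n1", "n2", "n3")))
    expect_equal(signMatrix(out$connectome)["n1", "n2"], 1)
    expect_equal(maskMatrix(out$mask)["n1", "n2"], 1)
    expect_equal(maskMatrix(out$mask)["n2", "n3"], 1)
    expect_equal(sum(maskMatrix(out$mask)), 3)
    expect_equal(sum(signMatrix(out$connectome) != 0), 1)

    # invariant violations
    writeLines(c("pre\tpost\tcategory\tsign", "n1\tn2\tcomplex\t1"), path)
    expect_error(suppressMessages(readSignedEdges(path, c("n1", "n2"))),
                 "non-known")
    writeLines(c("pre\tpost\tcategory\tsign", "n1\tnX\tunknown\t"), path)
    expect_error(suppressMessages(readSignedEdges(path, c("n1", "n2"))),
                 "unknown neuron")
    writeLines(c("pre\tpost\tcategory\tsign",
                 "n1\tn2\tunknown\t", "n1\tn2\tunknown\t"), path)
    expect_error(suppressMessages(readSignedEdges(path, c("n1", "n2"))),
                 "duplicate")
})

test_that("edge-list and prediction round-trips are lossless", {
    d <- generatePlanted(plantedModel(nNeurons = 80L, nR = 10L, seed = 3L))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeSignedEdges(d$catalog, path)
    back <- suppressMessages(readSignedEdges(path, neuronIds(d$X)))
    expect_equal(catalogTable(back$catalog), catalogTable(d$catalog))
    expect_equal(signMatrix(back$connectome), signMatrix(d$Aknown))

    scores <- sl3Scores(d$Aknown)
    ranked <- rankPredictions(scores, unresolvedPairs(d$catalog))
    expect_gt(nrow(predTable(ranked)), 0)
    writePredictions(ranked, path)
    back2 <- readPredictions(path, method = "SL3")
    expect_equal(predTable(back2)$score, predTable(ranked)$score)
    # re-ranking the written file reproduces the same order
    rr <- rankPredictions(scores, predTable(back2)[, c("pre", "post")])
    expect_identical(predTable(rr)[c("pre", "post")],
                     predTable(ranked)[c("pre", "post")])

    # empty prediction set -> header-only file
    empty <- rankPredictions(ScoreMatrix(signMatrix(d$Aknown) * 0, "SL3"),
                             unresolvedPairs(d$catalog))
    writePredictions(empty, path)
    expect_equal(nrow(predTable(empty)), 0)
    expect_equal(length(readLines(path)), 1L)
})

test_that("expression and rules round-trip through TSV", {
    d <- generatePlanted(plantedModel(nNeurons = 12L, nR = 5L, seed = 9L))
    px <- withr::local_tempfile(fileext = ".tsv")
    writeExpression(d$X, px)
    expect_equal(exprValues(suppressMessages(readExpression(px))),
                 exprValues(d$X))
    writeRules(d$O, px)
    expect_equal(ruleWeights(readRules(px)), ruleWeights(d$O))
})

test_that("class validity rejects malformed objects", {
    expect_error(ExpressionMatrix(matrix(1, 1, 1)), "names")
    expect_error(SignedConnectome(namedMatrix(2, "a", "a")), "outside")
    expect_error(ConnectomeMask(namedMatrix(c(0, 1, 1, 3),
                                            c("a", "b"), c("a", "b"))),
                 "binary")
    expect_error(WiringRuleNetwork(namedMatrix(0.5, "t", "r"),
                                   ternary = TRUE), "outside")
    ok <- WiringRuleNetwork(namedMatrix(0.5, "t", "r"), ternary = FALSE)
    expect_s4_class(ok, "WiringRuleNetwork")
})

test_that("label-order permutation of inputs permutes CM outputs identically", {
    inst <- randomCMInstance(5, 2, 3, seed = 21)
    B <- scoreValues(cmWeights(inst$X, inst$O, inst$Y))
    perm <- c(3, 1, 5, 2, 4)
    Xp <- ExpressionMatrix(exprValues(inst$X)[perm, , drop = FALSE])
    Yp <- ExpressionMatrix(exprValues(inst$Y)[perm, , drop = FALSE])
    Bp <- scoreValues(cmWeights(Xp, inst$O, Yp))
    expect_equal(Bp, B[perm, perm])
})

test_that("GraphML export writes nodes and signed edges", {
    A <- randomSigned(6, seed = 5)
    path <- withr::local_tempfile(fileext = ".graphml")
    writeGraphML(A, path)
    g <- igraph::read_graph(path, format = "graphml")
    expect_equal(igraph::gorder(g), 6)
    expect_equal(igraph::gsize(g), sum(signMatrix(A) != 0))
    expect_setequal(unique(igraph::E(g)$sign), c(-1, 1))
})

test_that("dataset bundles round-trip through the configurable adapter", {
    d <- generatePlanted(plantedModel(nNeurons = 25L, nR = 6L, seed = 13L))
    dir <- withr::local_tempdir()
    writeDatasetBundle(d, dir)
    cfg <- list(files = list(X = "X.tsv", Y = "Y.tsv", O = "O.tsv",
                             edges = "edges.tsv"))
    back <- suppressMessages(loadPolarityDataset(dir, cfg))
    expect_equal(exprValues(back$X), exprValues(d$X))
    expect_equal(ruleWeights(back$O), ruleWeights(d$O))
    expect_equal(catalogTable(back$catalog), catalogTable(d$catalog))
    expect_equal(maskMatrix(back$mask), maskMatrix(d$mask))
    # column remapping and category translation
    df <- read.delim(file.path(dir, "edges.tsv"))
    names(df) <- c("source", "target", "cls", "polarity")
    df$cls[df$cls == "unknown"] <- "UNK"
    write.table(df, file.path(dir, "edges2.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, na = "")
    cfg2 <- list(files = list(X = "X.tsv", Y = "Y.tsv", O = "O.tsv",
                              edges = "edges2.tsv"),
                 columns = list(pre = "source", post = "target",
                                category = "cls", sign = "polarity"),
                 categories = list(UNK = "unknown"))
    back2 <- suppressMessages(loadPolarityDataset(dir, cfg2))
    expect_equal(catalogTable(back2$catalog), catalogTable(d$catalog))
})
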