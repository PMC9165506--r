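rankedFrom <- function(pre, post, score, method = "toy") {
    ids <- sort(unique(c(pre, post)))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(match(pre, ids), match(post, ids))] <- score
    rankPredictions(ScoreMatrix(m, method), data.frame(pre = pre, post = post))
}

test_that("running precision counts hits per rank", {
    # predicted [+, +, -] vs truth [+, -, -] -> p = 1, 1/2, 2/3
    ranked <- rankedFrom(c("a", "a", "a"), c("b", "c", "d"),
                         c(3, 2, -1))
    truth <- signedFromPairs(data.frame(pre = c("a", "a", "a"),
                                        post = c("b", "c", "d"),
                                        sign = c(1, -1, -1)),
                             c("a", "b", "c", "d"))
    curve <- precisionCurve(ranked, truth)
    expect_equal(curveTable(curve)$precision, c(1, 1 / 2, 2 / 3))
    expect_equal(curveTable(curve)$hit, c(1, 0, 1))

    # perfect agreement -> p(r) = 1 for every r
    perfect <- precisionCurve(ranked,
        signedFromPairs(data.frame(pre = c("a", "a", "a"),
                                   post = c("b", "c", "d"),
                                   sign = c(1, 1, -1)),
                        c("a", "b", "c", "d")))
    expect_true(all(curveTable(perfect)$precision == 1))

    # pairs without a reference sign are dropped before re-ranking
    partial <- precisionCurve(ranked,
        signedFromPairs(data.frame(pre = "a", post = "d", sign = -1),
                        c("a", "b", "c", "d")))
    expect_equal(nrow(curveTable(partial)), 1)
    expect_equal(curveTable(partial)$precision, 1)

    none <- signedFromPairs(data.frame(pre = "b", post = "a", sign = 1),
                            c("a", "b", "c", "d"))
    expect_error(precisionCurve(ranked, none), "no ranked pair")
})

test_that("precision curve equals a brute-force prefix recount", {
    for (seed in 141:143) {
        d <- generatePlanted(plantedModel(nNeurons = 120L, nR = 15L,
                                          hideFraction = 0.5, seed = seed))
        ranked <- rankPredictions(sl3Scores(d$Aknown), d$hidden)
        expect_gt(nrow(predTable(ranked)), 0)
        truth <- signedFromPairs(d$hidden, neuronIds(d$X))
        curve <- curveTable(precisionCurve(ranked, truth))
        t <- predTable(ranked)
        ts <- signMatrix(truth)
        ref <- ts[cbind(match(t$pre, rownames(ts)),
                        match(t$post, rownames(ts)))]
        t <- t[ref != 0, ]; ref <- ref[ref != 0]
        manual <- vapply(seq_len(nrow(t)), function(r)
            mean(t$sign[1:r] == ref[1:r]), numeric(1))
        expect_equal(curve$precision, manual)
    }
})

test_that("operating point is the largest rank at target precision", {
    curve <- new("PrecisionCurve",
                 table = data.frame(rank = 1:3, hit = c(1, 0, 1),
                                    precision = c(1, 0.5, 2 / 3),
                                    score = c(0.9, 0.5, 0.3)),
                 method = "toy")
    op <- thresholdForPrecision(curve, 0.6)
    expect_equal(op$rank, 3L)
    expect_equal(op$cutoff, 0.3)
    expect_equal(thresholdForPrecision(curve, 1)$rank, 1L)
    bad <- new("PrecisionCurve",
               table = data.frame(rank = 1, hit = 0, precision = 0,
                                  score = 1), method = "toy")
    expect_warning(op2 <- thresholdForPrecision(bad, 0.5), "no rank")
    expect_true(is.na(op2$rank))
})

test_that("random baseline is exact and matches Monte Carlo", {
    expect_equal(randomBaseline(0.64), 0.5392)
    expect_equal(randomBaseline(0.5), 0.5)
    expect_equal(randomBaseline(1), 1)
    expect_error(randomBaseline(1.2))
    set.seed(99)
    n <- 1e5; p <- 0.64
    truthDraw <- rbinom(n, 1, p)
    predDraw <- rbinom(n, 1, p)
    expect_lt(abs(mean(truthDraw == predDraw) - randomBaseline(p)), 0.005)
})

test_that("cross-validation is deterministic and near-perfect on clean planted data", {
    d <- generatePlanted(plantedModel(nNeurons = 100L, nR = 15L, seed = 47L))
    known <- knownPairs(d$catalog)
    cv1 <- kfoldCV("scm", known, X = d$X, Y = d$Y, k = 5L, alpha = 1,
                   seed = 7L)
    cv2 <- kfoldCV("scm", known, X = d$X, Y = d$Y, k = 5L, alpha = 1,
                   seed = 7L)
    expect_identical(curveTable(cv1$mean), curveTable(cv2$mean))
    expect_equal(length(cv1$folds), 5L)
    # noiseless planted data: mean precision close to 1 at every rank
    expect_true(all(curveTable(cv1$mean)$precision > 0.95))

    # network-based methods run through the same folds
    cvNet <- suppressWarnings(kfoldCV("sl3", known, A = d$Aknown, k = 4L,
                                      seed = 3L))
    expect_true(all(curveTable(cvNet$mean)$precision >= 0))
})

test_that("leave-one-out CV of a deterministic scorer ignores the fold seed", {
    A <- randomSigned(10, seed = 53, pNeg = 0.25, pPos = 0.45)
    known <- trainingPairsOf(A)
    n <- nrow(known)
    loo1 <- suppressWarnings(kfoldCV("sl3", known, A = A, k = n, seed = 1L))
    loo2 <- suppressWarnings(kfoldCV("sl3", known, A = A, k = n, seed = 99L))
    # every fold holds exactly one pair, so the mean curve cannot depend
    # on how pairs were shuffled into folds
    expect_equal(mean(curveTable(loo1$mean)$precision),
                 mean(curveTable(loo2$mean)$precision))
})

test_that("two-fold CV fold curves match a manual per-fold reconstruction", {
    A <- randomSigned(6, seed = 163, pNeg = 0.3, pPos = 0.6)
    ids <- neuronIds(A)
    known <- trainingPairsOf(A)
    cv <- suppressWarnings(kfoldCV("sl3", known, A = A, k = 2L, seed = 5L))
    fold <- SynapticPolarity:::.foldAssignments(nrow(known), 2, 5L)
    checked <- 0
    for (f in 1:2) {
        test <- known[fold == f, ]
        Atrain <- signedFromPairs(known[fold != f, ], ids)
        st <- signMatrix(Atrain)
        manual <- st %*% t(st) %*% st   # hand SL3 on the training half
        ranked <- predTable(rankPredictions(ScoreMatrix(manual, "SL3"), test))
        if (nrow(ranked)) {
            truthSigns <- signedFromPairs(test, ids)
            hits <- ranked$sign == signMatrix(truthSigns)[
                cbind(match(ranked$pre, ids), match(ranked$post, ids))]
            expect_equal(curveTable(cv$folds[[f]])$hit, as.integer(hits))
            checked <- checked + 1
        }
    }
    expect_gt(checked, 0)
})

test_that("subsampling at fraction 1 reproduces the full-input curve", {
    d <- generatePlanted(plantedModel(seed = 59L))
    B <- cmWeights(d$X, d$O, d$Y)
    reference <- resolvedComplexPairs(B, d$catalog)
    expect_gt(nrow(reference), 0)
    train <- knownPairs(d$catalog)
    tab <- subsampleExperiment(d$X, d$Y, train, reference,
                               fractions = 1, reps = 2L, alpha = 1,
                               seed = 3L)
    fit <- ridgeFit(buildDesign(d$X, d$Y, train), alpha = 1)
    curve <- precisionCurve(
        rankPredictions(scmScores(d$X, fit, d$Y), reference),
        signedFromPairs(reference, neuronIds(d$X)))
    full <- thresholdForPrecision(curve, 0.95, quiet = TRUE)
    expect_equal(tab$rankAtTarget, rep(full$rank, 2))
})

test_that("union report tallies disjoint contributions and flags conflicts", {
    ids <- c("a", "b", "c")
    known <- signedFromPairs(data.frame(pre = c("a", "b"), post = c("b", "c"),
                                        sign = c(1, -1)), ids)
    cmres <- signedFromPairs(data.frame(pre = "a", post = "c", sign = 1), ids)
    scm <- signedFromPairs(data.frame(pre = "c", post = "a", sign = -1), ids)
    rep <- unionReport(known, cmres, scm)
    expect_equal(rep$total, 4)
    expect_equal(rep$addedExcitatory, 1)
    expect_equal(rep$addedInhibitory, 1)
    expect_equal(rep$excitatoryFractionBefore, 0.5)
    expect_equal(rep$excitatoryFractionAfter, 0.5)

    none <- signedFromPairs(data.frame(pre = character(), post = character(),
                                       sign = numeric()), ids)
    rep0 <- unionReport(known, none, none)
    expect_equal(rep0$total, 2)
    expect_equal(rep0$addedExcitatory + rep0$addedInhibitory, 0)

    clash <- signedFromPairs(data.frame(pre = "a", post = "b", sign = -1), ids)
    expect_error(unionReport(known, clash, none), "overlap")
})
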