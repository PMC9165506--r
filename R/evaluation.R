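#' Precision-at-rank curve of ranked sign predictions
#'
#' Walks the ranked predictions, marks each rank with a 0/1 hit
#' indicator (predicted sign equals the reference sign) and accumulates
#' the running precision p(r) = (1/r) * sum_{i<=r} hit_i. Pairs absent
#' from the reference (reference sign 0) are dropped before ranking is
#' re-indexed.
#'
#' @param ranked a [RankedPredictions-class]
#' @param reference a [SignedConnectome-class] of reference signs
#' @return a [PrecisionCurve-class]
#' @export
precisionCurve <- function(ranked, reference) {
    stopifnot(is(ranked, "RankedPredictions"), is(reference, "SignedConnectome"))
    t <- predTable(ranked)
    refs <- signMatrix(reference)
    ids <- rownames(refs)
    i <- match(t$pre, ids); j <- match(t$post, ids)
    if (anyNA(i) || anyNA(j))
        stop("ranked pair with neuron label absent from the reference")
    refSign <- refs[cbind(i, j)]
    keep <- refSign != 0
    if (!any(keep))
        stop("no ranked pair has a reference sign")
    hit <- as.integer(t$sign[keep] == refSign[keep])
    r <- seq_along(hit)
    .newCurve(data.frame(rank = r, hit = hit,
                         precision = cumsum(hit) / r,
                         score = abs(t$score[keep])),
              scoreMethod(ranked))
}

#' Operating point at a target precision
#'
#' Finds the largest rank r whose running precision still satisfies
#' p(r) >= target, and the absolute-score cutoff at that rank (predict
#' only pairs with |score| >= cutoff to operate at the target
#' precision).
#'
#' @param curve a [PrecisionCurve-class]
#' @param target target precision in (0, 1]
#' @param quiet suppress the warning when no rank reaches the target
#' @return list with `rank` and `cutoff` (both `NA` when the target is
#'   never reached)
#' @export
thresholdForPrecision <- function(curve, target, quiet = FALSE) {
    stopifnot(is(curve, "PrecisionCurve"), target > 0, target <= 1)
    t <- curveTable(curve)
    ok <- which(t$precision >= target)
    if (!length(ok)) {
        if (!quiet) warning("no rank attains the target precision")
        return(list(rank = NA_integer_, cutoff = NA_real_))
    }
    r <- max(ok)
    list(rank = as.integer(r),
         cutoff = if ("score" %in% names(t)) t$score[r] else NA_real_)
}

#' Analytic precision of sign-matched random predictions
#'
#' With a fraction `pPos` of positive reference signs, a random
#' predictor drawing signs with the same positive fraction agrees with
#' probability `pPos^2 + (1 - pPos)^2`; this is the baseline any ranked
#' method must beat.
#'
#' @param pPos positive fraction in `[0, 1]`
#' @return the expected precision
#' @examples
#' randomBaseline(0.64)  # 0.5392
#' @export
randomBaseline <- function(pPos) {
    stopifnot(is.numeric(pPos), pPos >= 0, pPos <= 1)
    pPos^2 + (1 - pPos)^2
}

.foldAssignments <- function(n, k, seed) {
    set.seed(seed)
    sample(rep_len(seq_len(k), n))
}

.scoreNetworkMethod <- function(method, Atrain, alpha) {
    switch(method,
           sl2 = sl2Scores(Atrain),
           sl3 = sl3Scores(Atrain),
           spa = spaScores(Atrain),
           gcm = gcmScores(Atrain, gcmFit(Atrain, alpha = alpha)),
           stop("unknown method: ", method))
}

#' k-fold cross-validation of a polarity predictor
#'
#' Partitions the known-polarity connections into k random folds. Each
#' method is trained with the test fold withheld -- the SCM refits its
#' rule matrix on the remaining folds, the network-based methods see the
#' signed network with the test-fold entries zeroed -- then the test-fold
#' pairs are ranked by |score| and compared with their known signs. The
#' mean curve averages precision per rank over folds, truncated to the
#' shortest fold.
#'
#' @param method one of "scm", "gcm", "sl2", "sl3", "spa"
#' @param known data.frame of known pairs (`pre`, `post`, `sign`)
#' @param A [SignedConnectome-class] of the known polarities (needed for
#'   the network-based methods; rebuilt from `known` when `NULL`)
#' @param X,Y expression matrices (SCM only)
#' @param k number of folds (>= 2)
#' @param alpha regularization strength for "scm" / "gcm" ( `Inf` gives
#'   the heavily regularized GCM, i.e. the SL3 operating point)
#' @param seed fold-assignment seed
#' @return list with `mean` (the mean [PrecisionCurve-class]) and
#'   `folds` (per-fold curves)
#' @export
kfoldCV <- function(method = c("scm", "gcm", "sl2", "sl3", "spa"),
                    known, A = NULL, X = NULL, Y = NULL,
                    k = 10L, alpha = 31.92, seed = 1L) {
    method <- match.arg(method)
    stopifnot(k >= 2L, nrow(known) >= k)
    ids <- if (!is.null(A)) neuronIds(A) else neuronIds(X)
    if (is.null(A)) A <- .pairsToSigned(known, ids)
    fold <- .foldAssignments(nrow(known), k, seed)
    curves <- vector("list", k)
    for (f in seq_len(k)) {
        test <- known[fold == f, , drop = FALSE]
        train <- known[fold != f, , drop = FALSE]
        if (nrow(test) == 0L) stop("fold with no test pairs")
        scores <- if (method == "scm") {
            fit <- ridgeFit(buildDesign(X, Y, train), alpha = alpha)
            scmScores(X, fit, Y)
        } else {
            Atrain <- .pairsToSigned(train, ids)
            .scoreNetworkMethod(method, Atrain, alpha)
        }
        ranked <- rankPredictions(scores, test)
        curves[[f]] <- if (nrow(predTable(ranked)) == 0L) {
            .newCurve(data.frame(rank = integer(), hit = integer(),
                                 precision = numeric(), score = numeric()),
                      method)
        } else {
            precisionCurve(ranked, .pairsToSigned(test, ids))
        }
    }
    lens <- vapply(curves, function(cv) nrow(curveTable(cv)), integer(1))
    if (all(lens == 0L)) stop("no fold produced any prediction")
    if (any(lens == 0L))
        warning(sum(lens == 0L), " fold(s) produced no nonzero prediction ",
                "and are excluded from the mean curve")
    use <- curves[lens > 0L]
    len <- min(lens[lens > 0L])
    prec <- rowMeans(matrix(vapply(use,
                                   function(cv)
                                       curveTable(cv)$precision[seq_len(len)],
                                   numeric(len)),
                            nrow = len))
    meanCurve <- .newCurve(data.frame(rank = seq_len(len), precision = prec),
                           paste0(method, " (", k, "-fold mean)"))
    list(mean = meanCurve, folds = curves)
}

#' Training-fraction robustness experiment
#'
#' Refits the SCM on random subsamples of the known-polarity network and
#' scores the result against a fixed reference (typically the
#' CM-resolved complex connections), recording for each draw the rank at
#' the target precision and, optionally, the precision attained at a
#' fixed absolute-score cutoff.
#'
#' @inheritParams buildDesign
#' @param reference data.frame (`pre`, `post`, `sign`) evaluation set
#' @param fractions vector of training fractions in (0, 1]
#' @param reps random subsamples per fraction
#' @param alpha SCM regularization strength
#' @param target target precision (default 0.95)
#' @param cutoff optional fixed |score| cutoff at which to record the
#'   realized precision
#' @param seed base RNG seed
#' @return data.frame with one row per (fraction, rep):
#'   `fraction`, `rep`, `nTrain`, `rankAtTarget`, `precisionAtCutoff`
#' @export
subsampleExperiment <- function(X, Y, pairs, reference,
                                fractions = seq(0.1, 1, by = 0.1),
                                reps = 25L, alpha = 31.92, target = 0.95,
                                cutoff = NULL, seed = 1L) {
    stopifnot(all(fractions > 0), all(fractions <= 1))
    refConn <- .pairsToSigned(reference, neuronIds(X))
    grid <- expand.grid(rep = seq_len(reps), fraction = fractions)
    out <- lapply(seq_len(nrow(grid)), function(g) {
        fr <- grid$fraction[g]
        set.seed(seed + g)
        n <- max(1L, round(fr * nrow(pairs)))
        take <- if (fr >= 1) seq_len(nrow(pairs)) else
            sort(sample.int(nrow(pairs), n))
        train <- pairs[take, , drop = FALSE]
        fit <- ridgeFit(buildDesign(X, Y, train), alpha = alpha)
        ranked <- rankPredictions(scmScores(X, fit, Y), reference)
        curve <- precisionCurve(ranked, refConn)
        tp <- thresholdForPrecision(curve, target, quiet = TRUE)
        pc <- NA_real_
        if (!is.null(cutoff)) {
            t <- curveTable(curve)
            above <- t$score >= cutoff
            pc <- if (any(above)) t$precision[max(which(above))] else NA_real_
        }
        data.frame(fraction = fr, rep = grid$rep[g], nTrain = nrow(train),
                   rankAtTarget = tp$rank, precisionAtCutoff = pc)
    })
    do.call(rbind, out)
}

#' Union report of known and inferred polarities
#'
#' Combines the known network with CM-resolved complex connections and
#' above-threshold SCM predictions into one signed network, enforcing
#' that the contributing sets are disjoint, and tallies
#' excitatory/inhibitory counts and the E:I balance before and after.
#'
#' @param known [SignedConnectome-class] of known polarities
#' @param cmResolved [SignedConnectome-class] of CM-resolved complex
#'   connections (zeros elsewhere)
#' @param scmAdditions [SignedConnectome-class] of SCM predictions kept
#'   above the precision threshold, on pairs not covered by the other
#'   two sets
#' @return list with `counts` (data.frame of per-set +/- tallies),
#'   `union` (the merged [SignedConnectome-class]), `total` resolved
#'   polarities, `addedExcitatory`, `addedInhibitory` and E:I fractions
#'   before/after
#' @export
unionReport <- function(known, cmResolved, scmAdditions) {
    ks <- signMatrix(known); cs <- signMatrix(cmResolved)
    ss <- signMatrix(scmAdditions)
    stopifnot(identical(dimnames(ks), dimnames(cs)),
              identical(dimnames(ks), dimnames(ss)))
    overlap <- (ks != 0 & cs != 0) | (ks != 0 & ss != 0) | (cs != 0 & ss != 0)
    if (any(overlap)) {
        ij <- which(overlap, arr.ind = TRUE)
        stop("contributing sets overlap on ", nrow(ij), " pair(s), e.g. ",
             rownames(ks)[ij[1, 1]], " -> ", colnames(ks)[ij[1, 2]])
    }
    u <- ks + cs + ss
    tally <- function(m) c(positive = sum(m > 0), negative = sum(m < 0))
    counts <- rbind(known = tally(ks), cmResolved = tally(cs),
                    scmAdditions = tally(ss), union = tally(u))
    eiBefore <- sum(ks > 0) / max(1, sum(ks != 0))
    eiAfter <- sum(u > 0) / max(1, sum(u != 0))
    list(counts = as.data.frame(counts),
         union = SignedConnectome(u),
         total = sum(u != 0),
         addedExcitatory = sum(cs > 0) + sum(ss > 0),
         addedInhibitory = sum(cs < 0) + sum(ss < 0),
         excitatoryFractionBefore = eiBefore,
         excitatoryFractionAfter = eiAfter)
}
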