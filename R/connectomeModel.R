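#' Binarize an expression matrix
#'
#' The connectome model treats curated expression as presence/absence: a
#' gene is expressed in a neuron iff its value is strictly positive.
#' Weighted expression levels are deliberately not used -- the model
#' counts applicable wiring rules rather than weighting them.
#'
#' @param x an [ExpressionMatrix-class]
#' @return an ExpressionMatrix with values in \{0, 1\}
#' @export
binarizeExpression <- function(x) {
    stopifnot(is(x, "ExpressionMatrix"))
    ExpressionMatrix((exprValues(x) > 0) * 1)
}

.checkCMlabels <- function(X, O, Y) {
    if (!identical(geneIds(X), rownames(ruleWeights(O))))
        stop("NT labels of X do not match the rule network rows")
    if (!identical(geneIds(Y), colnames(ruleWeights(O))))
        stop("receptor labels of Y do not match the rule network columns")
    if (!identical(neuronIds(X), neuronIds(Y)))
        stop("X and Y must share the same neuron order")
    invisible(TRUE)
}

#' Connectome-model polarity weights
#'
#' Computes the weighted polarity score matrix B = X O Y' of the
#' connectome model (CM): entry `B[i, j]` sums the signed wiring rules
#' (O) applicable to the connection i -> j, i.e. rules whose NT is
#' expressed presynaptically (X) and whose receptor is expressed
#' postsynaptically (Y). Expression is binarized first, so with ternary
#' rules `B[i, j]` is (number of positive) minus (number of negative)
#' contributing rules.
#'
#' @param X presynaptic NT [ExpressionMatrix-class]
#' @param O signed [WiringRuleNetwork-class] (NT x receptor)
#' @param Y postsynaptic receptor [ExpressionMatrix-class]
#' @return a [ScoreMatrix-class] of CM weights over all neuron pairs;
#'   restrict to observed connections with a [ConnectomeMask-class] when
#'   ranking (see [rankPredictions()])
#' @examples
#' # one NT expressed presynaptically, 4 excitatory + 1 inhibitory rule
#' # receptors expressed postsynaptically: B = +3
#' X <- ExpressionMatrix(matrix(1, 1, 1, dimnames = list("pre", "Glu")))
#' Y <- ExpressionMatrix(matrix(1, 1, 5,
#'     dimnames = list("pre", paste0("r", 1:5))))
#' O <- WiringRuleNetwork(matrix(c(1, 1, 1, 1, -1), 1,
#'     dimnames = list("Glu", paste0("r", 1:5))))
#' @export
cmWeights <- function(X, O, Y) {
    stopifnot(is(X, "ExpressionMatrix"), is(O, "WiringRuleNetwork"),
              is(Y, "ExpressionMatrix"))
    .checkCMlabels(X, O, Y)
    Xb <- exprValues(binarizeExpression(X))
    Yb <- exprValues(binarizeExpression(Y))
    B <- Xb %*% ruleWeights(O) %*% t(Yb)
    ScoreMatrix(B, method = "CM")
}

#' Sign of a score matrix
#'
#' Element-wise sign extraction A = sign(B); a zero score stays zero
#' (the pair remains unresolved). Idempotent on its own output.
#'
#' @param B a [ScoreMatrix-class]
#' @return a [SignedConnectome-class]
#' @export
cmSign <- function(B) {
    stopifnot(is(B, "ScoreMatrix"))
    SignedConnectome(sign(scoreValues(B)))
}

#' Classify observed connections by wiring-rule support
#'
#' Assigns each mask-present directed connection to one of four
#' categories: `excluded` (the presynaptic neuron expresses no NT, or the
#' postsynaptic neuron no receptor), `known_positive` / `known_negative`
#' (at least one contributing rule and all of one sign), `complex`
#' (contributing rules of both signs) or `unknown` (expression on both
#' sides but no applicable rule). A contributing rule for (i, j) is a
#' pair (NT k, receptor l) with `X[i,k] > 0`, `Y[j,l] > 0` and
#' `O[k,l] != 0`.
#'
#' @inheritParams cmWeights
#' @param mask [ConnectomeMask-class] of observed connections
#' @return a [PolarityCatalog-class]
#' @export
classifyPairs <- function(X, O, Y, mask) {
    stopifnot(is(mask, "ConnectomeMask"))
    if (!isTernary(O))
        stop("classifyPairs requires a ternary rule network")
    .checkCMlabels(X, O, Y)
    if (!identical(neuronIds(mask), neuronIds(X)))
        stop("mask neuron order must match the expression matrices")
    Xb <- exprValues(binarizeExpression(X))
    Yb <- exprValues(binarizeExpression(Y))
    W <- ruleWeights(O)
    nPos <- Xb %*% (W > 0) %*% t(Yb)
    nNeg <- Xb %*% (W < 0) %*% t(Yb)
    hasNT <- rowSums(Xb) > 0
    hasR <- rowSums(Yb) > 0

    idx <- which(maskMatrix(mask) == 1, arr.ind = TRUE)
    # deterministic pair order: presynaptic then postsynaptic index
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    pos <- nPos[idx]
    neg <- nNeg[idx]
    category <- rep("unknown", nrow(idx))
    category[pos > 0 & neg == 0] <- "known_positive"
    category[neg > 0 & pos == 0] <- "known_negative"
    category[pos > 0 & neg > 0] <- "complex"
    category[!hasNT[idx[, 1]] | !hasR[idx[, 2]]] <- "excluded"
    sgn <- numeric(nrow(idx))
    sgn[category == "known_positive"] <- 1
    sgn[category == "known_negative"] <- -1
    ids <- neuronIds(X)
    PolarityCatalog(data.frame(pre = ids[idx[, 1]], post = ids[idx[, 2]],
                               category = category, sign = sgn,
                               stringsAsFactors = FALSE),
                    neuronIds = ids)
}

#' Resolve complex connections with CM weights
#'
#' A connection supported by wiring rules of both signs ("complex") is
#' resolved to the majority sign of its contributing rules, i.e. to
#' `sign(B)`; exact cancellation (B = 0) leaves it unresolved.
#'
#' @param B CM [ScoreMatrix-class] computed from the same X, O, Y as
#'   `catalog`
#' @param catalog [PolarityCatalog-class] from [classifyPairs()]
#' @return a [SignedConnectome-class] holding signs only on resolved
#'   complex connections (zero elsewhere)
#' @export
resolveComplex <- function(B, catalog) {
    stopifnot(is(B, "ScoreMatrix"), is(catalog, "PolarityCatalog"))
    ids <- neuronIds(B)
    out <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    p <- catalogTable(catalog)
    cx <- p[p$category == "complex", , drop = FALSE]
    if (nrow(cx)) {
        ij <- cbind(match(cx$pre, ids), match(cx$post, ids))
        out[ij] <- sign(scoreValues(B)[ij])
    }
    SignedConnectome(out)
}

#' Extract signed connections of known polarity
#'
#' @param catalog a [PolarityCatalog-class]
#' @return a [SignedConnectome-class] with the known_positive /
#'   known_negative signs and zeros elsewhere
#' @export
knownConnectome <- function(catalog) {
    stopifnot(is(catalog, "PolarityCatalog"))
    ids <- neuronIds(catalog)
    out <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    p <- catalogTable(catalog)
    kn <- p[p$sign != 0, , drop = FALSE]
    if (nrow(kn))
        out[cbind(match(kn$pre, ids), match(kn$post, ids))] <- kn$sign
    SignedConnectome(out)
}
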