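#' Build the truncated design matrix of the spatial connectome model
#'
#' The SCM solves a' = K' o for a minimal rule vector o, where a is the
#' row-major vectorization of the signed connectome and K = X (x) Y is
#' the Kronecker-product design. Only rows for connections of known
#' polarity are kept (spatial truncation); the full N^2 x (NT*R) matrix
#' is never materialized. The design row for pair (i, j) is the Kronecker
#' product of row i of the (binarized) NT expression and row j of the
#' receptor expression, so column (k-1)*nR + l corresponds to rule
#' (NT k, receptor l) -- the row-major vec convention used throughout.
#'
#' @param X presynaptic NT [ExpressionMatrix-class]
#' @param Y postsynaptic receptor [ExpressionMatrix-class]
#' @param pairs data.frame with columns `pre`, `post` (neuron labels) and
#'   `sign` (the known polarity, -1 or +1) -- typically the known rows of
#'   a [PolarityCatalog-class]
#' @return list with `K` (training design matrix, one row per pair) and
#'   `a` (the matching sign vector)
#' @export
buildDesign <- function(X, Y, pairs) {
    stopifnot(is(X, "ExpressionMatrix"), is(Y, "ExpressionMatrix"))
    if (!all(c("pre", "post", "sign") %in% names(pairs)))
        stop("'pairs' needs columns pre, post, sign")
    if (nrow(pairs) == 0L) stop("empty training set")
    if (any(!pairs$sign %in% c(-1, 1)))
        stop("every training pair must carry a known sign (-1 or +1)")
    Xb <- exprValues(binarizeExpression(X))
    Yb <- exprValues(binarizeExpression(Y))
    i <- match(pairs$pre, rownames(Xb))
    j <- match(pairs$post, rownames(Yb))
    if (anyNA(i) || anyNA(j)) stop("training pair with unknown neuron label")
    nK <- ncol(Xb); nR <- ncol(Yb)
    # row-wise Kronecker product: column (k-1)*nR + l  <->  rule (k, l)
    K <- Xb[i, rep(seq_len(nK), each = nR), drop = FALSE] *
         Yb[j, rep(seq_len(nR), times = nK), drop = FALSE]
    colnames(K) <- paste(rep(colnames(Xb), each = nR),
                         rep(colnames(Yb), times = nK), sep = ":")
    rownames(K) <- paste(pairs$pre, pairs$post, sep = "->")
    list(K = K, a = as.numeric(pairs$sign))
}

#' Ridge fit of the minimal wiring-rule vector
#'
#' Solves `argmin_o ||K' o - a'||^2 + alpha ||o||^2` by the normal
#' equations `o = (K'K' + alpha I)^-1 K' a'` and reshapes the solution
#' row-major into an NT x receptor rule matrix. At `alpha = 0` the
#' minimum-norm least-squares solution (Moore-Penrose pseudoinverse) is
#' used, with a warning when the normal matrix is singular.
#'
#' @param design list from [buildDesign()] (elements `K`, `a`)
#' @param alpha nonnegative regularization strength
#' @param ntIds,rIds NT / receptor labels of the rule matrix; defaults
#'   are recovered from the design column names
#' @return a real-valued [WiringRuleNetwork-class] (the learned rules)
#' @export
ridgeFit <- function(design, alpha, ntIds = NULL, rIds = NULL) {
    K <- design$K; a <- design$a
    stopifnot(is.matrix(K), length(a) == nrow(K), alpha >= 0)
    if (is.null(ntIds) || is.null(rIds)) {
        parts <- strsplit(colnames(K), ":", fixed = TRUE)
        ntIds <- unique(vapply(parts, `[`, "", 1L))
        rIds <- unique(vapply(parts, `[`, "", 2L))
    }
    p <- ncol(K)
    if (alpha > 0) {
        o <- solve(crossprod(K) + diag(alpha, p), crossprod(K, a))
    } else {
        G <- crossprod(K)
        if (rcond(G) < .Machine$double.eps) {
            warning("singular normal matrix at alpha = 0; using the ",
                    "minimum-norm pseudoinverse solution")
            o <- MASS::ginv(K) %*% a
        } else {
            o <- solve(G, crossprod(K, a))
        }
    }
    W <- matrix(as.numeric(o), nrow = length(ntIds), byrow = TRUE,
                dimnames = list(ntIds, rIds))
    WiringRuleNetwork(W, ternary = FALSE)
}

#' SCM prediction scores
#'
#' Substitutes the learned rule matrix back into the CM bilinear form:
#' `B~ = X O~ Y'`.
#'
#' @param X,Y expression matrices as in [cmWeights()]
#' @param Otilde learned [WiringRuleNetwork-class] from [ridgeFit()]
#' @return a [ScoreMatrix-class] with method tag "SCM"
#' @export
scmScores <- function(X, Otilde, Y) {
    stopifnot(is(Otilde, "WiringRuleNetwork"))
    .checkCMlabels(X, Otilde, Y)
    Xb <- exprValues(binarizeExpression(X))
    Yb <- exprValues(binarizeExpression(Y))
    ScoreMatrix(Xb %*% ruleWeights(Otilde) %*% t(Yb), method = "SCM")
}

#' Rank predictions by absolute score
#'
#' Orders the eligible directed pairs by decreasing `|score|` (stable
#' ties broken on presynaptic then postsynaptic label); zero-score pairs
#' carry no prediction and are dropped.
#'
#' @param scores a [ScoreMatrix-class]
#' @param eligible data.frame with columns `pre`, `post` naming the pairs
#'   to rank (e.g. mask-present pairs of a target category)
#' @return a [RankedPredictions-class]
#' @export
rankPredictions <- function(scores, eligible) {
    stopifnot(is(scores, "ScoreMatrix"))
    ids <- neuronIds(scores)
    i <- match(eligible$pre, ids); j <- match(eligible$post, ids)
    if (anyNA(i) || anyNA(j)) stop("eligible pair with unknown neuron label")
    s <- scoreValues(scores)[cbind(i, j)]
    keep <- s != 0
    tab <- data.frame(pre = as.character(eligible$pre)[keep],
                      post = as.character(eligible$post)[keep],
                      score = s[keep], stringsAsFactors = FALSE)
    ord <- order(-abs(tab$score), tab$pre, tab$post, method = "radix")
    tab <- tab[ord, , drop = FALSE]
    tab <- data.frame(rank = seq_len(nrow(tab)), tab, sign = sign(tab$score))
    .newRanked(tab, scoreMethod(scores))
}

#' Default logarithmic regularization grid
#'
#' @param from,to log10 endpoints
#' @param length number of grid points
#' @return increasing numeric vector of alphas
#' @export
alphaGridDefault <- function(from = -3, to = 3, length = 121L) {
    10^seq(from, to, length.out = length)
}

#' Select the SCM regularization strength
#'
#' Fits the SCM for each alpha on the training pairs, ranks the
#' reference pairs by the resulting scores, and picks the alpha that
#' maximizes the rank at which the target running precision is still
#' attained against the reference signs (ties broken toward larger
#' alpha, i.e. the smoothest competitive model).
#'
#' @inheritParams buildDesign
#' @param reference data.frame with columns `pre`, `post`, `sign`: the
#'   evaluation set (typically CM-resolved complex connections)
#' @param alphaGrid increasing positive grid, see [alphaGridDefault()]
#' @param target target precision (default 0.95)
#' @return list with `alpha` (chosen value), `rank` (its precision rank)
#'   and `table` (per-alpha ranks)
#' @export
selectAlpha <- function(X, Y, pairs, reference,
                        alphaGrid = alphaGridDefault(), target = 0.95) {
    stopifnot(all(alphaGrid > 0), !is.unsorted(alphaGrid))
    design <- buildDesign(X, Y, pairs)
    refConn <- .pairsToSigned(reference, neuronIds(X))
    ranks <- vapply(alphaGrid, function(al) {
        fit <- ridgeFit(design, alpha = al)
        ranked <- rankPredictions(scmScores(X, fit, Y), reference)
        curve <- precisionCurve(ranked, refConn)
        tp <- thresholdForPrecision(curve, target, quiet = TRUE)
        if (is.na(tp$rank)) 0L else as.integer(tp$rank)
    }, integer(1))
    best <- max(which(ranks == max(ranks)))  # ties -> larger alpha
    list(alpha = alphaGrid[best], rank = ranks[best],
         table = data.frame(alpha = alphaGrid, rankAtTarget = ranks))
}

.pairsToSigned <- function(pairs, ids) {
    out <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    if (nrow(pairs))
        out[cbind(match(pairs$pre, ids), match(pairs$post, ids))] <- pairs$sign
    SignedConnectome(out)
}
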