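#' Fit the generalized connectome model
#'
#' The GCM infers polarities from the signed network alone through the
#' bilinear equation A = A W A, where W is an unknown generalized rule
#' matrix absorbing both expression profiles and wiring rules. Two
#' solvers are provided:
#'
#' * `solver = "inverse"` (default): W(alpha) = (A'A + alpha I)^-1 A',
#'   the ridge-regularized pseudoinverse of A. This is the solution whose
#'   limits match the model's analytic behaviour: at alpha -> 0 it gives
#'   W = A+ (Moore-Penrose), so A W A refits the input exactly without
#'   inferring anything new, and at alpha -> infinity W is proportional
#'   to A', so the predictions reduce to the signed length-3 score
#'   A A' A (see [sl3Scores()]). `alpha = Inf` is accepted and returns
#'   W = A' directly.
#' * `solver = "dual"`: ridge regression of the vectorized equation with
#'   spatial truncation to the training pairs, exactly as in the SCM. The
#'   design row for pair (i, j) is the Kronecker product of row i and
#'   column j of A; because the feature count is N^2 the problem is
#'   solved in the dual, via the Gram matrix
#'   `G[(i,j),(i',j')] = <A_i., A_i'.> * <A_.j, A_.j'>`, and the full
#'   Kronecker design is never materialized.
#'
#' The two solvers agree in the alpha -> 0 refit limit but differ for
#' large alpha (the dual solution tends to A'AA' rather than A'); the
#' "inverse" solver is the default operating choice because the heavily
#' regularized limit is the recommended operating point.
#'
#' @param A [SignedConnectome-class] containing the known polarities
#'   (zeros elsewhere)
#' @param alpha nonnegative regularization strength; `Inf` allowed for
#'   `solver = "inverse"`
#' @param trainingPairs for `solver = "dual"`, data.frame with columns
#'   `pre`, `post`, `sign`; default: all nonzero entries of A
#' @param solver "inverse" or "dual"
#' @return a [GeneralizedRuleMatrix-class]
#' @export
gcmFit <- function(A, alpha, trainingPairs = NULL,
                   solver = c("inverse", "dual")) {
    stopifnot(is(A, "SignedConnectome"), alpha >= 0)
    solver <- match.arg(solver)
    s <- signMatrix(A)
    ids <- rownames(s)
    if (solver == "inverse") {
        W <- if (is.infinite(alpha)) {
            t(s)
        } else if (alpha == 0) {
            MASS::ginv(s)
        } else {
            solve(crossprod(s) + diag(alpha, ncol(s)), t(s))
        }
        dimnames(W) <- list(ids, ids)
        return(new("GeneralizedRuleMatrix", weights = W,
                   alpha = alpha, solver = solver))
    }
    if (is.infinite(alpha))
        stop("solver = \"dual\" requires finite alpha")
    if (is.null(trainingPairs)) {
        nz <- which(s != 0, arr.ind = TRUE)
        nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
        trainingPairs <- data.frame(pre = ids[nz[, 1]], post = ids[nz[, 2]],
                                    sign = s[nz], stringsAsFactors = FALSE)
    }
    if (nrow(trainingPairs) == 0L) stop("empty training set")
    i <- match(trainingPairs$pre, ids)
    j <- match(trainingPairs$post, ids)
    if (anyNA(i) || anyNA(j)) stop("training pair with unknown neuron label")
    a <- as.numeric(trainingPairs$sign)
    R <- tcrossprod(s)          # row inner products  <A_i., A_i'.>
    C <- crossprod(s)           # column inner products <A_.j, A_.j'>
    G <- R[i, i, drop = FALSE] * C[j, j, drop = FALSE]
    d <- if (alpha > 0) {
        solve(G + diag(alpha, nrow(G)), a)
    } else {
        MASS::ginv(G) %*% a     # minimum-norm solution of K'w = a'
    }
    # W = sum_m d_m * outer(A[i_m, ], A[, j_m])
    W <- crossprod(s[i, , drop = FALSE] * as.numeric(d), t(s)[j, , drop = FALSE])
    dimnames(W) <- list(ids, ids)
    new("GeneralizedRuleMatrix", weights = W, alpha = alpha, solver = solver)
}

#' GCM prediction scores
#'
#' Evaluates the fitted bilinear form A* = A W A. The prediction is
#' cubic in the input network (doubling A multiplies the heavily
#' regularized scores by 8).
#'
#' @param A [SignedConnectome-class] used for the fit
#' @param W a [GeneralizedRuleMatrix-class] from [gcmFit()]
#' @return a [ScoreMatrix-class] with method tag "GCM"
#' @export
gcmScores <- function(A, W) {
    stopifnot(is(A, "SignedConnectome"), is(W, "GeneralizedRuleMatrix"))
    s <- signMatrix(A)
    if (!identical(rownames(s), rownames(ruleWeights(W))))
        stop("network and rule matrix neuron orders differ")
    ScoreMatrix(s %*% ruleWeights(W) %*% s, method = "GCM")
}
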