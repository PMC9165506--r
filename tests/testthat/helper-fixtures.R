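# Small in-code fixtures shared across the suite.

namedMatrix <- function(v, rows, cols) {
    matrix(v, length(rows), length(cols), byrow = TRUE,
           dimnames = list(rows, cols))
}

# random ternary signed directed network with empty diagonal
randomSigned <- function(n, seed, pNeg = 0.15, pPos = 0.25) {
    set.seed(seed)
    s <- matrix(sample(c(-1, 0, 1), n * n, replace = TRUE,
                       prob = c(pNeg, 1 - pNeg - pPos, pPos)), n,
                dimnames = list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n)))
    diag(s) <- 0
    SignedConnectome(s)
}

# random small CM instance for brute-force comparisons
randomCMInstance <- function(nNeuron, nNT, nR, seed) {
    set.seed(seed)
    neurons <- paste0("n", seq_len(nNeuron))
    nts <- paste0("t", seq_len(nNT))
    rs <- paste0("r", seq_len(nR))
    X <- ExpressionMatrix(matrix(rbinom(nNeuron * nNT, 1, 0.5) *
                                 runif(nNeuron * nNT, 0.5, 2),
                                 nNeuron, dimnames = list(neurons, nts)))
    Y <- ExpressionMatrix(matrix(rbinom(nNeuron * nR, 1, 0.5) *
                                 runif(nNeuron * nR, 0.5, 2),
                                 nNeuron, dimnames = list(neurons, rs)))
    O <- WiringRuleNetwork(matrix(sample(c(-1, 0, 1), nNT * nR, TRUE),
                                  nNT, dimnames = list(nts, rs)))
    list(X = X, O = O, Y = Y)
}

# quadruple-loop oracle for the CM bilinear form (binarized expression)
bruteForceCM <- function(X, O, Y) {
    Xv <- (exprValues(X) > 0) * 1
    Yv <- (exprValues(Y) > 0) * 1
    W <- ruleWeights(O)
    n <- nrow(Xv)
    B <- matrix(0, n, n, dimnames = list(rownames(Xv), rownames(Yv)))
    for (i in seq_len(n)) for (j in seq_len(n))
        for (k in seq_len(ncol(Xv))) for (l in seq_len(ncol(Yv)))
            B[i, j] <- B[i, j] + Xv[i, k] * W[k, l] * Yv[j, l]
    B
}

# path-enumeration oracle for signed length-3 scores:
# forward step i -> x, backward step x <- y, forward step y -> j;
# each path contributes the product of its three edge signs
bruteForceSL3 <- function(A) {
    s <- signMatrix(A)
    n <- nrow(s)
    P <- matrix(0, n, n, dimnames = dimnames(s))
    for (i in 1:n) for (j in 1:n)
        for (x in 1:n) for (y in 1:n)
            P[i, j] <- P[i, j] + s[i, x] * s[y, x] * s[y, j]
    P
}

# explicit Kronecker design row for the GCM: features (k, l) = A[i,k]*A[l,j]
gcmDesignRow <- function(s, i, j) {
    as.vector(t(outer(s[i, ], s[, j])))
}

# primal Kronecker ridge for the GCM on small networks
bruteForceGCMRidge <- function(A, pairs, alpha) {
    s <- signMatrix(A)
    ids <- rownames(s)
    K <- t(vapply(seq_len(nrow(pairs)), function(m)
        gcmDesignRow(s, match(pairs$pre[m], ids), match(pairs$post[m], ids)),
        numeric(nrow(s)^2)))
    a <- pairs$sign
    w <- solve(crossprod(K) + diag(alpha, ncol(K)), crossprod(K, a))
    matrix(w, nrow(s), byrow = TRUE, dimnames = dimnames(s))
}

trainingPairsOf <- function(A) {
    s <- signMatrix(A)
    nz <- which(s != 0, arr.ind = TRUE)
    nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
    data.frame(pre = rownames(s)[nz[, 1]], post = colnames(s)[nz[, 2]],
               sign = s[nz], stringsAsFactors = FALSE)
}

signedFromPairs <- function(pairs, ids) {
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(match(pairs$pre, ids), match(pairs$post, ids))] <- pairs$sign
    SignedConnectome(m)
}
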