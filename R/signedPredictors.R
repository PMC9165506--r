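#' Signed in/out degrees of a signed directed network
#'
#' @param A a [SignedConnectome-class]
#' @return data.frame with one row per neuron and columns `kPlusOut`,
#'   `kMinusOut`, `kPlusIn`, `kMinusIn` (counts of signed edges; edges of
#'   unknown polarity do not contribute)
#' @export
signedDegrees <- function(A) {
    stopifnot(is(A, "SignedConnectome"))
    s <- signMatrix(A)
    data.frame(neuron = rownames(s),
               kPlusOut = rowSums(s > 0), kMinusOut = rowSums(s < 0),
               kPlusIn = colSums(s > 0), kMinusIn = colSums(s < 0),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Signed paths of length two (structural balance)
#'
#' Signed common-neighbour similarity of a directed network. `S_in = A'A`
#' counts shared presynaptic partners (with the product of edge signs),
#' `S_out = AA'` shared postsynaptic partners; the SL2 score is their
#' sum, `P = A'A + AA'`. Even path length makes the score invariant to a
#' global sign flip of the network.
#'
#' @param A a [SignedConnectome-class] of known polarities
#' @return a [ScoreMatrix-class] with method tag "SL2"
#' @export
sl2Scores <- function(A) {
    stopifnot(is(A, "SignedConnectome"))
    s <- signMatrix(A)
    ScoreMatrix(crossprod(s) + tcrossprod(s), method = "SL2")
}

#' Signed paths of length three
#'
#' `P = A A' A`: each path i -> x <- y -> j (forward, backward, forward
#' steps) contributes the product of its three edge signs. Equivalently
#' `P = A S_in = S_out A`: a partner is predicted inhibited when
#' similarly-connected partners are mostly inhibited.
#'
#' @param A a [SignedConnectome-class] of known polarities
#' @return a [ScoreMatrix-class] with method tag "SL3"
#' @export
sl3Scores <- function(A) {
    stopifnot(is(A, "SignedConnectome"))
    s <- signMatrix(A)
    ScoreMatrix(s %*% t(s) %*% s, method = "SL3")
}

#' Signed preferential attachment
#'
#' Treats the positive and negative layers as independent
#' preferential-attachment networks and scores their difference:
#' `P[i, j] = k_i^{+,out} k_j^{+,in} - k_i^{-,out} k_j^{-,in}`.
#'
#' @param A a [SignedConnectome-class] of known polarities
#' @return a [ScoreMatrix-class] with method tag "SPA"
#' @export
spaScores <- function(A) {
    stopifnot(is(A, "SignedConnectome"))
    d <- signedDegrees(A)
    P <- outer(d$kPlusOut, d$kPlusIn) - outer(d$kMinusOut, d$kMinusIn)
    dimnames(P) <- list(d$neuron, d$neuron)
    ScoreMatrix(P, method = "SPA")
}
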