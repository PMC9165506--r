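#' Generate a planted-rule synthetic dataset
#'
#' Draws Bernoulli NT and receptor expression, a sparse ternary planted
#' rule network and a Bernoulli directed connectome mask, then derives
#' the ground-truth signed network `A_full = sign(X O Y')` on the mask
#' and the polarity catalog exactly as [classifyPairs()] would, so the
#' full CM/SCM/GCM pipeline can be exercised without any downloaded
#' data. Complex connections whose rule contributions cancel exactly
#' stay unresolved (sign 0), mirroring real curated data. Optionally a
#' share of the known labels is hidden (relabelled `unknown`, providing
#' held-out ground truth) and retained known signs are flipped with a
#' noise probability.
#'
#' @param model a [PlantedModel-class] from [plantedModel()]
#' @return list with elements
#' \describe{
#'   \item{X, Y}{[ExpressionMatrix-class] NT / receptor expression}
#'   \item{O}{planted ternary [WiringRuleNetwork-class]}
#'   \item{mask}{[ConnectomeMask-class]}
#'   \item{Afull}{[SignedConnectome-class]: sign(X O Y') on the mask
#'     (ground truth, before hiding/noise)}
#'   \item{catalog}{observed [PolarityCatalog-class] after hiding and
#'     label noise}
#'   \item{Aknown}{[SignedConnectome-class] of the observed known signs}
#'   \item{hidden}{data.frame of hidden pairs with their true signs}
#'   \item{model}{the input model}
#' }
#' @export
generatePlanted <- function(model) {
    stopifnot(is(model, "PlantedModel"))
    set.seed(model@seed)
    n <- model@nNeurons
    neurons <- sprintf("n%03d", seq_len(n))
    nts <- sprintf("NT%d", seq_len(model@nNT))
    rs <- sprintf("R%02d", seq_len(model@nR))

    X <- matrix(rbinom(n * model@nNT, 1, model@pExpressNT), n,
                dimnames = list(neurons, nts))
    Y <- matrix(rbinom(n * model@nR, 1, model@pExpressR), n,
                dimnames = list(neurons, rs))
    O <- matrix(0, model@nNT, model@nR, dimnames = list(nts, rs))
    # Rule signs are stratified, not i.i.d.: with only a few dozen rules,
    # per-rule Bernoulli signs make the positive share of the derived
    # labels fluctuate wildly between seeds. Instead, each NT gets a
    # fixed count of excitatory rules (pRulePositive of its nonzero
    # slots), interleaved across receptors ordered by how many neurons
    # express them, so heavily and lightly used rules carry both signs.
    usage <- colSums(Y)
    for (k in seq_len(model@nNT)) {
        slots <- which(rbinom(model@nR, 1, model@ruleDensity) == 1)
        if (!length(slots)) next
        slots <- slots[order(usage[slots], decreasing = TRUE)]
        nPos <- round(model@pRulePositive * length(slots))
        sgn <- rep(-1, length(slots))
        if (nPos > 0)
            sgn[round(seq(1, length(slots), length.out = nPos))] <- 1
        O[k, slots] <- sgn
    }
    mask <- matrix(rbinom(n * n, 1, model@edgeDensity), n,
                   dimnames = list(neurons, neurons))
    diag(mask) <- 0

    if (sum(X) == 0 || sum(Y) == 0)
        stop("degenerate model: no expressed genes")
    if (sum(mask) == 0)
        stop("degenerate model: empty connectome mask")

    Xe <- ExpressionMatrix(X); Ye <- ExpressionMatrix(Y)
    Oe <- WiringRuleNetwork(O, ternary = TRUE)
    maske <- ConnectomeMask(mask)
    B <- scoreValues(cmWeights(Xe, Oe, Ye))
    Afull <- SignedConnectome(sign(B) * mask)
    catalog <- classifyPairs(Xe, Oe, Ye, maske)

    pairs <- catalogTable(catalog)
    known <- which(pairs$sign != 0)
    hidden <- pairs[integer(0), c("pre", "post", "sign")]
    if (model@hideFraction > 0 && length(known)) {
        nHide <- round(model@hideFraction * length(known))
        hideIdx <- sort(sample(known, nHide))
        hidden <- pairs[hideIdx, c("pre", "post", "sign")]
        pairs$category[hideIdx] <- "unknown"
        pairs$sign[hideIdx] <- 0
    }
    if (model@labelNoise > 0) {
        kn <- which(pairs$sign != 0)
        flip <- kn[rbinom(length(kn), 1, model@labelNoise) == 1]
        pairs$sign[flip] <- -pairs$sign[flip]
        pairs$category[flip] <- ifelse(pairs$sign[flip] > 0,
                                       "known_positive", "known_negative")
    }
    catalogObs <- PolarityCatalog(pairs, neurons)
    list(X = Xe, Y = Ye, O = Oe, mask = maske, Afull = Afull,
         catalog = catalogObs, Aknown = knownConnectome(catalogObs),
         hidden = hidden, model = model)
}

#' Known pairs of a catalog as a training table
#'
#' @param catalog a [PolarityCatalog-class]
#' @return data.frame with columns `pre`, `post`, `sign` for the
#'   known-polarity connections (the SCM training set)
#' @export
knownPairs <- function(catalog) {
    p <- catalogTable(catalog)
    p[p$sign != 0, c("pre", "post", "sign"), drop = FALSE]
}

#' Unresolved pairs of a catalog
#'
#' @param catalog a [PolarityCatalog-class]
#' @param categories which categories count as unresolved
#' @return data.frame with columns `pre`, `post`
#' @export
unresolvedPairs <- function(catalog,
                            categories = c("complex", "unknown")) {
    p <- catalogTable(catalog)
    p[p$category %in% categories, c("pre", "post"), drop = FALSE]
}
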