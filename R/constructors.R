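#' Construct an ExpressionMatrix
#'
#' @param values nonnegative numeric matrix, rows = neurons, cols = genes;
#'   dimnames are required and become the canonical labels
#' @return an [ExpressionMatrix-class] object
#' @examples
#' X <- ExpressionMatrix(matrix(c(1, 0), 2, 1,
#'     dimnames = list(c("n1", "n2"), "Glu")))
#' neuronIds(X)
#' @export
ExpressionMatrix <- function(values) {
    new("ExpressionMatrix", values = as.matrix(values))
}

#' Construct a WiringRuleNetwork
#'
#' @param weights NT x receptor numeric matrix with dimnames
#' @param ternary whether entries are restricted to \{-1, 0, +1\}
#'   (curated input rules); learned rule matrices use `FALSE`
#' @return a [WiringRuleNetwork-class] object
#' @export
WiringRuleNetwork <- function(weights, ternary = TRUE) {
    new("WiringRuleNetwork", weights = as.matrix(weights),
        ternary = isTRUE(ternary))
}

#' Construct a SignedConnectome
#'
#' @param signs square matrix over \{-1, 0, +1\}, rows = presynaptic
#' @return a [SignedConnectome-class] object
#' @export
SignedConnectome <- function(signs) {
    new("SignedConnectome", signs = as.matrix(signs))
}

#' Construct a ConnectomeMask
#'
#' @param present square binary matrix of observed directed connections
#' @return a [ConnectomeMask-class] object
#' @export
ConnectomeMask <- function(present) {
    new("ConnectomeMask", present = as.matrix(present))
}

#' Construct a PolarityCatalog
#'
#' @param pairs data.frame with columns `pre`, `post`, `category`, `sign`
#' @param neuronIds canonical neuron label order
#' @return a [PolarityCatalog-class] object
#' @export
PolarityCatalog <- function(pairs, neuronIds) {
    pairs$pre <- as.character(pairs$pre)
    pairs$post <- as.character(pairs$post)
    pairs$category <- as.character(pairs$category)
    pairs$sign <- as.numeric(pairs$sign)
    rownames(pairs) <- NULL
    new("PolarityCatalog", pairs = pairs, neuronIds = as.character(neuronIds))
}

#' Construct a ScoreMatrix
#'
#' @param scores square numeric matrix of prediction scores
#' @param method method tag ("CM", "SCM", "GCM", "SL2", "SL3", "SPA", ...)
#' @return a [ScoreMatrix-class] object
#' @export
ScoreMatrix <- function(scores, method = "score") {
    new("ScoreMatrix", scores = as.matrix(scores), method = method)
}

.newRanked <- function(table, method) {
    rownames(table) <- NULL
    new("RankedPredictions", table = table, method = method)
}

.newCurve <- function(table, method) {
    rownames(table) <- NULL
    new("PrecisionCurve", table = table, method = method)
}

#' Parameters of the planted-rule synthetic generator
#'
#' Default values emulate the curated *C. elegans* chemical-synapse
#' dataset the connectome-model family was developed on: 295 neurons,
#' 3 neurotransmitters, 42 active receptors, a sparse mixed-sign rule
#' network, a directed mask of a few thousand connections, and a known
#' polarity set that is roughly 64% excitatory. See the package vignette
#' for the calibration rationale.
#'
#' @param nNeurons,nNT,nR numbers of neurons, neurotransmitters, receptors
#' @param pExpressNT,pExpressR per-gene Bernoulli expression probabilities
#' @param ruleDensity fraction of nonzero planted rules
#' @param pRulePositive probability a nonzero rule is excitatory (+1)
#' @param edgeDensity density of the directed connectome mask
#' @param hideFraction share of known polarities relabelled unknown
#'   (hidden ground truth for recovery experiments)
#' @param labelNoise probability of flipping a retained known sign
#' @param seed integer RNG seed
#' @return a [PlantedModel-class] object
#' @examples
#' m <- plantedModel(nNeurons = 40, nR = 10, seed = 7L)
#' d <- generatePlanted(m)
#' table(catalogTable(d$catalog)$category)
#' @export
plantedModel <- function(nNeurons = 295L, nNT = 3L, nR = 42L,
                         pExpressNT = 0.4, pExpressR = 0.09,
                         ruleDensity = 0.28, pRulePositive = 0.61,
                         edgeDensity = 0.05, hideFraction = 0,
                         labelNoise = 0, seed = 1L) {
    new("PlantedModel", nNeurons = as.integer(nNeurons),
        nNT = as.integer(nNT), nR = as.integer(nR),
        pExpressNT = pExpressNT, pExpressR = pExpressR,
        ruleDensity = ruleDensity, pRulePositive = pRulePositive,
        edgeDensity = edgeDensity, hideFraction = hideFraction,
        labelNoise = labelNoise, seed = as.integer(seed))
}
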