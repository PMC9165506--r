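#' @import methods
NULL

.checkLabelledMatrix <- function(m, what) {
    msgs <- character()
    if (!is.matrix(m) || !is.numeric(m))
        return(sprintf("%s must be a numeric matrix", what))
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msgs <- c(msgs, sprintf("%s must have row and column names", what))
    else {
        if (anyDuplicated(rownames(m)))
            msgs <- c(msgs, sprintf("duplicate row labels in %s", what))
        if (anyDuplicated(colnames(m)))
            msgs <- c(msgs, sprintf("duplicate column labels in %s", what))
    }
    if (anyNA(m) || any(!is.finite(m)))
        msgs <- c(msgs, sprintf("%s contains missing or non-finite values", what))
    msgs
}

#' ExpressionMatrix: neuron-by-gene expression
#'
#' Nonnegative expression levels of neurotransmitter (NT) genes in
#' presynaptic neurons, or receptor (R) genes in postsynaptic neurons.
#' Rows are neurons, columns are genes; dimnames carry the labels and row
#' order is canonical for every downstream matrix.
#'
#' @slot values nonnegative numeric matrix with unique row/column names
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix", slots = c(values = "matrix"))

setValidity("ExpressionMatrix", function(object) {
    msgs <- .checkLabelledMatrix(object@values, "expression")
    if (!length(msgs) && any(object@values < 0))
        msgs <- "expression values must be nonnegative"
    if (length(msgs)) msgs else TRUE
})

#' WiringRuleNetwork: signed NT-by-receptor rule matrix
#'
#' A wiring rule links an NT (row) to a receptor (column): +1 if the
#' combination is excitatory, -1 if inhibitory, 0 if no rule. Curated
#' input rules are ternary; rule matrices learned by the spatial
#' connectome model carry real-valued weights (`ternary = FALSE`).
#'
#' @slot weights numeric NT x R matrix with unique dimnames
#' @slot ternary logical; if TRUE every entry must be in \{-1, 0, +1\}
#' @exportClass WiringRuleNetwork
setClass("WiringRuleNetwork",
         slots = c(weights = "matrix", ternary = "logical"))

setValidity("WiringRuleNetwork", function(object) {
    msgs <- .checkLabelledMatrix(object@weights, "rule weights")
    if (length(object@ternary) != 1L || is.na(object@ternary))
        msgs <- c(msgs, "'ternary' must be TRUE or FALSE")
    else if (!length(msgs) && object@ternary &&
             !all(object@weights %in% c(-1, 0, 1)))
        msgs <- c(msgs, "ternary rule network has entries outside {-1, 0, +1}")
    if (length(msgs)) msgs else TRUE
})

#' SignedConnectome: directed signed adjacency over \{-1, 0, +1\}
#'
#' Square matrix of known or inferred synaptic polarities; rows are
#' presynaptic neurons, columns postsynaptic. Zero means unknown or
#' absent, not "no effect".
#'
#' @slot signs square numeric matrix over \{-1, 0, +1\} with matching
#'   row/column names
#' @exportClass SignedConnectome
setClass("SignedConnectome", slots = c(signs = "matrix"))

.checkSquareNamed <- function(m, what) {
    msgs <- .checkLabelledMatrix(m, what)
    if (length(msgs)) return(msgs)
    if (nrow(m) != ncol(m))
        return(sprintf("%s must be square", what))
    if (!identical(rownames(m), colnames(m)))
        return(sprintf("%s row and column labels must match", what))
    character()
}

setValidity("SignedConnectome", function(object) {
    msgs <- .checkSquareNamed(object@signs, "sign matrix")
    if (!length(msgs) && !all(object@signs %in% c(-1, 0, 1)))
        msgs <- "sign matrix has entries outside {-1, 0, +1}"
    if (length(msgs)) msgs else TRUE
})

#' ConnectomeMask: binary directed adjacency of observed connections
#'
#' @slot present square binary matrix; `present[i, j] = 1` when a directed
#'   chemical connection i -> j exists in the reconstruction
#' @exportClass ConnectomeMask
setClass("ConnectomeMask", slots = c(present = "matrix"))

setValidity("ConnectomeMask", function(object) {
    msgs <- .checkSquareNamed(object@present, "mask")
    if (!length(msgs) && !all(object@present %in% c(0, 1)))
        msgs <- "mask must be binary"
    if (length(msgs)) msgs else TRUE
})

.CATEGORIES <- c("known_positive", "known_negative", "complex",
                 "unknown", "excluded")

#' PolarityCatalog: per-connection polarity category
#'
#' One row per directed connection present in the mask, with a category:
#' `known_positive` / `known_negative` (all contributing wiring rules
#' agree), `complex` (rules of both signs), `unknown` (expression present
#' but no applicable rule), `excluded` (no presynaptic NT or no
#' postsynaptic receptor expression). Known rows carry the matching sign;
#' all other rows have sign 0.
#'
#' @slot pairs data.frame with columns `pre`, `post`, `category`, `sign`
#' @slot neuronIds canonical neuron label order
#' @exportClass PolarityCatalog
setClass("PolarityCatalog",
         slots = c(pairs = "data.frame", neuronIds = "character"))

setValidity("PolarityCatalog", function(object) {
    p <- object@pairs
    need <- c("pre", "post", "category", "sign")
    if (!all(need %in% names(p)))
        return(sprintf("catalog must have columns %s",
                       paste(need, collapse = ", ")))
    msgs <- character()
    if (!all(p$category %in% .CATEGORIES))
        msgs <- c(msgs, "invalid category label")
    if (!all(p$pre %in% object@neuronIds) || !all(p$post %in% object@neuronIds))
        msgs <- c(msgs, "catalog refers to unknown neuron labels")
    if (anyDuplicated(paste(p$pre, p$post, sep = "\r")))
        msgs <- c(msgs, "duplicate directed pair in catalog")
    known <- p$category %in% c("known_positive", "known_negative")
    if (any(known)) {
        want <- ifelse(p$category[known] == "known_positive", 1, -1)
        if (!all(p$sign[known] == want))
            msgs <- c(msgs, "known pairs must carry the matching sign")
    }
    if (any(p$sign[!known] != 0))
        msgs <- c(msgs, "non-known pairs must have sign 0")
    if (length(msgs)) msgs else TRUE
})

#' ScoreMatrix: real-valued polarity prediction scores
#'
#' @slot scores square numeric matrix of prediction scores (neuron order
#'   as in the inputs); the magnitude ranks confidence, the sign is the
#'   predicted polarity
#' @slot method short tag of the scoring method ("CM", "SCM", "GCM",
#'   "SL2", "SL3", "SPA")
#' @exportClass ScoreMatrix
setClass("ScoreMatrix", slots = c(scores = "matrix", method = "character"))

setValidity("ScoreMatrix", function(object) {
    msgs <- .checkSquareNamed(object@scores, "score matrix")
    if (length(object@method) != 1L)
        msgs <- c(msgs, "'method' must be a single string")
    if (length(msgs)) msgs else TRUE
})

#' RankedPredictions: predictions ordered by absolute score
#'
#' Rows are directed pairs ordered by decreasing `|score|`, ties broken
#' on (pre, post) labels; zero-score pairs are excluded so every row has
#' a predicted sign in \{-1, +1\}. Rank starts at 1.
#'
#' @slot table data.frame with columns `rank`, `pre`, `post`, `score`,
#'   `sign`
#' @slot method scoring method tag
#' @exportClass RankedPredictions
setClass("RankedPredictions",
         slots = c(table = "data.frame", method = "character"))

setValidity("RankedPredictions", function(object) {
    t <- object@table
    need <- c("rank", "pre", "post", "score", "sign")
    if (!all(need %in% names(t)))
        return(sprintf("prediction table must have columns %s",
                       paste(need, collapse = ", ")))
    msgs <- character()
    if (nrow(t)) {
        if (!identical(as.integer(t$rank), seq_len(nrow(t))))
            msgs <- c(msgs, "ranks must be 1..n in order")
        if (is.unsorted(-abs(t$score)))
            msgs <- c(msgs, "rows must be ordered by decreasing |score|")
        if (!all(t$sign %in% c(-1, 1)))
            msgs <- c(msgs, "predicted signs must be -1 or +1")
        if (any(t$score == 0))
            msgs <- c(msgs, "zero-score pairs must be excluded")
    }
    if (length(msgs)) msgs else TRUE
})

#' PrecisionCurve: running precision of ranked sign predictions
#'
#' `precision[r]` is the fraction of the top-r predictions whose sign
#' matches the reference. `hit` is the per-rank 0/1 agreement indicator
#' and `score` the absolute prediction score at that rank, from which
#' operating-point cutoffs are read.
#'
#' @slot table data.frame with columns `rank`, `hit`, `precision`, `score`
#' @slot method scoring method tag
#' @exportClass PrecisionCurve
setClass("PrecisionCurve",
         slots = c(table = "data.frame", method = "character"))

setValidity("PrecisionCurve", function(object) {
    t <- object@table
    if (!all(c("rank", "precision") %in% names(t)))
        return("curve table must have columns rank and precision")
    # per-rank hit indicators are present for single curves (and must be
    # consistent with the running precision) but absent for fold means
    if ("hit" %in% names(t) && nrow(t) && !anyNA(t$hit) &&
        max(abs(cumsum(t$hit) / seq_len(nrow(t)) - t$precision)) > 1e-9)
        return("precision column inconsistent with hits")
    TRUE
})

#' GeneralizedRuleMatrix: neuron-by-neuron rule matrix of the GCM
#'
#' The generalized connectome model rewrites polarity inference as
#' A = A W A; this class holds the fitted W together with the solver and
#' regularization strength that produced it.
#'
#' @slot weights square numeric matrix (neuron order of the input network)
#' @slot alpha regularization strength used in the fit (may be `Inf`)
#' @slot solver "inverse" or "dual"
#' @exportClass GeneralizedRuleMatrix
setClass("GeneralizedRuleMatrix",
         slots = c(weights = "matrix", alpha = "numeric", solver = "character"))

setValidity("GeneralizedRuleMatrix", function(object) {
    msgs <- .checkSquareNamed(object@weights, "generalized rule matrix")
    if (length(msgs)) msgs else TRUE
})

#' PlantedModel: parameters of the synthetic planted-rule generator
#'
#' @slot nNeurons,nNT,nR dimensions of the generated data
#' @slot pExpressNT,pExpressR Bernoulli expression probabilities
#' @slot ruleDensity fraction of nonzero entries in the planted rule matrix
#' @slot pRulePositive probability that a nonzero rule is excitatory
#' @slot edgeDensity Bernoulli density of the directed connectome mask
#' @slot hideFraction share of known polarities relabelled unknown
#' @slot labelNoise probability of flipping a retained known sign
#' @slot seed integer RNG seed
#' @exportClass PlantedModel
setClass("PlantedModel",
         slots = c(nNeurons = "integer", nNT = "integer", nR = "integer",
                   pExpressNT = "numeric", pExpressR = "numeric",
                   ruleDensity = "numeric", pRulePositive = "numeric",
                   edgeDensity = "numeric", hideFraction = "numeric",
                   labelNoise = "numeric", seed = "integer"))

setValidity("PlantedModel", function(object) {
    probs <- c(object@pExpressNT, object@pExpressR, object@ruleDensity,
               object@pRulePositive, object@edgeDensity,
               object@hideFraction, object@labelNoise)
    msgs <- character()
    if (any(probs < 0) || any(probs > 1))
        msgs <- c(msgs, "all probabilities must lie in [0, 1]")
    if (object@nNeurons < 2L || object@nNT < 1L || object@nR < 1L)
        msgs <- c(msgs, "counts must be positive (and at least 2 neurons)")
    if (length(msgs)) msgs else TRUE
})
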