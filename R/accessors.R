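#' Accessors for SynapticPolarity classes
#'
#' Small accessor generics returning the underlying labelled matrices and
#' tables; user code should use these rather than reaching into slots.
#'
#' @param x an object of the matching class
#' @return the labelled matrix, character vector or data.frame held by
#'   the object
#' @name accessors
NULL

#' @rdname accessors
setMethod("neuronIds", "ExpressionMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("geneIds", "ExpressionMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @rdname accessors
setMethod("ruleWeights", "WiringRuleNetwork", function(x) x@weights)
#' @rdname accessors
setMethod("isTernary", "WiringRuleNetwork", function(x) x@ternary)

#' @rdname accessors
setMethod("neuronIds", "SignedConnectome", function(x) rownames(x@signs))
#' @rdname accessors
setMethod("signMatrix", "SignedConnectome", function(x) x@signs)

#' @rdname accessors
setMethod("neuronIds", "ConnectomeMask", function(x) rownames(x@present))
#' @rdname accessors
setMethod("maskMatrix", "ConnectomeMask", function(x) x@present)

#' @rdname accessors
setMethod("neuronIds", "PolarityCatalog", function(x) x@neuronIds)
#' @rdname accessors
setMethod("catalogTable", "PolarityCatalog", function(x) x@pairs)

#' @rdname accessors
setMethod("neuronIds", "ScoreMatrix", function(x) rownames(x@scores))
#' @rdname accessors
setMethod("scoreValues", "ScoreMatrix", function(x) x@scores)
#' @rdname accessors
setMethod("scoreMethod", "ScoreMatrix", function(x) x@method)

#' @rdname accessors
setMethod("predTable", "RankedPredictions", function(x) x@table)
#' @rdname accessors
setMethod("scoreMethod", "RankedPredictions", function(x) x@method)

#' @rdname accessors
setMethod("curveTable", "PrecisionCurve", function(x) x@table)
#' @rdname accessors
setMethod("scoreMethod", "PrecisionCurve", function(x) x@method)

#' @rdname accessors
setMethod("ruleWeights", "GeneralizedRuleMatrix", function(x) x@weights)

setMethod("show", "ExpressionMatrix", function(object) {
    cat(sprintf("ExpressionMatrix: %d neurons x %d genes, %d nonzero\n",
                nrow(object@values), ncol(object@values),
                sum(object@values > 0)))
})

setMethod("show", "WiringRuleNetwork", function(object) {
    w <- object@weights
    cat(sprintf("WiringRuleNetwork: %d NT x %d R (%s), %d positive / %d negative rules\n",
                nrow(w), ncol(w),
                if (object@ternary) "ternary" else "real-valued",
                sum(w > 0), sum(w < 0)))
})

setMethod("show", "SignedConnectome", function(object) {
    s <- object@signs
    cat(sprintf("SignedConnectome: %d neurons, %d signed connections (%d+ / %d-)\n",
                nrow(s), sum(s != 0), sum(s > 0), sum(s < 0)))
})

setMethod("show", "ConnectomeMask", function(object) {
    cat(sprintf("ConnectomeMask: %d neurons, %d directed connections\n",
                nrow(object@present), sum(object@present)))
})

setMethod("show", "PolarityCatalog", function(object) {
    tab <- table(factor(object@pairs$category, levels = .CATEGORIES))
    cat(sprintf("PolarityCatalog: %d directed connections\n", nrow(object@pairs)))
    for (nm in names(tab)) cat(sprintf("  %-15s %d\n", nm, tab[[nm]]))
})

setMethod("show", "ScoreMatrix", function(object) {
    cat(sprintf("ScoreMatrix [%s]: %d neurons, %d nonzero scores\n",
                object@method, nrow(object@scores), sum(object@scores != 0)))
})

setMethod("show", "RankedPredictions", function(object) {
    cat(sprintf("RankedPredictions [%s]: %d pairs\n",
                object@method, nrow(object@table)))
    if (nrow(object@table))
        print(utils::head(object@table, 5))
})

setMethod("show", "PrecisionCurve", function(object) {
    t <- object@table
    cat(sprintf("PrecisionCurve [%s]: %d ranks", object@method, nrow(t)))
    if (nrow(t)) cat(sprintf(", final precision %.3f", t$precision[nrow(t)]))
    cat("\n")
})

setMethod("show", "GeneralizedRuleMatrix", function(object) {
    cat(sprintf("GeneralizedRuleMatrix: %d neurons, solver=%s, alpha=%g\n",
                nrow(object@weights), object@solver, object@alpha))
})

setMethod("show", "PlantedModel", function(object) {
    cat(sprintf("PlantedModel: %d neurons, %d NT, %d R, edge density %.3f, seed %d\n",
                object@nNeurons, object@nNT, object@nR,
                object@edgeDensity, object@seed))
})
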