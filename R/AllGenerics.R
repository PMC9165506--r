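#' @rdname accessors
#' @export
setGeneric("neuronIds", function(x) standardGeneric("neuronIds"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("ruleWeights", function(x) standardGeneric("ruleWeights"))

#' @rdname accessors
#' @export
setGeneric("isTernary", function(x) standardGeneric("isTernary"))

#' @rdname accessors
#' @export
setGeneric("signMatrix", function(x) standardGeneric("signMatrix"))

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' @rdname accessors
#' @export
setGeneric("scoreMethod", function(x) standardGeneric("scoreMethod"))

#' @rdname accessors
#' @export
setGeneric("catalogTable", function(x) standardGeneric("catalogTable"))

#' @rdname accessors
#' @export
setGeneric("predTable", function(x) standardGeneric("predTable"))

#' @rdname accessors
#' @export
setGeneric("curveTable", function(x) standardGeneric("curveTable"))
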