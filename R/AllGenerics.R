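#' Accessors for BetaSet and ExprSet
#'
#' \code{betaValues} returns the beta-value matrix; \code{detectionP}
#' the detection p-value matrix; \code{exprsValues} the expression
#' matrix; \code{designTable} the sample design as a data.frame.
#'
#' @param object a \linkS4class{BetaSet} or \linkS4class{ExprSet}.
#' @return a matrix (accessors) or data.frame (\code{designTable}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("betaValues", function(object) standardGeneric("betaValues"))

#' @rdname accessors
#' @export
setGeneric("detectionP", function(object) standardGeneric("detectionP"))

#' @rdname accessors
#' @export
setGeneric("exprsValues", function(object) standardGeneric("exprsValues"))

#' @rdname accessors
#' @export
setGeneric("designTable", function(object) standardGeneric("designTable"))

#' @rdname accessors
setMethod("betaValues", "BetaSet", function(object) assay(object, "beta"))

#' @rdname accessors
setMethod("detectionP", "SummarizedExperiment",
          function(object) assay(object, "detection"))

#' @rdname accessors
setMethod("exprsValues", "ExprSet", function(object) assay(object, "exprs"))

#' @rdname accessors
setMethod("designTable", "SummarizedExperiment", function(object) {
    as.data.frame(colData(object))
})
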