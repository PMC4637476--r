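#' @export
setGeneric("spotData", function(x) standardGeneric("spotData"))
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @export
setGeneric("arrayStage", function(x) standardGeneric("arrayStage"))
#' @export
setGeneric("excludedSamples", function(x) standardGeneric("excludedSamples"))
#' @export
setGeneric("nReplicatesUsed", function(x) standardGeneric("nReplicatesUsed"))
#' @export
setGeneric("removalOrder", function(x) standardGeneric("removalOrder"))
#' @export
setGeneric("klCurve", function(x) standardGeneric("klCurve"))
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))
#' @export
setGeneric("decisionValues", function(x, ...) standardGeneric("decisionValues"))
#' @export
setGeneric("violations", function(x) standardGeneric("violations"))
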