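## Generics for accessor functions. Slot access from user code should go
## through these.

#' @rdname AmplificationPlate-class
#' @param x an object.
#' @export
setGeneric("curves", function(x) standardGeneric("curves"))

#' @rdname AmplificationPlate-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname RichardsFit-class
#' @param x an object.
#' @export
setGeneric("cy0", function(x) standardGeneric("cy0"))

#' @rdname PlateQuant-class
#' @param x an object.
#' @export
setGeneric("wellData", function(x) standardGeneric("wellData"))

#' @rdname PlateQuant-class
#' @export
setGeneric("ampliconEfficiency", function(x) standardGeneric("ampliconEfficiency"))

#' @rdname PlateQuant-class
#' @export
setGeneric("excludedWells", function(x) standardGeneric("excludedWells"))

#' @rdname ConditionGroup-class
#' @param x an object.
#' @export
setGeneric("rfp", function(x) standardGeneric("rfp"))

#' @rdname ConditionGroup-class
#' @export
setGeneric("gfp", function(x) standardGeneric("gfp"))

#' @rdname CombinationRatios-class
#' @param x an object.
#' @export
setGeneric("ratios", function(x) standardGeneric("ratios"))

#' @rdname ContrastResult-class
#' @param x an object.
#' @export
setGeneric("smcv", function(x) standardGeneric("smcv"))

#' @rdname ContrastResult-class
#' @export
setGeneric("cplusProb", function(x) standardGeneric("cplusProb"))

#' @rdname ContrastResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname ContrastResult-class
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))

#' @rdname FlowEventSet-class
#' @param x an object.
#' @export
setGeneric("eventData", function(x) standardGeneric("eventData"))

#' @rdname MixtureFit-class
#' @param x an object.
#' @export
setGeneric("componentWeights", function(x) standardGeneric("componentWeights"))

#' @rdname MixtureFit-class
#' @export
setGeneric("componentMeans", function(x) standardGeneric("componentMeans"))

#' @rdname MixtureFit-class
#' @export
setGeneric("componentVariances", function(x) standardGeneric("componentVariances"))

#' @rdname MixtureFit-class
#' @export
setGeneric("inducedComponent", function(x) standardGeneric("inducedComponent"))

#' @rdname MixtureFit-class
#' @export
setGeneric("inducedAssignment", function(x) standardGeneric("inducedAssignment"))

#' @rdname VariantTally-class
#' @param x an object.
#' @export
setGeneric("tallyTable", function(x) standardGeneric("tallyTable"))
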