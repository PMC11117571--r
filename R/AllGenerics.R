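## Accessor generics. Slot access from user code should go through these.

#' @rdname EMGRecording-class
#' @param object an object of the documented class.
#' @export
setGeneric("emgSamples", function(object) standardGeneric("emgSamples"))

#' @rdname EMGRecording-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname EMGRecording-class
#' @export
setGeneric("muscleNames", function(object) standardGeneric("muscleNames"))

#' @rdname EMGRecording-class
#' @export
setGeneric("processingStage", function(object) standardGeneric("processingStage"))

#' @rdname ActivationMatrix-class
#' @param object an object of the documented class.
#' @export
setGeneric("activationValues", function(object) standardGeneric("activationValues"))

#' @rdname SynergyDecomposition-class
#' @param object an object of the documented class.
#' @export
setGeneric("synergyVectors", function(object) standardGeneric("synergyVectors"))

#' @rdname SynergyDecomposition-class
#' @export
setGeneric("activationCoefficients", function(object) standardGeneric("activationCoefficients"))

#' @rdname SynergyDecomposition-class
#' @export
setGeneric("vafGlobalOf", function(object) standardGeneric("vafGlobalOf"))

#' @rdname SynergyDecomposition-class
#' @export
setGeneric("vafLocalOf", function(object) standardGeneric("vafLocalOf"))

#' @rdname SynergyDecomposition-class
#' @export
setGeneric("lossTrace", function(object) standardGeneric("lossTrace"))

#' @rdname SynergyRankSelection-class
#' @param object an object of the documented class.
#' @export
setGeneric("noptSynergies", function(object) standardGeneric("noptSynergies"))

#' @rdname ReferenceSynergySet-class
#' @param object an object of the documented class.
#' @export
setGeneric("referenceCentroids", function(object) standardGeneric("referenceCentroids"))

#' @rdname SynergyMatch-class
#' @param object an object of the documented class.
#' @export
setGeneric("matchTable", function(object) standardGeneric("matchTable"))

setMethod("emgSamples", "EMGRecording", function(object) object@samples)
setMethod("samplingRate", "EMGRecording", function(object) object@fs)
setMethod("muscleNames", "EMGRecording", function(object) object@muscleNames)
setMethod("processingStage", "EMGRecording", function(object) object@stage)
setMethod("muscleNames", "ActivationMatrix", function(object) object@muscleNames)
setMethod("activationValues", "ActivationMatrix", function(object) object@values)
setMethod("synergyVectors", "SynergyDecomposition", function(object) object@W)
setMethod("activationCoefficients", "SynergyDecomposition", function(object) object@C)
setMethod("vafGlobalOf", "SynergyDecomposition", function(object) object@vafGlobal)
setMethod("vafLocalOf", "SynergyDecomposition", function(object) object@vafLocal)
setMethod("lossTrace", "SynergyDecomposition", function(object) object@lossTrace)
setMethod("noptSynergies", "SynergyRankSelection", function(object) object@nopt)
setMethod("referenceCentroids", "ReferenceSynergySet", function(object) object@centroids)
setMethod("matchTable", "SynergyMatch", function(object) object@table)
setMethod("muscleNames", "SynergyPool", function(object) object@muscleNames)
setMethod("muscleNames", "GroundTruth", function(object) object@muscleNames)
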