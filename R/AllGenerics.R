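#' @rdname IMMSDataset-class
#' @param object An object.
#' @export
setGeneric("featureTable", function(object) standardGeneric("featureTable"))

#' @rdname IMMSDataset-class
#' @export
setGeneric("imsPlatform", function(object) standardGeneric("imsPlatform"))

#' @rdname IMMSDataset-class
#' @export
setGeneric("mobilityAxis", function(object) standardGeneric("mobilityAxis"))

#' @rdname IMMSDataset-class
#' @export
setGeneric("quadWindow", function(object) standardGeneric("quadWindow"))

#' @rdname MobilitySpectrum-class
#' @param object An object.
#' @export
setGeneric("spectrumAxis", function(object) standardGeneric("spectrumAxis"))

#' @rdname MobilitySpectrum-class
#' @export
setGeneric("spectrumIntensity", function(object) standardGeneric("spectrumIntensity"))

#' @rdname AssignmentSet-class
#' @param object An object.
#' @export
setGeneric("assignmentTable", function(object) standardGeneric("assignmentTable"))

#' @rdname AssignmentSet-class
#' @export
setGeneric("assignmentEvidence", function(object) standardGeneric("assignmentEvidence"))

#' @rdname AssignmentSet-class
#' @export
setGeneric("residualPeaks", function(object) standardGeneric("residualPeaks"))

#' @rdname AssignmentSet-class
#' @export
setGeneric("assignmentWarnings", function(object) standardGeneric("assignmentWarnings"))

#' @rdname ElementalComposition-class
#' @param object An object.
#' @export
setGeneric("elementCounts", function(object) standardGeneric("elementCounts"))

#' Mass of a composition or envelope-bearing object
#'
#' @param object An object with a well-defined molecular mass.
#' @param ... Passed to methods; see [compositionMass()].
#' @export
setGeneric("moleculeMass", function(object, ...) standardGeneric("moleculeMass"))
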