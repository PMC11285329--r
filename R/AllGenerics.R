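#' Accessors for speclean classes
#'
#' @param object An object of the documented class.
#' @param key Metadata key (harmonized, lowercase).
#' @param default Value returned when `key` is absent.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spectrumMetadata", function(object) standardGeneric("spectrumMetadata"))

#' @rdname accessors
#' @export
setGeneric("metadataValue", function(object, key, default = NULL)
    standardGeneric("metadataValue"))

#' @rdname accessors
#' @export
setGeneric("peaksMz", function(object) standardGeneric("peaksMz"))

#' @rdname accessors
#' @export
setGeneric("peaksIntensity", function(object) standardGeneric("peaksIntensity"))

#' @rdname accessors
#' @export
setGeneric("peakCount", function(object) standardGeneric("peakCount"))

#' @rdname accessors
#' @export
setGeneric("adductName", function(object) standardGeneric("adductName"))

#' @rdname accessors
#' @export
setGeneric("adductIonmode", function(object) standardGeneric("adductIonmode"))

#' @rdname accessors
#' @export
setGeneric("adductCharge", function(object) standardGeneric("adductCharge"))

#' @rdname accessors
#' @export
setGeneric("adductMultiplier", function(object) standardGeneric("adductMultiplier"))

#' @rdname accessors
#' @export
setGeneric("adductMassShift", function(object) standardGeneric("adductMassShift"))

#' @rdname accessors
#' @export
setGeneric("outcomeStatus", function(object) standardGeneric("outcomeStatus"))

#' @rdname accessors
#' @export
setGeneric("reportCounts", function(object) standardGeneric("reportCounts"))

#' @rdname accessors
#' @export
setGeneric("reportTotals", function(object) standardGeneric("reportTotals"))

#' @rdname accessors
#' @export
setGeneric("workflowFilters", function(object) standardGeneric("workflowFilters"))

#' @rdname accessors
#' @export
setGeneric("workflowPreset", function(object) standardGeneric("workflowPreset"))
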