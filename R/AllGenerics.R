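#' @rdname accessors
#' @export
setGeneric("organ", function(x) standardGeneric("organ"))

#' @rdname accessors
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname accessors
#' @export
setGeneric("binVolume", function(x) standardGeneric("binVolume"))

#' @rdname accessors
#' @export
setGeneric("totalVolumeCc", function(x) standardGeneric("totalVolumeCc"))

#' @rdname accessors
#' @export
setGeneric("doseGrid", function(x) standardGeneric("doseGrid"))

#' @rdname accessors
#' @export
setGeneric("volumeAtOrAbove", function(x) standardGeneric("volumeAtOrAbove"))

#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname accessors
#' @export
setGeneric("technique", function(x) standardGeneric("technique"))

#' @rdname accessors
#' @export
setGeneric("organs", function(x) standardGeneric("organs"))

#' @rdname dvh-conversion
#' @export
setGeneric("toDifferential", function(x, ...) standardGeneric("toDifferential"))

#' @rdname dvh-conversion
#' @export
setGeneric("toCumulative", function(x, ...) standardGeneric("toCumulative"))

#' @rdname rebin
#' @export
setGeneric("rebin", function(x, width = 0.1, ...) standardGeneric("rebin"))

#' @rdname dose-summaries
#' @export
setGeneric("meanDose", function(x, ...) standardGeneric("meanDose"))

#' @rdname dose-summaries
#' @export
setGeneric("maxDose", function(x, tol = 1e-9, ...) standardGeneric("maxDose"))

#' @rdname dvhSurvival
#' @export
setGeneric("dvhSurvival", function(x, ...) standardGeneric("dvhSurvival"))

#' @rdname exactSignTest
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
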