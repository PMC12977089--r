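#' @name prsbrainmap-accessors
#' @title Accessors for prsbrainmap S4 containers
#' @description Slot accessors: prefer these over `@`.
#' @param object a prsbrainmap S4 object.
#' @param x a prsbrainmap S4 object.
NULL

#' @rdname prsbrainmap-accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname prsbrainmap-accessors
#' @export
setGeneric("effectSizes", function(x) standardGeneric("effectSizes"))

#' @rdname prsbrainmap-accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname prsbrainmap-accessors
#' @export
setGeneric("contrastType", function(x) standardGeneric("contrastType"))

#' @rdname prsbrainmap-accessors
#' @export
setGeneric("sumstats", function(x) standardGeneric("sumstats"))

#' @rdname prsbrainmap-accessors
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))

#' @rdname prsbrainmap-accessors
#' @export
setGeneric("instrumentTable", function(x) standardGeneric("instrumentTable"))

#' @rdname prsbrainmap-accessors
#' @export
setGeneric("nInstruments", function(x) standardGeneric("nInstruments"))

#' @rdname prsbrainmap-accessors
#' @export
setGeneric("estimate", function(x) standardGeneric("estimate"))

#' @rdname prsbrainmap-accessors
#' @export
setGeneric("stdError", function(x) standardGeneric("stdError"))

#' @rdname prsbrainmap-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname prsbrainmap-accessors
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))

#' @rdname prsbrainmap-accessors
#' @export
setGeneric("oddsRatioCI", function(x) standardGeneric("oddsRatioCI"))

#' @rdname prsbrainmap-accessors
#' @export
setGeneric("removedSnps", function(x) standardGeneric("removedSnps"))

#' @rdname prsbrainmap-accessors
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))

#' @rdname prsbrainmap-accessors
#' @export
setGeneric("prsScores", function(x) standardGeneric("prsScores"))

#' @rdname prsbrainmap-accessors
#' @export
setGeneric("diagnoses", function(x) standardGeneric("diagnoses"))

#' @rdname prsbrainmap-accessors
#' @export
setGeneric("cohortCovariates", function(x) standardGeneric("cohortCovariates"))

#' @rdname prsbrainmap-accessors
#' @export
setGeneric("brainMeasures", function(x, ...) standardGeneric("brainMeasures"))

#' @rdname prsbrainmap-accessors
#' @export
setGeneric("diseases", function(x) standardGeneric("diseases"))
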