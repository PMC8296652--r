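#' @include AllClasses.R
NULL

#' @export
setGeneric("betaValues", function(x, ...) standardGeneric("betaValues"))

#' @export
setGeneric("cpgAnnotation", function(x, ...) standardGeneric("cpgAnnotation"))

#' @export
setGeneric("cpgRanges", function(x, ...) standardGeneric("cpgRanges"))

#' @export
setGeneric("exprValues", function(x, ...) standardGeneric("exprValues"))

#' @export
setGeneric("valueKind", function(x, ...) standardGeneric("valueKind"))

#' @export
setGeneric("referenceGene", function(x, ...) standardGeneric("referenceGene"))

#' @export
setGeneric("statusCalls", function(x, ...) standardGeneric("statusCalls"))

#' @export
setGeneric("sampleStatus", function(x, ...) standardGeneric("sampleStatus"))

#' @export
setGeneric("medianBeta", function(x, ...) standardGeneric("medianBeta"))

#' @export
setGeneric("traitRecords", function(x, ...) standardGeneric("traitRecords"))

#' @export
setGeneric("traitInfo", function(x, ...) standardGeneric("traitInfo"))

#' @export
setGeneric("betaMatrices", function(x, ...) standardGeneric("betaMatrices"))

#' @export
setGeneric("cohortExpression", function(x, ...) standardGeneric("cohortExpression"))

#' @export
setGeneric("cohortTraits", function(x, ...) standardGeneric("cohortTraits"))

#' @export
setGeneric("cohortCovariates", function(x, ...) standardGeneric("cohortCovariates"))

#' @export
setGeneric("trueStatus", function(x, ...) standardGeneric("trueStatus"))

#' @export
setGeneric("concordance", function(x, ...) standardGeneric("concordance"))

#' @export
setGeneric("discordantSamples", function(x, ...) standardGeneric("discordantSamples"))
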