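#' @name phaseOrder-generics
#' @title Generics for phaseOrder
#' @description S4 generics for the main analysis verbs; methods are
#'   documented with their \code{PhaseStudy} implementations.
#' @keywords internal
NULL

#' @export
setGeneric("phaseAngles", function(x) standardGeneric("phaseAngles"))

#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @export
setGeneric("experimentGroups", function(x) standardGeneric("experimentGroups"))

#' @export
setGeneric("kappaValues", function(x) standardGeneric("kappaValues"))

#' @export
setGeneric("experimentWeights",
           function(x) standardGeneric("experimentWeights"))

#' @export
setGeneric("msce", function(study, order, ...) standardGeneric("msce"))

#' @export
setGeneric("estimateOrder",
           function(study, alpha = 3, ...) standardGeneric("estimateOrder"))

#' @export
setGeneric("circularLocalMinimization", function(order, study, ...)
  standardGeneric("circularLocalMinimization"))

#' @export
setGeneric("resampleStudy",
           function(study, seed = NULL, ...) standardGeneric("resampleStudy"))

#' @export
setGeneric("testCommonOrder", function(study, B = 1000L, seed = 1L, ...)
  standardGeneric("testCommonOrder"))

#' @export
setGeneric("confidencePartialOrder",
           function(study, B = 1000L, seed = 1L, freqThreshold = 0.10, ...)
  standardGeneric("confidencePartialOrder"))

#' @export
setGeneric("forwardSelection",
           function(study, alphaLevel = 0.05, B = 1000L, seed = 1L, ...)
  standardGeneric("forwardSelection"))

#' @export
setGeneric("writeStudy", function(study, phasePath, metadataPath, ...)
  standardGeneric("writeStudy"))

#' @export
setGeneric("orderReport", function(object, ...) standardGeneric("orderReport"))
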