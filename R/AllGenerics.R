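#' @include AllClasses.R
NULL

#' @export
setGeneric("genes", function(x, ...) standardGeneric("genes"))

#' @export
setGeneric("samples", function(x, ...) standardGeneric("samples"))

#' @export
setGeneric("alterationCalls",
           function(x) standardGeneric("alterationCalls"))

#' @export
setGeneric("phenotypeWeights",
           function(x) standardGeneric("phenotypeWeights"))

#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @export
setGeneric("increasedGenes", function(x) standardGeneric("increasedGenes"))

#' @export
setGeneric("decreasedGenes", function(x) standardGeneric("decreasedGenes"))

#' @export
setGeneric("moduleGenes", function(x) standardGeneric("moduleGenes"))

#' @export
setGeneric("moduleSize", function(x) standardGeneric("moduleSize"))

#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @export
setGeneric("solverStatus", function(x) standardGeneric("solverStatus"))

#' @export
setGeneric("solutionModule", function(x) standardGeneric("solutionModule"))

#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @export
setGeneric("plantedModule", function(x) standardGeneric("plantedModule"))
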