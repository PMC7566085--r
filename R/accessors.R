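#' @include AllGenerics.R
NULL

## AlterationMatrix ----------------------------------------------------------

#' @describeIn AlterationMatrix-class gene identifiers (row order).
#' @param x object.
#' @export
setMethod("genes", "AlterationMatrix", function(x, ...) {
  rn <- rownames(x@calls)
  if (is.null(rn)) character(0) else rn
})

#' @describeIn AlterationMatrix-class sample identifiers (column order).
#' @export
setMethod("samples", "AlterationMatrix", function(x, ...) colnames(x@calls))

#' @describeIn AlterationMatrix-class the underlying 0/1 integer matrix.
#' @export
setMethod("alterationCalls", "AlterationMatrix", function(x) x@calls)

setMethod("show", "AlterationMatrix", function(object) {
  m <- object@calls
  cat(sprintf("AlterationMatrix: %d genes x %d samples (%.1f%% altered)\n",
              nrow(m), ncol(m), 100 * mean(m)))
})

#' Dimensions of an AlterationMatrix
#' @param x an \linkS4class{AlterationMatrix}.
#' @export
setMethod("dim", "AlterationMatrix", function(x) dim(x@calls))

## PhenotypeProfile ----------------------------------------------------------

#' @describeIn PhenotypeProfile-class sample identifiers.
#' @param x object.
#' @export
setMethod("samples", "PhenotypeProfile", function(x, ...) names(x@weights))

#' @describeIn PhenotypeProfile-class named numeric weights.
#' @export
setMethod("phenotypeWeights", "PhenotypeProfile", function(x) x@weights)

#' @describeIn PhenotypeProfile-class whether weights are z-scored.
#' @export
setMethod("isNormalized", "PhenotypeProfile", function(x) x@normalized)

setMethod("show", "PhenotypeProfile", function(object) {
  w <- object@weights
  cat(sprintf("PhenotypeProfile: %d samples, range [%.3g, %.3g]%s\n",
              length(w), min(w), max(w),
              if (object@normalized) ", z-scored" else ""))
})

## GeneNetwork ---------------------------------------------------------------

#' @describeIn GeneNetwork-class gene (vertex) names.
#' @param x object.
#' @export
setMethod("genes", "GeneNetwork", function(x, ...) igraph::V(x@graph)$name)

#' @describeIn GeneNetwork-class the underlying igraph object.
#' @export
setMethod("networkGraph", "GeneNetwork", function(x) x@graph)

setMethod("show", "GeneNetwork", function(object) {
  g <- object@graph
  cat(sprintf("GeneNetwork: %d genes, %d edges\n",
              igraph::vcount(g), igraph::ecount(g)))
})

## TwoSidedModule ------------------------------------------------------------

#' @describeIn TwoSidedModule-class increased-sensitivity genes.
#' @param x object.
#' @export
setMethod("increasedGenes", "TwoSidedModule", function(x) x@increased)

#' @describeIn TwoSidedModule-class decreased-sensitivity genes.
#' @export
setMethod("decreasedGenes", "TwoSidedModule", function(x) x@decreased)

#' @describeIn TwoSidedModule-class union of both sides.
#' @export
setMethod("moduleGenes", "TwoSidedModule",
          function(x) sort(c(x@increased, x@decreased)))

#' @describeIn TwoSidedModule-class total number of genes.
#' @export
setMethod("moduleSize", "TwoSidedModule",
          function(x) length(x@increased) + length(x@decreased))

setMethod("show", "TwoSidedModule", function(object) {
  fmt <- function(g) if (length(g)) paste(g, collapse = ", ") else "-"
  cat("TwoSidedModule\n")
  cat("  increased:", fmt(object@increased), "\n")
  cat("  decreased:", fmt(object@decreased), "\n")
})

## ModuleSolution ------------------------------------------------------------

#' @describeIn ModuleSolution-class the selected module.
#' @param x object.
#' @export
setMethod("solutionModule", "ModuleSolution", function(x) x@module)

#' @describeIn ModuleSolution-class the objective value.
#' @export
setMethod("objectiveValue", "ModuleSolution", function(x) x@objective)

#' @describeIn ModuleSolution-class solver status string.
#' @export
setMethod("solverStatus", "ModuleSolution", function(x) x@status)

#' @describeIn ModuleSolution-class union of module genes.
#' @export
setMethod("moduleGenes", "ModuleSolution",
          function(x) moduleGenes(x@module))

setMethod("show", "ModuleSolution", function(object) {
  cat(sprintf(
    "ModuleSolution [%s]: k=%d %s, objective %.4f (%.2fs)\n",
    object@status, object@config@k, object@config@model,
    object@objective, object@solveSeconds))
  fmt <- function(g) if (length(g)) paste(g, collapse = ", ") else "-"
  cat("  increased:", fmt(object@module@increased), "\n")
  cat("  decreased:", fmt(object@module@decreased), "\n")
})

## SignificanceResult --------------------------------------------------------

#' @describeIn SignificanceResult-class permutation p-value.
#' @param x object.
#' @export
setMethod("pValue", "SignificanceResult", function(x) x@pValue)

#' @describeIn SignificanceResult-class the assessed candidate solution.
#' @export
setMethod("solutionModule", "SignificanceResult",
          function(x) x@candidate@module)

setMethod("show", "SignificanceResult", function(object) {
  cat(sprintf(
    "SignificanceResult: p = %.4g (%d permutations, observed %.4f)\n",
    object@pValue, object@nPermutations, object@candidate@objective))
})

## SimulatedInstance ---------------------------------------------------------

#' @describeIn SimulatedInstance-class the planted ground-truth module.
#' @param x object.
#' @export
setMethod("plantedModule", "SimulatedInstance", function(x) x@planted)

setMethod("show", "SimulatedInstance", function(object) {
  cat("SimulatedInstance\n  ")
  show(object@alterations)
  cat("  ")
  show(object@network)
  cat(sprintf("  planted: %d genes (%s)\n",
              moduleSize(object@planted),
              paste(moduleGenes(object@planted), collapse = ", ")))
})

## CandidateSet --------------------------------------------------------------

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet: %d candidates\n", length(object@candidates)))
  if (nrow(object@grid)) print(object@grid, row.names = FALSE)
})

#' @describeIn CandidateSet-class number of candidates.
#' @param x object.
#' @export
setMethod("length", "CandidateSet", function(x) length(x@candidates))
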