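#' @import methods
#' @importFrom stats sd
NULL

setOldClass("igraph")

## ---------------------------------------------------------------------------
## PenaltyScheme
## ---------------------------------------------------------------------------

#' Penalty scheme for overlapping alterations
#'
#' Describes the per-sample penalty \eqn{pt(p)} applied to overlapping
#' (non mutually exclusive) alterations in a covered sample.  With mode
#' \code{"none"} the objective reduces to the plain coverage objective;
#' \code{"abs_weight"} sets \eqn{pt(p) = \lambda |w(p)|} so the penalty is
#' commensurate with the reward of covering sample \eqn{p}; \code{"constant"}
#' sets \eqn{pt(p) = \lambda}.
#'
#' @slot mode one of \code{"none"}, \code{"abs_weight"}, \code{"constant"}.
#' @slot lambda nonnegative scale factor.
#' @export
setClass("PenaltyScheme",
  representation(mode = "character", lambda = "numeric"),
  prototype(mode = "abs_weight", lambda = 1)
)

setValidity("PenaltyScheme", function(object) {
  msg <- NULL
  if (length(object@mode) != 1L ||
      !object@mode %in% c("none", "abs_weight", "constant"))
    msg <- c(msg, "mode must be one of 'none', 'abs_weight', 'constant'")
  if (length(object@lambda) != 1L || is.na(object@lambda) ||
      object@lambda < 0)
    msg <- c(msg, "lambda must be a single nonnegative number")
  if (is.null(msg)) TRUE else msg
})

#' @param mode penalty mode.
#' @param lambda nonnegative scale factor.
#' @rdname PenaltyScheme-class
#' @export
PenaltyScheme <- function(mode = c("abs_weight", "none", "constant"),
                          lambda = 1) {
  mode <- match.arg(mode)
  new("PenaltyScheme", mode = mode, lambda = as.numeric(lambda))
}

## ---------------------------------------------------------------------------
## AlterationMatrix
## ---------------------------------------------------------------------------

#' Binary gene-by-sample alteration matrix
#'
#' Stores the binary incidence \eqn{A(g, p) = 1} when gene \eqn{g} carries a
#' somatic alteration (mutation, amplification, deletion) in sample \eqn{p}.
#' Rows are genes, columns are samples; entries are strictly 0/1 with no
#' missing values (missing data are rejected at load time, never imputed).
#'
#' @slot calls integer matrix of 0/1 with gene rownames and sample colnames.
#' @export
setClass("AlterationMatrix", representation(calls = "matrix"))

setValidity("AlterationMatrix", function(object) {
  m <- object@calls
  msg <- NULL
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    return("calls must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(m)))
    msg <- c(msg, "duplicate gene identifiers")
  if (anyDuplicated(colnames(m)))
    msg <- c(msg, "duplicate sample identifiers")
  if (anyNA(m))
    msg <- c(msg, "missing entries are not allowed")
  else if (!all(m %in% c(0L, 1L)))
    msg <- c(msg, "entries must be 0 or 1")
  if (is.null(msg)) TRUE else msg
})

#' @param calls a 0/1 matrix with gene rownames and sample colnames.
#' @rdname AlterationMatrix-class
#' @export
AlterationMatrix <- function(calls) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  ## empty subsets lose their dimnames; restore the degenerate form
  if (nrow(calls) == 0L && is.null(rownames(calls)))
    rownames(calls) <- character(0)
  if (ncol(calls) == 0L && is.null(colnames(calls)))
    colnames(calls) <- character(0)
  new("AlterationMatrix", calls = calls)
}

## ---------------------------------------------------------------------------
## PhenotypeProfile
## ---------------------------------------------------------------------------

#' Continuous per-sample phenotype
#'
#' One real-valued weight per sample, e.g. a z-scored drug response where, by
#' package convention, larger values mean greater drug sensitivity.  The
#' \code{normalized} flag records whether the weights have been centered to
#' mean 0 and scaled to population standard deviation 1 (see
#' \code{\link{normalizePhenotype}}).
#'
#' @slot weights named numeric vector, one value per sample.
#' @slot normalized logical flag.
#' @export
setClass("PhenotypeProfile",
  representation(weights = "numeric", normalized = "logical"),
  prototype(normalized = FALSE)
)

setValidity("PhenotypeProfile", function(object) {
  w <- object@weights
  msg <- NULL
  if (is.null(names(w)) || any(!nzchar(names(w))))
    return("weights must be named by sample identifier")
  if (anyDuplicated(names(w)))
    msg <- c(msg, "duplicate sample identifiers")
  if (anyNA(w))
    msg <- c(msg, "missing phenotype values are not allowed (drop at load)")
  if (length(object@normalized) != 1L || is.na(object@normalized))
    msg <- c(msg, "normalized must be TRUE or FALSE")
  else if (object@normalized && length(w) > 1L && !anyNA(w)) {
    n <- length(w)
    if (abs(mean(w)) > 1e-9)
      msg <- c(msg, "normalized profile must have mean 0")
    if (abs(sqrt(sum((w - mean(w))^2) / n) - 1) > 1e-9)
      msg <- c(msg, "normalized profile must have population sd 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' @param weights named numeric vector of per-sample values.
#' @param normalized whether the values are already z-scored.
#' @rdname PhenotypeProfile-class
#' @export
PhenotypeProfile <- function(weights, normalized = FALSE) {
  new("PhenotypeProfile", weights = weights, normalized = normalized)
}

## ---------------------------------------------------------------------------
## GeneNetwork
## ---------------------------------------------------------------------------

#' Undirected gene interaction network
#'
#' A simple undirected graph over gene symbols with an edge confidence score
#' in [0, 1] (STRING-style).  Self-loops and duplicate edges are removed at
#' construction; connectivity constraints and target distances use unweighted
#' hops, scores are used only for thresholding at load time.
#'
#' @slot graph an undirected simple \pkg{igraph} object with vertex attribute
#'   \code{name} and edge attribute \code{score}.
#' @export
setClass("GeneNetwork", representation(graph = "igraph"))

setValidity("GeneNetwork", function(object) {
  g <- object@graph
  msg <- NULL
  if (igraph::is_directed(g))
    msg <- c(msg, "network must be undirected")
  if (is.null(igraph::V(g)$name) || anyDuplicated(igraph::V(g)$name))
    msg <- c(msg, "vertices must carry unique gene names")
  if (igraph::any_loop(g) || igraph::any_multiple(g))
    msg <- c(msg, "self-loops and duplicate edges are not allowed")
  sc <- igraph::E(g)$score
  if (igraph::ecount(g) > 0) {
    if (is.null(sc))
      msg <- c(msg, "edges must carry a 'score' attribute")
    else if (anyNA(sc) || any(sc < 0 | sc > 1))
      msg <- c(msg, "edge scores must lie in [0, 1]")
  }
  if (is.null(msg)) TRUE else msg
})

#' @param edges a data.frame with columns \code{gene1}, \code{gene2},
#'   \code{score}, or an igraph object.
#' @param nodes optional character vector of additional (isolated) nodes.
#' @rdname GeneNetwork-class
#' @export
GeneNetwork <- function(edges, nodes = NULL) {
  if (inherits(edges, "igraph")) {
    g <- edges
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
    if (is.null(igraph::E(g)$score)) igraph::E(g)$score <- 1
    g <- igraph::simplify(g, edge.attr.comb = list(score = "max"))
  } else {
    edges <- as.data.frame(edges)
    if (ncol(edges) == 2L) edges$score <- 1
    names(edges)[1:3] <- c("gene1", "gene2", "score")
    verts <- unique(c(edges$gene1, edges$gene2, nodes))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = verts)
    g <- igraph::simplify(g, edge.attr.comb = list(score = "max"))
  }
  new("GeneNetwork", graph = g)
}

## ---------------------------------------------------------------------------
## TwoSidedModule
## ---------------------------------------------------------------------------

#' A two-sided gene module
#'
#' The unit of output: a set of genes whose alterations associate with
#' increased phenotype values (e.g. drug-sensitive) and a disjoint set whose
#' alterations associate with decreased values (e.g. drug-resistant).
#' Either side may be empty.
#'
#' @slot increased character vector of increased-sensitivity genes.
#' @slot decreased character vector of decreased-sensitivity genes.
#' @export
setClass("TwoSidedModule",
  representation(increased = "character", decreased = "character"),
  prototype(increased = character(), decreased = character())
)

setValidity("TwoSidedModule", function(object) {
  msg <- NULL
  if (anyDuplicated(object@increased) || anyDuplicated(object@decreased))
    msg <- c(msg, "gene sets must not contain duplicates")
  if (length(intersect(object@increased, object@decreased)) > 0)
    msg <- c(msg, "increased and decreased gene sets must be disjoint")
  if (is.null(msg)) TRUE else msg
})

#' @param increased genes associated with increased sensitivity.
#' @param decreased genes associated with decreased sensitivity.
#' @rdname TwoSidedModule-class
#' @export
TwoSidedModule <- function(increased = character(), decreased = character()) {
  new("TwoSidedModule",
      increased = sort(unique(as.character(increased))),
      decreased = sort(unique(as.character(decreased))))
}

## ---------------------------------------------------------------------------
## SolverConfig / ModuleSolution
## ---------------------------------------------------------------------------

#' Configuration of one exact module search
#'
#' @slot k maximum total number of genes across both sides (the module size
#'   parameter searched; with \code{exactSize} the total must equal k).
#' @slot model \code{"combined"} (all selected genes induce one connected
#'   subgraph) or \code{"separate"} (each nonempty side is connected on its
#'   own).
#' @slot penalty a \linkS4class{PenaltyScheme}.
#' @slot timeLimit wall-clock cap in seconds; when reached the incumbent is
#'   returned with status \code{"feasible_time_limited"}.
#' @slot gap relative early-stop tolerance in [0, 1); 0 proves the exact
#'   optimum.
#' @slot exactSize require exactly k genes instead of at most k.
#' @slot sides which association directions may be selected:
#'   \code{"both"} (default), \code{"increased"} or \code{"decreased"} —
#'   single-direction searches mirror benchmark settings where alterations
#'   are associated with one response direction only.
#' @export
setClass("SolverConfig",
  representation(k = "integer", model = "character",
                 penalty = "PenaltyScheme", timeLimit = "numeric",
                 gap = "numeric", exactSize = "logical",
                 sides = "character"),
  prototype(sides = "both"))

setValidity("SolverConfig", function(object) {
  msg <- NULL
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    msg <- c(msg, "k must be a single integer >= 1")
  if (length(object@model) != 1L ||
      !object@model %in% c("combined", "separate"))
    msg <- c(msg, "model must be 'combined' or 'separate'")
  if (length(object@timeLimit) != 1L || object@timeLimit <= 0)
    msg <- c(msg, "timeLimit must be > 0")
  if (length(object@gap) != 1L || object@gap < 0 || object@gap >= 1)
    msg <- c(msg, "gap must lie in [0, 1)")
  if (length(object@sides) != 1L ||
      !object@sides %in% c("both", "increased", "decreased"))
    msg <- c(msg, "sides must be 'both', 'increased' or 'decreased'")
  if (is.null(msg)) TRUE else msg
})

#' @param k maximum total module size.
#' @param model connectivity model.
#' @param penalty a \linkS4class{PenaltyScheme}.
#' @param timeLimit seconds before returning the incumbent.
#' @param gap relative early-stop tolerance.
#' @param exactSize force total size exactly k.
#' @param sides association directions allowed in the solution.
#' @rdname SolverConfig-class
#' @export
SolverConfig <- function(k, model = c("combined", "separate"),
                         penalty = PenaltyScheme(), timeLimit = 600,
                         gap = 0, exactSize = FALSE,
                         sides = c("both", "increased", "decreased")) {
  model <- match.arg(model)
  sides <- match.arg(sides)
  new("SolverConfig", k = as.integer(k), model = model, penalty = penalty,
      timeLimit = as.numeric(timeLimit), gap = as.numeric(gap),
      exactSize = isTRUE(exactSize), sides = sides)
}

#' Result of one module search
#'
#' @slot module the selected \linkS4class{TwoSidedModule}.
#' @slot objective its objective value (recomputed post-solve and checked
#'   against the search's own value to 1e-6).
#' @slot config the \linkS4class{SolverConfig} used.
#' @slot status \code{"optimal"}, \code{"feasible_time_limited"} or
#'   \code{"infeasible"}.
#' @slot solveSeconds wall-clock time of the search.
#' @export
setClass("ModuleSolution",
  representation(module = "TwoSidedModule", objective = "numeric",
                 config = "SolverConfig", status = "character",
                 solveSeconds = "numeric"))

setValidity("ModuleSolution", function(object) {
  msg <- NULL
  if (!object@status %in% c("optimal", "feasible_time_limited", "infeasible"))
    msg <- c(msg, "invalid status")
  sz <- length(object@module@increased) + length(object@module@decreased)
  if (object@status != "infeasible" && sz > object@config@k)
    msg <- c(msg, "module exceeds the size bound k")
  if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## CandidateSet / SignificanceResult
## ---------------------------------------------------------------------------

#' Candidate modules over a parameter grid
#'
#' One \linkS4class{ModuleSolution} per grid point of
#' (k = 1..kMax) x connectivity model x penalty scheme.
#'
#' @slot candidates list of \linkS4class{ModuleSolution}.
#' @slot grid data.frame describing each grid point (k, model, penalty mode,
#'   lambda, status, objective).
#' @export
setClass("CandidateSet",
  representation(candidates = "list", grid = "data.frame"))

#' Permutation-test result for one candidate module
#'
#' @slot candidate the assessed \linkS4class{ModuleSolution}.
#' @slot nullObjectives optimal objectives under phenotype permutations.
#' @slot pValue add-one estimator
#'   \eqn{(1 + \#\{null \ge observed\}) / (1 + n)}, never zero.
#' @slot nPermutations number of permutations attempted.
#' @slot nFailed permutation solves that failed (excluded from the estimator).
#' @slot seed RNG seed that fully determines the permutations.
#' @export
setClass("SignificanceResult",
  representation(candidate = "ModuleSolution", nullObjectives = "numeric",
                 pValue = "numeric", nPermutations = "integer",
                 nFailed = "integer", seed = "integer"))

setValidity("SignificanceResult", function(object) {
  msg <- NULL
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "p-value must lie in (0, 1]")
  if (length(object@nullObjectives) + object@nFailed != object@nPermutations)
    msg <- c(msg, "null objectives + failures must equal nPermutations")
  if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## SimulatedInstance
## ---------------------------------------------------------------------------

#' A synthetic benchmark instance with a known planted module
#'
#' @slot alterations the \linkS4class{AlterationMatrix}.
#' @slot phenotype the z-scored \linkS4class{PhenotypeProfile}.
#' @slot network the \linkS4class{GeneNetwork} containing the planted module.
#' @slot planted ground-truth \linkS4class{TwoSidedModule}; its genes induce
#'   a connected subgraph of the network.
#' @slot params the generating parameters (see \code{\link{simulateInstance}}).
#' @export
setClass("SimulatedInstance",
  representation(alterations = "AlterationMatrix",
                 phenotype = "PhenotypeProfile",
                 network = "GeneNetwork",
                 planted = "TwoSidedModule",
                 params = "list"))

setValidity("SimulatedInstance", function(object) {
  pg <- c(object@planted@increased, object@planted@decreased)
  g <- object@network@graph
  msg <- NULL
  if (!all(pg %in% igraph::V(g)$name))
    msg <- c(msg, "planted genes must be network nodes")
  else if (length(pg) > 1L &&
           !igraph::is_connected(igraph::induced_subgraph(g, pg)))
    msg <- c(msg, "planted genes must induce a connected subgraph")
  if (!all(pg %in% rownames(object@alterations@calls)))
    msg <- c(msg, "planted genes must be rows of the alteration matrix")
  if (is.null(msg)) TRUE else msg
})
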