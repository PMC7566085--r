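#' @include accessors.R
NULL

## Reference semantics of the module objective.  Everything the optimizer
## returns is re-scored through these functions; they are deliberately plain
## vectorized R with no shared code with the C++ search.

#' Samples covered by a gene set
#'
#' The coverage \eqn{P(S)} of a gene set \eqn{S}: samples with an alteration
#' in at least one gene of \eqn{S}.
#'
#' @param S character vector of genes (subset of \code{genes(A)}).
#' @param A an \linkS4class{AlterationMatrix}.
#' @return character vector of sample identifiers (in matrix column order).
#' @export
coveredSamples <- function(S, A) {
  stopifnot(is(A, "AlterationMatrix"))
  S <- unique(as.character(S))
  if (length(S) == 0L) return(character())
  missing <- setdiff(S, genes(A))
  if (length(missing))
    stop("unknown gene(s): ", paste(missing, collapse = ", "))
  hit <- colSums(A@calls[S, , drop = FALSE]) > 0
  samples(A)[hit]
}

#' Number of selected genes altered in one sample
#'
#' The overlap count \eqn{c(p, S) = |\{g \in S : A(g, p) = 1\}|}; values
#' above 1 mean the sample violates mutual exclusivity within \eqn{S}.
#'
#' @param p a sample identifier.
#' @param S character vector of genes.
#' @param A an \linkS4class{AlterationMatrix}.
#' @return a nonnegative integer.
#' @export
overlapCount <- function(p, S, A) {
  stopifnot(is(A, "AlterationMatrix"))
  if (!p %in% samples(A)) stop("unknown sample: ", p)
  S <- unique(as.character(S))
  if (length(S) == 0L) return(0L)
  missing <- setdiff(S, genes(A))
  if (length(missing))
    stop("unknown gene(s): ", paste(missing, collapse = ", "))
  sum(A@calls[S, p])
}

## harmonize a weight vector (or profile) with the matrix's sample order;
## an unnamed vector of matching length is taken as already aligned
.alignWeights <- function(w, A) {
  wv <- if (is(w, "PhenotypeProfile")) w@weights else w
  if (is.null(names(wv))) {
    if (length(wv) != length(samples(A)))
      stop("phenotype is not aligned with the alteration matrix")
    names(wv) <- samples(A)
    return(wv)
  }
  if (!identical(names(wv), samples(A)))
    wv <- wv[samples(A)]
  if (anyNA(wv))
    stop("phenotype is not aligned with the alteration matrix")
  wv
}

## penalty pt(p) per sample for a weight vector, under a scheme
.penaltyTerm <- function(w, penalty) {
  switch(penalty@mode,
         none = rep(0, length(w)),
         abs_weight = penalty@lambda * abs(w),
         constant = rep(penalty@lambda, length(w)))
}

#' One-sided module objective
#'
#' The penalized coverage objective for a single direction:
#' \deqn{W(S) = \sum_{p \in P(S)} w(p) - \sum_{p \in P(S)} pt(p)\,(c(p,S)-1)}
#' where \eqn{P(S)} is the coverage, \eqn{c(p,S)} the overlap count and
#' \eqn{pt(p)} the \linkS4class{PenaltyScheme} term.  With penalty mode
#' \code{"none"} this is the plain coverage objective
#' \eqn{\sum_{p \in P(S)} w(p)}.
#'
#' @param S character vector of genes.
#' @param A an \linkS4class{AlterationMatrix}.
#' @param w a \linkS4class{PhenotypeProfile} aligned with \code{A}, or a
#'   named numeric vector of weights.
#' @param penalty a \linkS4class{PenaltyScheme}.
#' @return the objective value (0 for an empty set).
#' @export
oneSidedObjective <- function(S, A, w, penalty = PenaltyScheme("none")) {
  stopifnot(is(A, "AlterationMatrix"))
  wv <- .alignWeights(w, A)
  S <- unique(as.character(S))
  if (length(S) == 0L) return(0)
  missing <- setdiff(S, genes(A))
  if (length(missing))
    stop("unknown gene(s): ", paste(missing, collapse = ", "))
  cnt <- colSums(A@calls[S, , drop = FALSE])
  covered <- cnt > 0
  pt <- .penaltyTerm(wv, penalty)
  sum(wv[covered]) - sum(pt[covered] * (cnt[covered] - 1))
}

#' Two-sided module objective
#'
#' Scores a \linkS4class{TwoSidedModule}: the increased-sensitivity side is
#' scored against the phenotype weights, the decreased-sensitivity side
#' against their negation (its alterations should concentrate in
#' low-phenotype samples), and the two one-sided objectives are added.  A
#' sample covered by both sides contributes to both sums independently; use
#' \code{\link{crossSideOverlap}} to inspect such samples.
#'
#' @param module a \linkS4class{TwoSidedModule} (or a list with elements
#'   \code{increased}, \code{decreased}).
#' @param A an \linkS4class{AlterationMatrix}.
#' @param w a \linkS4class{PhenotypeProfile} aligned with \code{A}.
#' @param penalty a \linkS4class{PenaltyScheme}; the abs-weight penalty uses
#'   \eqn{|w(p)|}, identical on both sides.
#' @return the total objective value.
#' @export
moduleObjective <- function(module, A, w,
                            penalty = PenaltyScheme("none")) {
  if (is.list(module))
    module <- TwoSidedModule(module$increased, module$decreased)
  stopifnot(is(module, "TwoSidedModule"))
  validObject(module)
  wv <- .alignWeights(w, A)
  oneSidedObjective(module@increased, A, wv, penalty) +
    oneSidedObjective(module@decreased, A, -wv, penalty)
}

#' Samples covered by both sides of a module
#'
#' Diagnostic for cross-side overlap: samples altered in at least one
#' increased-side gene and at least one decreased-side gene.  Such samples
#' are not penalized by the objective but are excluded from the three-group
#' ANOVA (see \code{\link{assignGroups}}).
#'
#' @param module a \linkS4class{TwoSidedModule}.
#' @param A an \linkS4class{AlterationMatrix}.
#' @return character vector of sample identifiers.
#' @export
crossSideOverlap <- function(module, A) {
  intersect(coveredSamples(module@increased, A),
            coveredSamples(module@decreased, A))
}
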