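#' @include simulate.R
NULL

#' Network distance from a module to a drug's targets
#'
#' For each module gene, the minimum unweighted shortest-path length to any
#' target gene (0 when the gene is itself a target); means are reported per
#' side and over all module genes.  Module genes or targets missing from the
#' network are dropped with a warning; genes unreachable from every target
#' are excluded from the means and counted separately.  Edge confidence
#' scores play no role here beyond having thresholded the network at load.
#'
#' @param module a \linkS4class{TwoSidedModule}.
#' @param targets character vector of target genes for the drug.
#' @param network a \linkS4class{GeneNetwork}.
#' @return list with \code{perGene} (named vector), \code{meanIncreased},
#'   \code{meanDecreased}, \code{meanOverall} (NA with a warning when no gene
#'   is reachable), and \code{nUnreachable}.
#' @export
moduleTargetDistance <- function(module, targets, network) {
  stopifnot(is(module, "TwoSidedModule"))
  g <- networkGraph(network)
  known <- igraph::V(g)$name
  targets <- unique(as.character(targets))
  dropT <- setdiff(targets, known)
  if (length(dropT)) {
    warning("target(s) not in network dropped: ",
            paste(dropT, collapse = ", "))
    targets <- intersect(targets, known)
  }
  if (length(targets) == 0L) stop("no usable target genes")
  mg <- moduleGenes(module)
  dropM <- setdiff(mg, known)
  if (length(dropM)) {
    warning("module gene(s) not in network dropped: ",
            paste(dropM, collapse = ", "))
    mg <- intersect(mg, known)
  }
  if (length(mg) == 0L) stop("no usable module genes")
  d <- igraph::distances(g, v = mg, to = targets, weights = NA)
  perGene <- apply(d, 1L, min)
  reachable <- is.finite(perGene)
  if (!any(reachable))
    warning("no module gene is reachable from any target")
  sideMean <- function(side) {
    v <- perGene[intersect(side, mg)]
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  }
  list(perGene = perGene,
       meanIncreased = sideMean(module@increased),
       meanDecreased = sideMean(module@decreased),
       meanOverall = if (any(reachable)) mean(perGene[reachable])
                     else NA_real_,
       nUnreachable = sum(!reachable))
}

#' Group samples by their alteration status in a module
#'
#' The three-group validation design: samples altered in decreased-side
#' genes only, in increased-side genes only, or in no module gene.  Samples
#' altered on both sides do not fit any of the three groups and are put in a
#' fourth \code{"excluded"} bucket, dropped from the ANOVA by default.  The
#' four labels partition the samples.
#'
#' @param module a \linkS4class{TwoSidedModule}.
#' @param A an \linkS4class{AlterationMatrix}.
#' @return factor of labels (\code{decreased_only}, \code{increased_only},
#'   \code{unaltered}, \code{excluded}) named by sample.
#' @export
assignGroups <- function(module, A) {
  stopifnot(is(module, "TwoSidedModule"), is(A, "AlterationMatrix"))
  validObject(module)
  inc <- coveredSamples(module@increased, A)
  dec <- coveredSamples(module@decreased, A)
  lab <- rep("unaltered", length(samples(A)))
  names(lab) <- samples(A)
  lab[setdiff(inc, dec)] <- "increased_only"
  lab[setdiff(dec, inc)] <- "decreased_only"
  lab[intersect(inc, dec)] <- "excluded"
  factor(lab, levels = c("decreased_only", "increased_only", "unaltered",
                         "excluded"))
}

#' One-way ANOVA across the three alteration groups
#'
#' Fixed-effects one-way ANOVA of a response (e.g. an independent drug
#' sensitivity profile) across the \code{decreased_only},
#' \code{increased_only} and \code{unaltered} groups of
#' \code{\link{assignGroups}}; \code{excluded} samples are dropped.  Groups
#' need at least 2 nonempty levels with >= 2 samples each; otherwise a
#' not-testable sentinel (\code{NA} statistics with a \code{reason}) is
#' returned rather than an error.
#'
#' @param groups factor from \code{\link{assignGroups}} (or any grouping
#'   factor), named by sample.
#' @param response named numeric response; matched to \code{groups} by name.
#' @param dropExcluded drop the \code{excluded} bucket (default) or test it
#'   as a fourth group.
#' @return list with \code{F}, \code{p}, \code{df}, \code{groupMeans},
#'   \code{testable}, \code{reason}.
#' @export
anovaThreeGroup <- function(groups, response, dropExcluded = TRUE) {
  common <- intersect(names(groups), names(response))
  g <- groups[common]
  y <- response[common]
  if (dropExcluded) {
    keep <- g != "excluded"
    g <- g[keep]
    y <- y[keep]
  }
  g <- droplevels(factor(g))
  sizes <- table(g)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    return(list(F = NA_real_, p = NA_real_, df = c(NA_real_, NA_real_),
                groupMeans = tapply(y, g, mean), testable = FALSE,
                reason = "need >= 2 groups with >= 2 samples each"))
  }
  fit <- stats::lm(y ~ g)
  av <- stats::anova(fit)
  list(F = av[["F value"]][1L], p = av[["Pr(>F)"]][1L],
       df = c(av[["Df"]][1L], av[["Df"]][2L]),
       groupMeans = tapply(y, g, mean), testable = TRUE, reason = "")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted values (monotone enforced), delegated to
#' \code{\link[stats]{p.adjust}}.  Input p-values outside [0, 1] are an
#' error.
#'
#' @param p numeric vector of p-values.
#' @return adjusted q-values in the input order.
#' @export
benjaminiHochberg <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Suggest drug pairs with opposite-direction shared modules
#'
#' Screens the final modules of multiple drugs for combination-therapy
#' candidates: a pair of drugs is reported when at least \code{minShared}
#' genes appear in both drugs' modules with opposite side labels (a gene
#' driving sensitivity to one drug and resistance to the other).  The
#' witnessing genes are listed; output is symmetric in the pair and ordered
#' deterministically by drug name.
#'
#' @param modulesByDrug named list (one element per drug) of lists of
#'   \linkS4class{ModuleSolution} or \linkS4class{TwoSidedModule}.
#' @param minShared minimum number of opposite-direction witness genes.
#' @param minJaccard optional additional requirement on the Jaccard overlap
#'   of the two drugs' gene unions (0 disables it).
#' @return data.frame with columns \code{drug1}, \code{drug2},
#'   \code{witnesses}, \code{nShared}, \code{jaccard}.
#' @export
suggestDrugPairs <- function(modulesByDrug, minShared = 1, minJaccard = 0) {
  stopifnot(length(modulesByDrug) >= 2, !is.null(names(modulesByDrug)))
  sideMap <- lapply(modulesByDrug, function(mods) {
    inc <- unique(unlist(lapply(mods, function(m) {
      if (is(m, "ModuleSolution")) m <- m@module
      m@increased
    })))
    dec <- unique(unlist(lapply(mods, function(m) {
      if (is(m, "ModuleSolution")) m <- m@module
      m@decreased
    })))
    list(inc = inc %||% character(), dec = dec %||% character())
  })
  drugs <- sort(names(modulesByDrug))
  out <- list()
  for (i in seq_along(drugs)) {
    for (j in seq_along(drugs)) {
      if (j <= i) next
      a <- sideMap[[drugs[i]]]
      b <- sideMap[[drugs[j]]]
      witness <- sort(union(intersect(a$inc, b$dec),
                            intersect(a$dec, b$inc)))
      ua <- union(a$inc, a$dec)
      ub <- union(b$inc, b$dec)
      jac <- if (length(union(ua, ub)) == 0) 0 else
        length(intersect(ua, ub)) / length(union(ua, ub))
      if (length(witness) >= minShared && jac >= minJaccard &&
          length(witness) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          drug1 = drugs[i], drug2 = drugs[j],
          witnesses = paste(witness, collapse = ","),
          nShared = length(witness), jaccard = jac)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(drug1 = character(), drug2 = character(),
                      witnesses = character(), nShared = integer(),
                      jaccard = numeric()))
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
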