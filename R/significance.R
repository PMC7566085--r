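#' @include solver.R
NULL

#' Generate candidate modules over a parameter grid
#'
#' Solves one exact module search per grid point
#' (k = 1..\code{kMax}) x connectivity model x penalty scheme and collects
#' the per-point optima as candidates.  A solver error at one grid point is
#' recorded for that point and does not abort the rest of the grid.
#'
#' @param A an \linkS4class{AlterationMatrix}.
#' @param w an aligned \linkS4class{PhenotypeProfile}.
#' @param network a \linkS4class{GeneNetwork}.
#' @param kMax largest module size searched.
#' @param models connectivity models to include.
#' @param penalties list of \linkS4class{PenaltyScheme}s.
#' @param timeLimit,gap passed to each \linkS4class{SolverConfig}.
#' @return a \linkS4class{CandidateSet}.
#' @export
generateCandidates <- function(A, w, network, kMax,
                               models = c("combined", "separate"),
                               penalties = list(PenaltyScheme()),
                               timeLimit = 600, gap = 0) {
  stopifnot(kMax >= 1)
  models <- match.arg(models, c("combined", "separate"), several.ok = TRUE)
  if (is(penalties, "PenaltyScheme")) penalties <- list(penalties)
  cands <- list()
  rows <- list()
  for (model in models) {
    for (pi in seq_along(penalties)) {
      pen <- penalties[[pi]]
      for (k in seq_len(kMax)) {
        cfg <- SolverConfig(k = k, model = model, penalty = pen,
                            timeLimit = timeLimit, gap = gap)
        sol <- tryCatch(solveModule(A, w, network, cfg),
                        error = function(e) e)
        if (inherits(sol, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            k = k, model = model, penalty = pen@mode, lambda = pen@lambda,
            status = "error", objective = NA_real_,
            message = conditionMessage(sol))
          next
        }
        cands[[length(cands) + 1L]] <- sol
        rows[[length(rows) + 1L]] <- data.frame(
          k = k, model = model, penalty = pen@mode, lambda = pen@lambda,
          status = sol@status, objective = sol@objective, message = "")
      }
    }
  }
  new("CandidateSet", candidates = cands,
      grid = do.call(rbind, rows))
}

#' Permutation test for one candidate's association
#'
#' Assesses whether the optimal objective at a grid point could arise from a
#' phenotype unrelated to the alterations: the phenotype values are randomly
#' permuted across samples (the alteration matrix stays fixed), the same
#' optimization is re-solved per permutation, and the add-one empirical
#' p-value \eqn{(1 + \#\{W_{null} \ge W_{obs}\}) / (1 + n)} is reported —
#' never exactly zero.  The RNG is fully determined by \code{seed}.
#'
#' @param A an \linkS4class{AlterationMatrix}.
#' @param w an aligned \linkS4class{PhenotypeProfile}.
#' @param network a \linkS4class{GeneNetwork}.
#' @param config the grid point's \linkS4class{SolverConfig}.
#' @param nPermutations number of phenotype permutations (>= 1).
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @param observed optionally, the already-solved observed
#'   \linkS4class{ModuleSolution} for this config (re-solved when NULL).
#' @return a \linkS4class{SignificanceResult}.
#' @export
permutationTest <- function(A, w, network, config, nPermutations = 100,
                            seed, observed = NULL) {
  stopifnot(nPermutations >= 1, !missing(seed))
  if (is.null(observed)) observed <- solveModule(A, w, network, config)
  wv <- if (is(w, "PhenotypeProfile")) w@weights else w
  wv <- wv[samples(A)]
  null <- numeric(0)
  nFailed <- 0L
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(as.integer(seed))
  for (i in seq_len(nPermutations)) {
    wp <- PhenotypeProfile(
      structure(sample(unname(wv)), names = names(wv)),
      normalized = FALSE)
    sol <- tryCatch(solveModule(A, wp, network, config),
                    error = function(e) e)
    if (inherits(sol, "error")) {
      nFailed <- nFailed + 1L
    } else {
      null <- c(null, sol@objective)
    }
  }
  if (nFailed > 0L)
    warning(nFailed, " permutation solve(s) failed; p-value computed over ",
            length(null), " successful permutations")
  p <- (1 + sum(null >= observed@objective - 1e-9)) / (1 + length(null))
  new("SignificanceResult", candidate = observed, nullObjectives = null,
      pValue = p, nPermutations = as.integer(nPermutations),
      nFailed = nFailed, seed = as.integer(seed))
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed.restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}

## side-labeled strict containment: x subset of y
.isStrictSubmodule <- function(x, y, respectSides = TRUE) {
  if (respectSides) {
    sub <- all(x@increased %in% y@increased) &&
      all(x@decreased %in% y@decreased)
    same <- setequal(x@increased, y@increased) &&
      setequal(x@decreased, y@decreased)
  } else {
    sub <- all(moduleGenes(x) %in% moduleGenes(y))
    same <- setequal(moduleGenes(x), moduleGenes(y))
  }
  sub && !same
}

#' Select the final maximal significant modules
#'
#' Keeps candidates with permutation p-value below \code{alpha}, then removes
#' redundancy: a significant module strictly contained in another significant
#' module is dropped, so the output is an antichain under (side-labeled) set
#' inclusion.  By default containment respects side labels — a gene counted
#' as increased-sensitivity is not "contained" in a module carrying it on the
#' decreased side; set \code{respectSides = FALSE} to compare plain gene
#' unions.  Candidates whose solve hit the time limit are excluded unless
#' \code{includeTimeLimited}.
#'
#' Output order is deterministic: decreasing objective, then lexicographic
#' gene names.
#'
#' @param results list of \linkS4class{SignificanceResult}.
#' @param alpha significance threshold (default 0.05).
#' @param respectSides compare containment per side label.
#' @param includeTimeLimited keep solutions with status
#'   \code{"feasible_time_limited"}.
#' @return list of \linkS4class{ModuleSolution} (possibly empty).
#' @export
selectFinalModules <- function(results, alpha = 0.05, respectSides = TRUE,
                               includeTimeLimited = FALSE) {
  keep <- Filter(function(r) {
    r@pValue < alpha && moduleSize(r@candidate@module) > 0 &&
      (includeTimeLimited ||
         r@candidate@status != "feasible_time_limited")
  }, results)
  if (length(keep) == 0L) return(list())
  sols <- lapply(keep, function(r) r@candidate)

  ## deterministic order: objective desc, then lexicographic gene key
  key <- vapply(sols, function(s)
    paste(sort(c(paste0("+", s@module@increased),
                 paste0("-", s@module@decreased))), collapse = "|"),
    character(1))
  ord <- order(-vapply(sols, objectiveValue, numeric(1)), key)
  sols <- sols[ord]
  key <- key[ord]

  ## drop exact duplicates (same side-labeled gene sets), keep best objective
  sols <- sols[!duplicated(key)]

  ## maximality: drop strict submodules of any other significant module
  mods <- lapply(sols, solutionModule)
  maximal <- vapply(seq_along(mods), function(i) {
    !any(vapply(seq_along(mods), function(j) {
      i != j && .isStrictSubmodule(mods[[i]], mods[[j]], respectSides)
    }, logical(1)))
  }, logical(1))
  sols[maximal]
}
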