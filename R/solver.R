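#' @include objective.R
NULL

.modelCode <- c(combined = 0L, separate = 1L)
.penCode <- c(none = 0L, abs_weight = 1L, constant = 2L)
.sidesCode <- c(both = 0L, increased = 1L, decreased = 2L)

#' Does a module satisfy a connectivity model?
#'
#' Graph-traversal check of the connectivity contract: under the
#' \code{"combined"} model the union of both sides must induce one connected
#' subgraph of the network; under \code{"separate"} each nonempty side must
#' induce a connected subgraph on its own.  Empty sides (and the empty
#' module) are vacuously connected.
#'
#' @param module a \linkS4class{TwoSidedModule}.
#' @param network a \linkS4class{GeneNetwork}.
#' @param model \code{"combined"} or \code{"separate"}.
#' @return TRUE or FALSE.
#' @export
moduleIsConnected <- function(module, network,
                              model = c("combined", "separate")) {
  model <- match.arg(model)
  g <- networkGraph(network)
  connected <- function(gs) {
    if (length(gs) <= 1L) return(TRUE)
    if (!all(gs %in% igraph::V(g)$name)) return(FALSE)
    igraph::is_connected(igraph::induced_subgraph(g, gs))
  }
  if (model == "combined") {
    connected(moduleGenes(module))
  } else {
    connected(module@increased) && connected(module@decreased)
  }
}

## shared input marshalling for the exact search
.solverInputs <- function(A, w, network) {
  stopifnot(is(A, "AlterationMatrix"), is(network, "GeneNetwork"))
  wv <- if (is(w, "PhenotypeProfile")) w@weights else w
  if (!identical(names(wv), samples(A))) {
    wv <- wv[samples(A)]
    if (anyNA(wv))
      stop("phenotype and alteration matrix sample sets differ; ",
           "run alignSamples() first")
  }
  gs <- genes(A)
  absent <- setdiff(gs, genes(network))
  if (length(absent))
    stop(length(absent), " gene(s) of the alteration matrix are not in the ",
         "network (filterGenes with requireInNetwork drops them): ",
         paste(utils::head(absent, 5), collapse = ", "))
  sub <- igraph::induced_subgraph(networkGraph(network), gs)
  idx <- match(igraph::V(sub)$name, gs)
  adj <- lapply(seq_along(gs), function(i) integer())
  for (i in seq_len(igraph::vcount(sub))) {
    nb <- igraph::neighbors(sub, i)
    adj[[idx[i]]] <- sort(idx[as.integer(nb)]) - 1L
  }
  cov <- lapply(seq_along(gs),
                function(i) which(A@calls[i, ] == 1L) - 1L)
  list(genes = gs, adj = adj, cov = cov, w = unname(wv))
}

#' Exactly solve the connected two-sided module problem
#'
#' Finds the module maximizing \code{\link{moduleObjective}} subject to the
#' connectivity model and size bound of \code{config}, by exact
#' branch-and-bound over connected gene subsets of the network restricted to
#' the genes of \code{A}.  The empty module is always feasible with
#' objective 0, so reported optima are nonnegative.  The returned objective
#' is recomputed through the reference objective functions and must agree
#' with the search's own value to 1e-6; the connectivity contract is
#' re-checked by graph traversal.
#'
#' If the wall-clock limit of \code{config} is hit the incumbent is returned
#' with status \code{"feasible_time_limited"}.
#'
#' @param A an \linkS4class{AlterationMatrix} (all genes must be network
#'   nodes; see \code{\link{filterGenes}}).
#' @param w an aligned \linkS4class{PhenotypeProfile} (larger = more
#'   sensitive).
#' @param network a \linkS4class{GeneNetwork}.
#' @param config a \linkS4class{SolverConfig}.
#' @return a \linkS4class{ModuleSolution}.
#' @examples
#' A <- AlterationMatrix(matrix(c(1, 0, 1, 0, 1, 0, 0, 1), 2, 4,
#'   dimnames = list(c("g1", "g2"), paste0("p", 1:4))))
#' w <- PhenotypeProfile(c(p1 = 3, p2 = 2, p3 = -1, p4 = 1))
#' net <- GeneNetwork(data.frame(gene1 = "g1", gene2 = "g2", score = 0.9))
#' solveModule(A, w, net, SolverConfig(k = 2, penalty = PenaltyScheme("none")))
#' @export
solveModule <- function(A, w, network, config) {
  stopifnot(is(config, "SolverConfig"))
  validObject(config)
  inp <- .solverInputs(A, w, network)
  t0 <- proc.time()[["elapsed"]]
  res <- cpp_solve_module(inp$adj, inp$cov, inp$w,
                          config@k, .modelCode[[config@model]],
                          .penCode[[config@penalty@mode]],
                          config@penalty@lambda,
                          config@timeLimit, config@gap, config@exactSize,
                          .sidesCode[[config@sides]])
  dt <- proc.time()[["elapsed"]] - t0
  if (res$status == "infeasible") {
    return(new("ModuleSolution", module = TwoSidedModule(),
               objective = NA_real_, config = config,
               status = "infeasible", solveSeconds = dt))
  }
  mod <- TwoSidedModule(increased = inp$genes[res$inc + 1L],
                        decreased = inp$genes[res$dec + 1L])
  obj <- moduleObjective(mod, A, inp$w, config@penalty)
  if (abs(obj - res$objective) > 1e-6)
    stop(sprintf(
      "internal inconsistency: search objective %.8f != re-scored %.8f",
      res$objective, obj))
  if (!moduleIsConnected(mod, network, config@model))
    stop("internal error: returned module violates the connectivity model")
  new("ModuleSolution", module = mod, objective = obj, config = config,
      status = res$status, solveSeconds = dt)
}

#' Brute-force verification oracle
#'
#' Independently recomputes the optimum of \code{\link{moduleObjective}}
#' under the connectivity model by exhaustive enumeration: every side-labeled
#' gene set of total size at most \code{config@k} (exactly \code{k} when
#' \code{config@exactSize}) is generated with \code{\link[utils]{combn}},
#' its connectivity checked with \pkg{igraph}, and its objective evaluated
#' through the reference objective functions.  Shares no code with
#' \code{\link{solveModule}}'s search and exists to verify it.
#'
#' Ties are broken deterministically: lexicographically by the sorted gene
#' names of the union, then by the side assignment (decreased-side gene names
#' as the tiebreaker key).
#'
#' @inheritParams solveModule
#' @param maxGenes combinatorial guard; more genes than this is an error.
#' @return a \linkS4class{ModuleSolution} with status \code{"optimal"}.
#' @export
bruteForceBest <- function(A, w, network, config, maxGenes = 15L) {
  stopifnot(is(config, "SolverConfig"))
  gs <- genes(A)
  if (length(gs) > maxGenes)
    stop("brute force is guarded to ", maxGenes, " genes; got ", length(gs))
  wv <- if (is(w, "PhenotypeProfile")) w@weights else w
  g <- networkGraph(network)
  t0 <- proc.time()[["elapsed"]]

  subsets <- list(character())
  for (s in seq_len(config@k))
    subsets <- c(subsets,
                 utils::combn(sort(gs), s, simplify = FALSE))

  conn <- new.env(parent = emptyenv())
  isConn <- function(set) {
    if (length(set) <= 1L) return(TRUE)
    key <- paste(set, collapse = "\r")
    got <- conn[[key]]
    if (is.null(got)) {
      got <- all(set %in% igraph::V(g)$name) &&
        igraph::is_connected(igraph::induced_subgraph(g, set))
      conn[[key]] <- got
    }
    got
  }

  best <- NULL
  bestObj <- -Inf
  bestKey <- NULL
  consider <- function(inc, dec, obj) {
    key <- c(paste(sort(c(inc, dec)), collapse = "|"),
             paste(sort(dec), collapse = "|"))
    if (obj > bestObj + 1e-9 ||
        (abs(obj - bestObj) <= 1e-9 && !is.null(bestKey) &&
         (key[1] < bestKey[1] ||
          (key[1] == bestKey[1] && key[2] < bestKey[2])))) {
      best <<- list(inc = inc, dec = dec)
      bestObj <<- obj
      bestKey <<- key
    }
  }

  for (set in subsets) {
    s <- length(set)
    if (config@exactSize && s != config@k) next
    if (s == 0L) {
      consider(character(), character(), 0)
      next
    }
    if (config@model == "combined" && !isConn(set)) next
    masks <- switch(config@sides,
                    both = 0:(2^s - 1L),
                    increased = 0L,
                    decreased = 2^s - 1L)
    for (mask in masks) {
      dec <- set[bitwAnd(bitwShiftR(mask, seq_len(s) - 1L), 1L) == 1L]
      inc <- setdiff(set, dec)
      if (config@model == "separate" &&
          !(isConn(inc) && isConn(dec))) next
      obj <- oneSidedObjective(inc, A, wv, config@penalty) +
        oneSidedObjective(dec, A, -wv, config@penalty)
      consider(inc, dec, obj)
    }
  }
  dt <- proc.time()[["elapsed"]] - t0
  if (is.null(best))
    return(new("ModuleSolution", module = TwoSidedModule(),
               objective = NA_real_, config = config,
               status = "infeasible", solveSeconds = dt))
  new("ModuleSolution",
      module = TwoSidedModule(best$inc, best$dec),
      objective = bestObj, config = config, status = "optimal",
      solveSeconds = dt)
}
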