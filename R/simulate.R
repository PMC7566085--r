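#' @include significance.R
NULL

#' Parameters for a simulated benchmark instance
#'
#' Defaults describe the package's reference benchmark regime: 150 genes on
#' a scale-free (Barabasi-Albert, m = 2) network, 100 samples, a planted
#' connected module of 4 genes covering 30\% of samples with mutually
#' exclusive alterations on a 5\% background alteration rate, and a phenotype
#' shifted by two noise standard deviations in covered samples.
#'
#' @param nGenes number of genes (network nodes).
#' @param nSamples number of samples.
#' @param networkModel \code{"barabasi_albert"}, \code{"erdos_renyi"} or
#'   \code{"from_file"} (supply \code{network} to
#'   \code{\link{simulateInstance}}).
#' @param baM edges per new node for the Barabasi-Albert model.
#' @param erProb edge probability for the Erdos-Renyi model.
#' @param backgroundRate per-gene per-sample alteration probability outside
#'   the planted module, in (0, 1).
#' @param plantedSize number of planted genes (the benchmark uses 3-5).
#' @param plantedDirection \code{"increased"}, \code{"decreased"} or
#'   \code{"mixed"}.
#' @param coverageTarget fraction of samples altered in >= 1 planted gene.
#' @param exclusivity \code{"exclusive"} (each covered sample altered in
#'   exactly one planted gene) or \code{"overlapping"}.
#' @param effectSize mean phenotype shift of covered samples, in units of
#'   \code{noiseSd}... the raw shift is \code{effectSize * noiseSd} applied
#'   before z-scoring when \code{noiseSd = 1} it is the shift itself.
#' @param noiseSd phenotype noise standard deviation (> 0).
#' @param seed integer RNG seed; mandatory, the instance is fully
#'   seed-determined.
#' @return a named list of validated parameters.
#' @export
simulationParams <- function(nGenes = 150, nSamples = 100,
                             networkModel = c("barabasi_albert",
                                              "erdos_renyi", "from_file"),
                             baM = 2, erProb = 0.04,
                             backgroundRate = 0.05,
                             plantedSize = 4,
                             plantedDirection = c("increased", "decreased",
                                                  "mixed"),
                             coverageTarget = 0.3,
                             exclusivity = c("exclusive", "overlapping"),
                             effectSize = 2, noiseSd = 1, seed) {
  networkModel <- match.arg(networkModel)
  plantedDirection <- match.arg(plantedDirection)
  exclusivity <- match.arg(exclusivity)
  stopifnot(plantedSize >= 1, plantedSize <= nGenes,
            backgroundRate > 0, backgroundRate < 1,
            coverageTarget >= 0, coverageTarget <= 1,
            noiseSd > 0, nSamples >= 2, !missing(seed))
  list(nGenes = as.integer(nGenes), nSamples = as.integer(nSamples),
       networkModel = networkModel, baM = baM, erProb = erProb,
       backgroundRate = backgroundRate, plantedSize = as.integer(plantedSize),
       plantedDirection = plantedDirection, coverageTarget = coverageTarget,
       exclusivity = exclusivity, effectSize = effectSize,
       noiseSd = noiseSd, seed = as.integer(seed))
}

## uniform random connected subgraph by random-walk growth
.growConnected <- function(g, size, maxTries = 100L) {
  n <- igraph::vcount(g)
  for (try in seq_len(maxTries)) {
    cur <- sample.int(n, 1L)
    set <- cur
    while (length(set) < size) {
      nb <- unique(unlist(lapply(set, function(v)
        as.integer(igraph::neighbors(g, v)))))
      nb <- setdiff(nb, set)
      if (length(nb) == 0L) break
      set <- c(set, nb[sample.int(length(nb), 1L)])
    }
    if (length(set) == size) return(set)
  }
  stop("could not find a connected subgraph of size ", size,
       " in ", maxTries, " attempts")
}

#' Simulate an instance with a planted phenotype-associated module
#'
#' Generates a full synthetic input set — network, binary alteration matrix
#' and z-scored phenotype — in which a known connected gene module drives
#' the phenotype:
#' \enumerate{
#'   \item build (or accept) the gene network;
#'   \item plant a uniformly grown random connected subgraph of
#'     \code{plantedSize} genes;
#'   \item alter the planted genes in a \code{coverageTarget} fraction of
#'     samples — under \code{"exclusive"} each covered sample carries exactly
#'     one planted alteration (every planted gene covers at least one
#'     sample); planted gene rows are fully determined by this step;
#'   \item fill all other gene rows with Bernoulli(\code{backgroundRate})
#'     alterations;
#'   \item draw the phenotype Normal(\eqn{\pm}\code{effectSize}, noiseSd) for
#'     covered samples (sign per the planted direction) and
#'     Normal(0, noiseSd) otherwise, then z-score it.
#' }
#' With \code{effectSize = 0} the phenotype is independent of the
#' alterations — the null construction used for calibration tests.
#'
#' @param params a list from \code{\link{simulationParams}}.
#' @param network a \linkS4class{GeneNetwork}, required when
#'   \code{params$networkModel == "from_file"}.
#' @return a \linkS4class{SimulatedInstance}.
#' @export
simulateInstance <- function(params, network = NULL) {
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(params$seed)

  if (params$networkModel == "from_file") {
    if (is.null(network))
      stop("networkModel 'from_file' requires a network")
    g <- networkGraph(network)
    if (igraph::vcount(g) != params$nGenes)
      params$nGenes <- igraph::vcount(g)
  } else {
    g <- switch(params$networkModel,
      barabasi_albert = igraph::sample_pa(params$nGenes, power = 1,
                                          m = params$baM, directed = FALSE),
      erdos_renyi = igraph::sample_gnp(params$nGenes, params$erProb))
    igraph::V(g)$name <- sprintf("g%03d", seq_len(params$nGenes))
    if (igraph::ecount(g) > 0)
      igraph::E(g)$score <- round(stats::runif(igraph::ecount(g), 0.4, 1), 3)
    network <- GeneNetwork(g)
    g <- networkGraph(network)
  }
  geneNames <- igraph::V(g)$name
  sampleNames <- sprintf("s%03d", seq_len(params$nSamples))

  plantedIdx <- .growConnected(g, params$plantedSize)
  planted <- geneNames[plantedIdx]

  nCov <- round(params$coverageTarget * params$nSamples)
  if (params$exclusivity == "exclusive" && nCov < params$plantedSize)
    stop("coverage target yields fewer covered samples than planted genes")
  covered <- sort(sample.int(params$nSamples, nCov))

  A <- matrix(0L, params$nGenes, params$nSamples,
              dimnames = list(geneNames, sampleNames))
  coveringGenes <- vector("list", params$nSamples)
  if (nCov > 0) {
    if (params$exclusivity == "exclusive") {
      ## every covered sample gets exactly one planted gene; every planted
      ## gene gets at least one sample
      assign <- c(sample(planted),
                  sample(planted, nCov - params$plantedSize, replace = TRUE))
      assign <- assign[sample.int(nCov)]
      for (i in seq_len(nCov)) {
        A[assign[i], covered[i]] <- 1L
        coveringGenes[[covered[i]]] <- assign[i]
      }
    } else {
      for (i in seq_len(nCov)) {
        hit <- planted[stats::runif(params$plantedSize) < 0.5]
        if (length(hit) == 0L) hit <- sample(planted, 1L)
        A[hit, covered[i]] <- 1L
        coveringGenes[[covered[i]]] <- hit
      }
    }
  }

  ## background alterations for all rows not fixed by planting
  bg <- setdiff(geneNames, planted)
  if (length(bg) > 0) {
    A[bg, ] <- matrix(
      as.integer(stats::runif(length(bg) * params$nSamples) <
                   params$backgroundRate),
      length(bg), params$nSamples)
  }

  ## side assignment of planted genes
  if (params$plantedDirection == "mixed" && params$plantedSize >= 2) {
    shuffled <- sample(planted)
    nInc <- ceiling(params$plantedSize / 2)
    incSide <- shuffled[seq_len(nInc)]
    decSide <- setdiff(shuffled, incSide)
  } else if (params$plantedDirection == "decreased") {
    incSide <- character()
    decSide <- planted
  } else {
    incSide <- planted
    decSide <- character()
  }

  shift <- numeric(params$nSamples)
  for (p in covered) {
    cg <- coveringGenes[[p]]
    hasInc <- any(cg %in% incSide)
    hasDec <- any(cg %in% decSide)
    shift[p] <- if (hasInc && !hasDec) params$effectSize * params$noiseSd
                else if (hasDec && !hasInc) -params$effectSize * params$noiseSd
                else 0
  }
  raw <- shift + stats::rnorm(params$nSamples, 0, params$noiseSd)
  w <- normalizePhenotype(
    PhenotypeProfile(structure(raw, names = sampleNames)))

  new("SimulatedInstance",
      alterations = AlterationMatrix(A),
      phenotype = w,
      network = network,
      planted = TwoSidedModule(incSide, decSide),
      params = params)
}

#' Precision / recall / F1 of a recovered module against the planted truth
#'
#' By default the comparison is direction-agnostic on the gene-set unions:
#' precision \eqn{|F \cap T| / |F|}, recall \eqn{|F \cap T| / |T|}, F1 their
#' harmonic mean.  An empty recovered set scores (0, 0, 0).  With
#' \code{directionAware}, a gene only counts as recovered when its side label
#' matches the planted side.
#'
#' @param instance a \linkS4class{SimulatedInstance}.
#' @param found a \linkS4class{ModuleSolution} or
#'   \linkS4class{TwoSidedModule}.
#' @param directionAware require matching side labels.
#' @return named list with \code{precision}, \code{recall}, \code{f1}.
#' @export
recoverabilityReport <- function(instance, found, directionAware = FALSE) {
  if (is(found, "ModuleSolution")) found <- found@module
  stopifnot(is(found, "TwoSidedModule"))
  truth <- plantedModule(instance)
  if (directionAware) {
    tp <- length(intersect(found@increased, truth@increased)) +
      length(intersect(found@decreased, truth@decreased))
  } else {
    tp <- length(intersect(moduleGenes(found), moduleGenes(truth)))
  }
  nf <- moduleSize(found)
  nt <- moduleSize(truth)
  precision <- if (nf == 0L) 0 else tp / nf
  recall <- if (nt == 0L) 0 else tp / nt
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Write a simulated instance to disk
#'
#' Writes the three TSV artifacts (alterations, phenotype, network) in the
#' package's input dialects plus a ground-truth JSON sidecar with the planted
#' side-labeled genes and the generating parameters.
#'
#' @param instance a \linkS4class{SimulatedInstance}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the named vector of file paths.
#' @export
writeInstance <- function(instance, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    alterations = file.path(dir, paste0(prefix, "_alterations.tsv")),
    phenotype = file.path(dir, paste0(prefix, "_phenotype.tsv")),
    network = file.path(dir, paste0(prefix, "_network.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.json")))
  writeAlterations(instance@alterations, paths[["alterations"]])
  writePhenotype(instance@phenotype, paths[["phenotype"]])
  writeNetwork(instance@network, paths[["network"]])
  jsonlite::write_json(
    list(planted_increased = instance@planted@increased,
         planted_decreased = instance@planted@decreased,
         params = instance@params),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
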