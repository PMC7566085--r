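#' @include evaluate.R
NULL

#' Run the full module-discovery pipeline
#'
#' End-to-end orchestration for one phenotype (drug): load and align inputs,
#' filter genes, generate candidate modules across the parameter grid,
#' assess each candidate by phenotype permutation, and select the final
#' maximal significant modules.  When \code{outDir} is given, writes the
#' final modules as JSON lines and a TSV summary plus a machine-readable
#' provenance record (configuration, seed, package version, wall time).
#'
#' @param alterations an \linkS4class{AlterationMatrix} or a path to its TSV.
#' @param phenotype a \linkS4class{PhenotypeProfile} or a path to its TSV.
#' @param network a \linkS4class{GeneNetwork} or a path to its edge list.
#' @param kMax largest module size searched (candidates use k = 1..kMax).
#' @param models connectivity models to search.
#' @param penalties list of \linkS4class{PenaltyScheme}s.
#' @param minFreq,maxFreq gene alteration-frequency filter bounds.
#' @param minEdgeScore edge confidence threshold applied when \code{network}
#'   is a path.
#' @param negatePhenotype sign-flip raw phenotype values (IC50-style input).
#' @param nPermutations permutations per candidate.
#' @param alpha significance level for final module selection.
#' @param seed integer seed driving all permutations (mandatory).
#' @param timeLimit per-solve wall-clock cap, seconds.
#' @param outDir optional output directory.
#' @param drug optional drug label carried into the outputs.
#' @return list with \code{final} (list of \linkS4class{ModuleSolution}),
#'   \code{results} (list of \linkS4class{SignificanceResult}),
#'   \code{candidates} (a \linkS4class{CandidateSet}) and \code{files}
#'   (paths written, or NULL).
#' @export
runPipeline <- function(alterations, phenotype, network,
                        kMax = 3,
                        models = c("combined", "separate"),
                        penalties = list(PenaltyScheme()),
                        minFreq = 0.01, maxFreq = 1,
                        minEdgeScore = 0,
                        negatePhenotype = FALSE,
                        nPermutations = 100, alpha = 0.05,
                        seed, timeLimit = 600,
                        outDir = NULL, drug = NA_character_) {
  stopifnot(!missing(seed))
  t0 <- proc.time()[["elapsed"]]
  if (is.character(alterations)) alterations <- readAlterations(alterations)
  if (is.character(phenotype)) phenotype <- readPhenotype(phenotype)
  if (is.character(network)) network <- readNetwork(network, minEdgeScore)

  phenotype <- normalizePhenotype(phenotype, negate = negatePhenotype)
  ali <- alignSamples(alterations, phenotype)
  A <- filterGenes(ali$alterations, network, minFreq = minFreq,
                   maxFreq = maxFreq, requireInNetwork = TRUE)
  w <- ali$phenotype

  cands <- generateCandidates(A, w, network, kMax = kMax, models = models,
                              penalties = penalties, timeLimit = timeLimit)
  results <- vector("list", length(cands@candidates))
  for (i in seq_along(cands@candidates)) {
    sol <- cands@candidates[[i]]
    results[[i]] <- permutationTest(A, w, network, sol@config,
                                    nPermutations = nPermutations,
                                    seed = as.integer(seed) + i,
                                    observed = sol)
  }
  final <- selectFinalModules(results, alpha = alpha)

  files <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- writeModuleOutputs(final, results, outDir, drug = drug,
                                seed = seed)
    prov <- list(
      drug = drug, seed = as.integer(seed), kMax = kMax, models = models,
      penalties = lapply(penalties, function(p)
        list(mode = p@mode, lambda = p@lambda)),
      minFreq = minFreq, maxFreq = maxFreq, minEdgeScore = minEdgeScore,
      nPermutations = nPermutations, alpha = alpha,
      nGenes = length(genes(A)), nSamples = length(samples(A)),
      packageVersion = as.character(utils::packageVersion("phenomod")),
      wallSeconds = proc.time()[["elapsed"]] - t0)
    provPath <- file.path(outDir, "provenance.json")
    jsonlite::write_json(prov, provPath, auto_unbox = TRUE, digits = NA)
    files <- c(files, provenance = provPath)
  }
  list(final = final, results = results, candidates = cands, files = files)
}

#' Write final modules as JSON lines and a TSV summary
#'
#' The JSON-lines file is the canonical artifact (one object per final
#' module); the TSV is a derived human-readable view.
#'
#' @param final list of final \linkS4class{ModuleSolution}.
#' @param results the full list of \linkS4class{SignificanceResult} (used to
#'   look up p-values for the final modules).
#' @param outDir output directory.
#' @param drug optional drug label.
#' @param seed the pipeline seed (recorded per line).
#' @return named vector of file paths.
#' @export
writeModuleOutputs <- function(final, results, outDir,
                               drug = NA_character_, seed = NA_integer_) {
  pLookup <- function(sol) {
    for (r in results) {
      m <- r@candidate@module
      if (setequal(m@increased, sol@module@increased) &&
          setequal(m@decreased, sol@module@decreased) &&
          identical(r@candidate@config@k, sol@config@k) &&
          identical(r@candidate@config@model, sol@config@model))
        return(c(r@pValue, r@nPermutations))
    }
    c(NA_real_, NA_integer_)
  }
  jsonPath <- file.path(outDir, "modules.jsonl")
  tsvPath <- file.path(outDir, "modules.tsv")
  con <- file(jsonPath, "w")
  rows <- list()
  for (sol in final) {
    pn <- pLookup(sol)
    rec <- list(
      drug = drug,
      genes_increased = sol@module@increased,
      genes_decreased = sol@module@decreased,
      objective = sol@objective,
      k = sol@config@k,
      model = sol@config@model,
      penalty = sol@config@penalty@mode,
      lambda = sol@config@penalty@lambda,
      p_value = pn[1],
      n_permutations = pn[2],
      seed = seed)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    rows[[length(rows) + 1L]] <- data.frame(
      drug = drug,
      genes_increased = paste(sol@module@increased, collapse = ","),
      genes_decreased = paste(sol@module@decreased, collapse = ","),
      objective = sol@objective, k = sol@config@k,
      model = sol@config@model, penalty = sol@config@penalty@mode,
      p_value = pn[1])
  }
  close(con)
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(drug = character(), genes_increased = character(),
               genes_decreased = character(), objective = numeric(),
               k = integer(), model = character(), penalty = character(),
               p_value = numeric())
  utils::write.table(tab, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(modules_jsonl = jsonPath, modules_tsv = tsvPath)
}
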