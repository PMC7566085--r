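test_that("the candidate grid has one optimum per grid point", {
  inst <- randomInstance(seed = 1001, nGenes = 8, nSamples = 12)
  one <- generateCandidates(inst$A, inst$w, inst$net, kMax = 1,
                            models = "combined",
                            penalties = list(PenaltyScheme("none")))
  expect_equal(length(one), 1L)
  grid <- generateCandidates(inst$A, inst$w, inst$net, kMax = 3,
                             models = c("combined", "separate"),
                             penalties = list(PenaltyScheme("none")))
  expect_equal(length(grid), 6L)
  expect_equal(nrow(grid@grid), 6L)
  ## objectives non-decreasing in k within each model
  for (m in c("combined", "separate")) {
    objs <- grid@grid$objective[grid@grid$model == m]
    expect_true(all(diff(objs) >= -1e-9))
  }
})

test_that("permutation p-values are reproducible, add-one and never zero", {
  inst <- smallPlanted(seed = 1101, nGenes = 20, nSamples = 40)
  A <- inst@alterations; w <- inst@phenotype; net <- inst@network
  cfg <- SolverConfig(k = 3, model = "combined")
  r1 <- permutationTest(A, w, net, cfg, nPermutations = 19, seed = 5)
  r2 <- permutationTest(A, w, net, cfg, nPermutations = 19, seed = 5)
  expect_identical(r1@nullObjectives, r2@nullObjectives)
  expect_identical(pValue(r1), pValue(r2))
  expect_gt(pValue(r1), 0)
  ## strong planted signal should beat every null: p hits the floor
  expect_equal(pValue(r1), 1 / 20)
  ## estimator definition holds exactly
  expect_equal(pValue(r1),
               (1 + sum(r1@nullObjectives >=
                          objectiveValue(r1@candidate) - 1e-9)) /
                 (1 + length(r1@nullObjectives)))
})

test_that("an all-zero phenotype yields p = 1", {
  inst <- randomInstance(seed = 1201, nGenes = 6, nSamples = 10)
  w0 <- PhenotypeProfile(setNames(rep(0, 10), samples(inst$w)))
  r <- permutationTest(inst$A, w0, inst$net,
                       SolverConfig(k = 2, model = "combined"),
                       nPermutations = 9, seed = 1)
  expect_equal(objectiveValue(r@candidate), 0)
  expect_true(all(r@nullObjectives == 0))
  expect_equal(pValue(r), 1)
})

## build a synthetic SignificanceResult without running the solver
fakeResult <- function(inc, dec, p, objective = 1, k = 4L,
                       model = "combined", status = "optimal") {
  cfg <- SolverConfig(k = k, model = model)
  sol <- new("ModuleSolution", module = TwoSidedModule(inc, dec),
             objective = objective, config = cfg, status = status,
             solveSeconds = 0)
  new("SignificanceResult", candidate = sol, nullObjectives = rep(0, 9),
      pValue = p, nPermutations = 9L, nFailed = 0L, seed = 1L)
}

test_that("final selection keeps maximal significant modules only", {
  rs <- list(
    fakeResult(c("A", "B"), character(), 0.01, objective = 2),
    fakeResult(c("A", "B", "C"), character(), 0.02, objective = 3),
    fakeResult(c("D"), c("E"), 0.03, objective = 1.5),
    fakeResult(c("F"), character(), 0.5, objective = 9))
  fin <- selectFinalModules(rs, alpha = 0.05)
  keys <- vapply(fin, function(s) paste(moduleGenes(s), collapse = ","),
                 character(1))
  ## {A,B} subset of {A,B,C} -> dropped; F not significant; {D}/{E} kept
  expect_setequal(keys, c("A,B,C", "D,E"))
  ## deterministic order: descending objective
  expect_identical(keys, c("A,B,C", "D,E"))
})

test_that("side labels matter for containment by default", {
  rs <- list(
    fakeResult(c("A"), character(), 0.01, objective = 1),
    fakeResult(character(), c("A", "B"), 0.01, objective = 2))
  ## A-increased is not contained in {A,B}-decreased
  fin <- selectFinalModules(rs, alpha = 0.05)
  expect_equal(length(fin), 2L)
  ## union-based containment collapses them
  fin2 <- selectFinalModules(rs, alpha = 0.05, respectSides = FALSE)
  expect_equal(length(fin2), 1L)
})

test_that("the final list is an antichain and grows with alpha", {
  set.seed(1301)
  rs <- lapply(1:15, function(i) {
    gs <- sample(LETTERS[1:6], sample(1:4, 1))
    ndec <- sample(0:length(gs), 1)
    fakeResult(setdiff(gs, gs[seq_len(ndec)]), gs[seq_len(ndec)],
               p = runif(1, 0.001, 0.2), objective = runif(1, 0.5, 4))
  })
  last <- 0
  for (alpha in c(0.01, 0.05, 0.1, 0.2)) {
    fin <- selectFinalModules(rs, alpha = alpha)
    expect_gte(length(fin), last)
    last <- length(fin)
    mods <- lapply(fin, solutionModule)
    for (i in seq_along(mods)) for (j in seq_along(mods)) {
      if (i != j)
        expect_false(phenomod:::.isStrictSubmodule(mods[[i]], mods[[j]]))
    }
  }
})

test_that("time-limited candidates are excluded from finals by default", {
  rs <- list(fakeResult("A", character(), 0.01, objective = 2,
                        status = "feasible_time_limited"))
  expect_equal(length(selectFinalModules(rs, alpha = 0.05)), 0L)
  expect_equal(length(selectFinalModules(rs, alpha = 0.05,
                                         includeTimeLimited = TRUE)), 1L)
})
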