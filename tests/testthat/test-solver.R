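test_that("k = 1 reduces to an exhaustive single-gene scan", {
  for (i in 1:5) {
    inst <- randomInstance(seed = 500 + i)
    wv <- phenotypeWeights(inst$w)
    best1 <- max(0, vapply(genes(inst$A), function(g)
      max(oneSidedObjective(g, inst$A, wv),
          oneSidedObjective(g, inst$A, -wv)), numeric(1)))
    sol <- solveModule(inst$A, inst$w, inst$net, SolverConfig(
      k = 1, model = "combined", penalty = PenaltyScheme("none")))
    expect_equal(objectiveValue(sol), best1, tolerance = 1e-9)
  }
})

test_that("combined connectivity forces bridge genes on a path graph", {
  ## a - b - c; only {a, c} are jointly profitable
  A <- AlterationMatrix(matrix(
    c(1, 0, 0, 0,
      0, 1, 1, 0,
      0, 0, 0, 1),
    3, 4, byrow = TRUE,
    dimnames = list(c("a", "b", "c"), paste0("p", 1:4))))
  w <- PhenotypeProfile(c(p1 = 2, p2 = -0.5, p3 = -0.5, p4 = 2))
  net <- GeneNetwork(data.frame(gene1 = c("a", "b"), gene2 = c("b", "c"),
                                score = 1))
  cfg <- SolverConfig(k = 3, model = "combined",
                      penalty = PenaltyScheme("none"), sides = "increased")
  sol <- solveModule(A, w, net, cfg)
  oracle <- bruteForceBest(A, w, net, cfg)
  expect_equal(objectiveValue(sol), objectiveValue(oracle),
               tolerance = 1e-9)
  ## {a, c} alone (objective 4) is not connected; optimum must include b
  ## (4 - 1 = 3) or stay single-gene (2): brute force says which
  expect_equal(objectiveValue(oracle), 3)
  expect_true(moduleIsConnected(solutionModule(sol), net, "combined"))
})

test_that("separate model selects disconnected opposite-direction genes", {
  ## x profits on the increased side, y on the decreased side; no edge x-y
  A <- AlterationMatrix(matrix(
    c(1, 1, 0, 0,
      0, 0, 1, 1),
    2, 4, byrow = TRUE,
    dimnames = list(c("x", "y"), paste0("p", 1:4))))
  w <- PhenotypeProfile(c(p1 = 1.5, p2 = 1, p3 = -1, p4 = -1.2))
  net <- GeneNetwork(data.frame(gene1 = "x", gene2 = "z", score = 1),
                     nodes = c("x", "y", "z"))
  A2 <- AlterationMatrix(rbind(alterationCalls(A),
                               z = c(0L, 0L, 0L, 0L)))
  cfgS <- SolverConfig(k = 2, model = "separate",
                       penalty = PenaltyScheme("none"))
  solS <- solveModule(A2, w, net, cfgS)
  expect_identical(increasedGenes(solutionModule(solS)), "x")
  expect_identical(decreasedGenes(solutionModule(solS)), "y")
  expect_equal(objectiveValue(solS), 2.5 + 2.2)
  ## combined model cannot join them: it must pick one side
  cfgC <- SolverConfig(k = 2, model = "combined",
                       penalty = PenaltyScheme("none"))
  solC <- solveModule(A2, w, net, cfgC)
  expect_equal(objectiveValue(solC),
               objectiveValue(bruteForceBest(A2, w, net, cfgC)))
  expect_lt(objectiveValue(solC), objectiveValue(solS))
})

test_that("all-negative weights give the empty module with objective 0", {
  inst <- randomInstance(seed = 521, nGenes = 6, nSamples = 8)
  w <- PhenotypeProfile(setNames(-abs(phenotypeWeights(inst$w)) - 0.1,
                                 samples(inst$w)))
  sol <- solveModule(inst$A, w, inst$net,
                     SolverConfig(k = 3, model = "combined",
                                  penalty = PenaltyScheme("none"),
                                  sides = "increased"))
  expect_equal(objectiveValue(sol), 0)
  expect_equal(moduleSize(solutionModule(sol)), 0)
})

test_that("solver matches the enumeration oracle across models and penalties", {
  ## the deep 200-instance sweep lives in the acceptance suite; this is the
  ## fast regression version
  bad <- 0
  for (i in 1:25) {
    inst <- randomInstance(seed = 600 + i)
    model <- if (i %% 2) "combined" else "separate"
    pen <- switch(1 + (i %% 3), PenaltyScheme("none"),
                  PenaltyScheme("abs_weight", 1),
                  PenaltyScheme("constant", 0.4))
    sides <- c("both", "increased", "decreased")[1 + (i %% 3)]
    cfg <- SolverConfig(k = 2 + (i %% 3), model = model, penalty = pen,
                        sides = sides)
    sol <- solveModule(inst$A, inst$w, inst$net, cfg)
    ora <- bruteForceBest(inst$A, inst$w, inst$net, cfg)
    expect_equal(objectiveValue(sol), objectiveValue(ora),
                 tolerance = 1e-6,
                 label = sprintf("instance %d (%s/%s/%s)", i, model,
                                 pen@mode, sides))
    expect_true(moduleIsConnected(solutionModule(sol), inst$net, model))
  }
})

test_that("optimal objectives are monotone in k and in the penalty", {
  for (i in 1:6) {
    inst <- randomInstance(seed = 700 + i)
    for (model in c("combined", "separate")) {
      objs <- vapply(1:4, function(k)
        objectiveValue(solveModule(inst$A, inst$w, inst$net,
          SolverConfig(k = k, model = model,
                       penalty = PenaltyScheme("none")))), numeric(1))
      expect_true(all(diff(objs) >= -1e-9))
      ## penalized optimum never beats the unpenalized one
      pen <- objectiveValue(solveModule(inst$A, inst$w, inst$net,
        SolverConfig(k = 3, model = model,
                     penalty = PenaltyScheme("abs_weight", 1))))
      unpen <- objectiveValue(solveModule(inst$A, inst$w, inst$net,
        SolverConfig(k = 3, model = model,
                     penalty = PenaltyScheme("none"))))
      expect_lte(pen, unpen + 1e-9)
    }
    ## with a single allowed direction the two connectivity models coincide
    ## (one connected set either way); neither model dominates in general
    cO <- objectiveValue(solveModule(inst$A, inst$w, inst$net,
      SolverConfig(k = 3, model = "combined", sides = "increased")))
    sO <- objectiveValue(solveModule(inst$A, inst$w, inst$net,
      SolverConfig(k = 3, model = "separate", sides = "increased")))
    expect_equal(sO, cO, tolerance = 1e-9)
  }
})

test_that("brute force is permutation-invariant under gene relabeling", {
  inst <- randomInstance(seed = 801, nGenes = 6, nSamples = 10)
  cfg <- SolverConfig(k = 3, model = "combined",
                      penalty = PenaltyScheme("abs_weight", 1))
  ora1 <- bruteForceBest(inst$A, inst$w, inst$net, cfg)
  ## relabel genes reversibly
  map <- setNames(sprintf("Z%02d", seq_along(genes(inst$A))),
                  genes(inst$A))
  calls <- alterationCalls(inst$A)
  rownames(calls) <- unname(map[rownames(calls)])
  g2 <- networkGraph(inst$net)
  igraph::V(g2)$name <- unname(map[igraph::V(g2)$name])
  ora2 <- bruteForceBest(AlterationMatrix(calls), inst$w, GeneNetwork(g2),
                         cfg)
  expect_equal(objectiveValue(ora1), objectiveValue(ora2))
  expect_identical(unname(map[moduleGenes(ora1@module)]),
                   moduleGenes(ora2@module))
  ## guard against combinatorial blow-up
  big <- randomInstance(seed = 802, nGenes = 16, nSamples = 6)
  expect_error(bruteForceBest(big$A, big$w, big$net, cfg), "guarded")
})

test_that("the time limit returns the incumbent with the limited status", {
  inst <- smallPlanted(seed = 901, nGenes = 150, nSamples = 60,
                       plantedSize = 4)
  sol <- solveModule(inst@alterations, inst@phenotype, inst@network,
                     SolverConfig(k = 5, model = "separate",
                                  timeLimit = 1e-4))
  expect_identical(solverStatus(sol), "feasible_time_limited")
  expect_gte(objectiveValue(sol), 0)
})

test_that("exact-size mode forces the requested cardinality", {
  inst <- randomInstance(seed = 921, nGenes = 8, nSamples = 10)
  cfg <- SolverConfig(k = 3, model = "combined",
                      penalty = PenaltyScheme("none"), exactSize = TRUE)
  sol <- solveModule(inst$A, inst$w, inst$net, cfg)
  ora <- bruteForceBest(inst$A, inst$w, inst$net, cfg)
  if (solverStatus(sol) != "infeasible") {
    expect_equal(moduleSize(solutionModule(sol)), 3L)
    expect_equal(objectiveValue(sol), objectiveValue(ora),
                 tolerance = 1e-6)
  } else {
    expect_identical(solverStatus(ora), "infeasible")
  }
})
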