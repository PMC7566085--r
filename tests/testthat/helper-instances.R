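## Shared fixture builders: everything is generated in code under fixed seeds.

## the worked 2-gene / 4-sample instance used throughout the objective tests:
## g1 altered in {p1, p3}, g2 altered in {p1, p4}, w = (3, 2, -1, 1)
workedInstance <- function() {
  A <- AlterationMatrix(matrix(
    c(1, 0, 1, 0,
      1, 0, 0, 1),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("g1", "g2"), paste0("p", 1:4))))
  w <- c(p1 = 3, p2 = 2, p3 = -1, p4 = 1)
  net <- GeneNetwork(data.frame(gene1 = "g1", gene2 = "g2", score = 1))
  list(A = A, w = w, profile = PhenotypeProfile(w), net = net)
}

## a random instance: connected random graph, Bernoulli alteration matrix,
## Gaussian weights; sized for brute-force verification
randomInstance <- function(seed, nGenes = NULL, nSamples = NULL,
                           altRate = 0.3, edgeProb = 0.4) {
  set.seed(seed)
  n <- if (is.null(nGenes)) sample(4:10, 1) else nGenes
  ns <- if (is.null(nSamples)) sample(6:15, 1) else nSamples
  repeat {
    g <- igraph::sample_gnp(n, edgeProb)
    if (igraph::ecount(g) > 0) break
  }
  igraph::V(g)$name <- paste0("G", seq_len(n))
  igraph::E(g)$score <- 1
  net <- GeneNetwork(g, nodes = paste0("G", seq_len(n)))
  calls <- matrix(stats::rbinom(n * ns, 1, altRate), n, ns,
                  dimnames = list(paste0("G", seq_len(n)),
                                  paste0("s", seq_len(ns))))
  wv <- stats::setNames(round(stats::rnorm(ns), 3), paste0("s", seq_len(ns)))
  list(A = AlterationMatrix(calls), w = PhenotypeProfile(wv), net = net)
}

## small planted instance for pipeline-level tests
smallPlanted <- function(seed, nGenes = 30, nSamples = 40, plantedSize = 3) {
  simulateInstance(simulationParams(
    nGenes = nGenes, nSamples = nSamples, plantedSize = plantedSize,
    seed = seed))
}
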