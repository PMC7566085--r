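## independent breadth-first search used as the distance oracle
bfsDistances <- function(adj, from) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (u in adj[[v]]) {
      if (is.infinite(dist[u])) {
        dist[u] <- dist[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  dist
}

test_that("target distances follow hand-computed shortest paths", {
  ## path t - x - y
  net <- GeneNetwork(data.frame(gene1 = c("t", "x"), gene2 = c("x", "y"),
                                score = 1))
  m <- TwoSidedModule(increased = c("x", "y"))
  d <- moduleTargetDistance(m, "t", net)
  expect_equal(unname(d$perGene[c("x", "y")]), c(1, 2))
  expect_equal(d$meanOverall, 1.5)
  expect_equal(d$meanIncreased, 1.5)
  expect_true(is.na(d$meanDecreased))
  ## a module gene that is itself a target sits at distance 0
  expect_equal(
    moduleTargetDistance(TwoSidedModule("t"), "t", net)$meanOverall, 0)
  ## minimum over multiple targets
  net2 <- GeneNetwork(data.frame(
    gene1 = c("t1", "a", "t2"), gene2 = c("a", "b", "g"), score = 1))
  d2 <- moduleTargetDistance(TwoSidedModule("g"), c("t1", "t2"), net2)
  expect_equal(unname(d2$perGene["g"]), 1)
  ## unreachable genes are excluded and counted
  net3 <- GeneNetwork(data.frame(gene1 = "t", gene2 = "x", score = 1),
                      nodes = c("t", "x", "iso"))
  d3 <- moduleTargetDistance(TwoSidedModule(c("x", "iso")), "t", net3)
  expect_equal(d3$meanOverall, 1)
  expect_equal(d3$nUnreachable, 1L)
})

test_that("target distances agree with a BFS oracle on random graphs", {
  set.seed(1401)
  for (i in 1:5) {
    n <- 50
    g <- igraph::sample_gnp(n, 0.08)
    igraph::V(g)$name <- sprintf("n%02d", 1:n)
    igraph::E(g)$score <- 1
    net <- GeneNetwork(g)
    adj <- lapply(seq_len(n), function(v)
      as.integer(igraph::neighbors(networkGraph(net), v)))
    targets <- sample(n, 3)
    mg <- sample(setdiff(seq_len(n), targets), 6)
    dmat <- vapply(targets, function(t) bfsDistances(adj, t), numeric(n))
    expected <- apply(dmat[mg, , drop = FALSE], 1, min)
    nms <- igraph::V(networkGraph(net))$name
    names(expected) <- nms[mg]
    m <- TwoSidedModule(increased = nms[mg])
    got <- moduleTargetDistance(m, nms[targets], net)
    expect_equal(got$perGene, expected[names(got$perGene)],
                 tolerance = 1e-12)
    ## means match the oracle's
    fin <- expected[is.finite(expected)]
    expect_equal(got$meanOverall,
                 if (length(fin)) mean(fin) else NA_real_)
  }
})

test_that("sample grouping partitions by side-specific alteration status", {
  A <- AlterationMatrix(matrix(
    c(1, 0, 0, 1, 0,
      0, 1, 0, 1, 0,
      0, 0, 0, 0, 0),
    3, 5, byrow = TRUE,
    dimnames = list(c("up", "down", "idle"), paste0("s", 1:5))))
  m <- TwoSidedModule(increased = "up", decreased = "down")
  gr <- assignGroups(m, A)
  expect_identical(as.character(gr[c("s1", "s2", "s3", "s4", "s5")]),
                   c("increased_only", "decreased_only", "unaltered",
                     "excluded", "unaltered"))
  ## the four buckets partition the samples
  expect_equal(sum(table(gr)), 5)
  ## a sample altered in two same-side genes stays in that side's group
  A2 <- AlterationMatrix(matrix(
    c(1, 0, 1, 0), 2, 2, byrow = TRUE,
    dimnames = list(c("u1", "u2"), c("s1", "s2"))))
  gr2 <- assignGroups(TwoSidedModule(increased = c("u1", "u2")), A2)
  expect_identical(as.character(gr2[["s1"]]), "increased_only")
})

test_that("the three-group ANOVA matches a direct SS decomposition", {
  g <- factor(rep(c("a", "b", "c"), each = 2))
  names(g) <- paste0("s", 1:6)
  y <- setNames(c(0, 1, 10, 11, 20, 21), names(g))
  got <- anovaThreeGroup(g, y)
  ## textbook decomposition oracle
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2)))
  Fref <- (ssb / 2) / (ssw / 3)
  expect_equal(got$F, Fref, tolerance = 1e-9)
  expect_equal(got$p, stats::pf(Fref, 2, 3, lower.tail = FALSE),
               tolerance = 1e-9)
  ## identical group distributions: F = 0, p = 1
  y2 <- setNames(rep(c(1, 2, 3), times = 3),
                 paste0("t", 1:9))
  g2 <- setNames(factor(rep(c("a", "b", "c"), each = 3)), names(y2))
  got2 <- anovaThreeGroup(g2, y2)
  expect_equal(got2$F, 0, tolerance = 1e-12)
  expect_equal(got2$p, 1, tolerance = 1e-12)
  ## insufficient groups give the sentinel, not an error
  g3 <- setNames(factor(c("a", "a", "b")), paste0("u", 1:3))
  y3 <- setNames(c(1, 2, 3), names(g3))
  got3 <- anovaThreeGroup(g3, y3)
  expect_false(got3$testable)
  expect_true(is.na(got3$F))
})

test_that("BH adjustment equals the hand step-up formula", {
  expect_equal(benjaminiHochberg(0.03), 0.03)
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjaminiHochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  ## random lists against the step-up definition
  set.seed(1501)
  for (i in 1:10) {
    p <- runif(sample(3:12, 1))
    m <- length(p)
    o <- order(p)
    stepup <- numeric(m)
    prev <- 1
    for (r in m:1) {
      prev <- min(prev, p[o[r]] * m / r)
      stepup[o[r]] <- prev
    }
    expect_equal(benjaminiHochberg(p), stepup, tolerance = 1e-12)
    expect_true(all(benjaminiHochberg(p) >= p - 1e-12))
    expect_true(all(benjaminiHochberg(p) <= 1))
  }
})

test_that("drug pairing reports exactly the opposite-direction witnesses", {
  m1 <- TwoSidedModule(increased = c("EGFR"), decreased = c("KRAS", "NRAS"))
  m2 <- TwoSidedModule(increased = c("KRAS", "NRAS"), decreased = "TP53")
  m3 <- TwoSidedModule(increased = c("KRAS"))
  pairs <- suggestDrugPairs(list(afatinib = list(m1),
                                 selumetinib = list(m2),
                                 other = list(m3)))
  ## afatinib/selumetinib share KRAS+NRAS in opposite directions
  row <- pairs[pairs$drug1 == "afatinib" & pairs$drug2 == "selumetinib", ]
  expect_equal(nrow(row), 1L)
  expect_identical(row$witnesses, "KRAS,NRAS")
  ## same-direction sharing (selumetinib/other both KRAS-increased): no pair
  expect_false(any(pairs$drug1 == "other" & pairs$drug2 == "selumetinib" |
                     pairs$drug1 == "selumetinib" & pairs$drug2 == "other"))
  ## but other's KRAS-increased opposes afatinib's KRAS-decreased
  expect_equal(pairs$witnesses[pairs$drug1 == "afatinib" &
                                 pairs$drug2 == "other"], "KRAS")
  ## symmetry: swapping the input order reports the same unordered pair
  pairs2 <- suggestDrugPairs(list(selumetinib = list(m2),
                                  afatinib = list(m1)))
  expect_identical(pairs2$witnesses, "KRAS,NRAS")
  ## disjoint modules produce nothing
  none <- suggestDrugPairs(list(
    d1 = list(TwoSidedModule(increased = "A")),
    d2 = list(TwoSidedModule(decreased = "B"))))
  expect_equal(nrow(none), 0L)
})
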