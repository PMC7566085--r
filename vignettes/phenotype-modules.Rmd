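---
title: "Finding connected gene modules associated with drug response"
author: "phenomod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding connected gene modules associated with drug response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomod)
```

# The problem

Drug response in cancer cell lines is a continuous phenotype driven by
heterogeneous genetic alterations: different samples that respond to the
same drug often carry causal alterations in *different but functionally
related* genes. Single-gene association tests miss this, because each
individual gene may be altered in only a few samples. `phenomod` searches a
gene interaction network for a *connected* set of genes whose combined
alterations cover the responsive samples — a connected set cover formulation
of the genotype–phenotype association problem.

# The model

The inputs are a binary alteration matrix \(A\) (\(A(g,p)=1\) if gene
\(g\) is altered in sample \(p\)), a per-sample weight vector \(w\)
(z-scored drug sensitivity; larger = more sensitive), and an undirected
gene network \(G=(V,E)\). For a gene set \(S\), its *coverage* \(P(S)\) is
the set of samples altered in at least one gene of \(S\). The score of a
set is

\[
W(S) \;=\; \sum_{p \in P(S)} w(p) \;-\; \sum_{p \in P(S)} pt(p)\,\bigl(c(p,S)-1\bigr),
\]

where \(c(p,S)\) counts how many selected genes are altered in \(p\), and
\(pt(p)\) is a penalty on *overlapping* alterations. Cancer driver
alterations in the same pathway tend to be mutually exclusive across
samples; the penalty makes the optimizer prefer such mutually exclusive
covers. The first term alone (penalty mode `"none"`) is the plain coverage
objective.

Modules are two-sided: a set of *increased-sensitivity* genes scored
against \(+w\) and a disjoint set of *decreased-sensitivity* (resistance)
genes scored against \(-w\), selected simultaneously. Two connectivity
models are supported:

* **combined** — all selected genes, both directions together, must induce
  one connected subgraph;
* **separate** — each nonempty side must be connected on its own.

Neither model dominates the other. Combined admits solutions whose sides
are individually disconnected but joined across directions; separate admits
two components far apart in the network. When only one direction is allowed
(`sides = "increased"`), the two models coincide. The empty module is
always feasible with \(W=0\), so reported optima are nonnegative.

## Penalty choice

`PenaltyScheme("abs_weight", lambda = 1)` is the default:
\(pt(p)=\lambda\,|w(p)|\). Scaling the penalty by the sample's own weight
keeps the objective scale-free — covering a strongly-responsive sample
twice forfeits exactly the reward of covering it once — and a unit
\(\lambda\) makes penalty and reward commensurate. A `"constant"` mode
(\(pt(p)=\lambda\), in weight units) is provided for sensitivity analysis.
A sample covered by *both* sides is not penalized across sides; the
`crossSideOverlap()` diagnostic reports such samples, and they are excluded
from the three-group validation below.

## Phenotype convention

`normalizePhenotype()` z-scores the raw response (mean 0, population
standard deviation 1). Centering matters: it makes the expected weight of a
randomly covered sample zero, so \(W\) measures association rather than
coverage volume. Raw IC50-style inputs, where *smaller* means more
sensitive, are accommodated with `negate = TRUE`. Samples with missing
phenotype are dropped at load, never imputed, and `alignSamples()`
restricts \(A\) and \(w\) to their common samples.

# Exact optimization

The maximizer of \(W\) over connected sets of at most \(k\) genes is found
*exactly* by a branch-and-bound implemented in C++: connected subsets are
enumerated once each (ESU-style enumeration rooted at each gene), the best
side assignment of a subset is found by Gray-code enumeration, and branches
are pruned with an admissible bound — extending a partial module by \(r\)
genes can gain at most the sum of the \(r\) largest per-gene potentials
\(\sum_{p \in cov(g)} \max(\pm w(p),0)\), since penalties only subtract.
Genes are visited in decreasing potential order so strong incumbents form
early. With `gap = 0` (default) the returned module is a proven optimum;
`timeLimit` (default 600 s) returns the incumbent with status
`"feasible_time_limited"` when exceeded, and such candidates are excluded
from final reporting by default.

Every solution is re-scored through the independent reference objective
(`moduleObjective()`) and its connectivity re-checked by graph traversal
before it is returned; a disagreement beyond 1e-6 is an error, not a
warning. `bruteForceBest()` — plain R enumeration over `combn()` subsets
with igraph connectivity checks — shares no code with the search and serves
as the verification oracle in the test suite (guarded to 15 genes).

Numerical conventions: objective comparisons in the search use a strict
improvement threshold of 1e-12; the brute-force oracle breaks ties
lexicographically by sorted gene names, then by side assignment, so its
output is fully deterministic. Optima are compared in tests at 1e-6.

# Significance and final modules

Candidates are generated over a grid: \(k = 1..k_{max}\), both connectivity
models, one or more penalty schemes (`generateCandidates()`). Each
candidate's association is assessed by permuting the phenotype values
across samples and re-solving the same optimization
(`permutationTest()`); the add-one estimator

\[
p = \frac{1 + \#\{W_{null} \ge W_{obs}\}}{1 + n_{perm}}
\]

is never zero and is exact under exchangeability, which holds because the
alteration matrix stays fixed. Because each permutation re-runs a full
optimization, the null distribution correctly reflects the selection
optimism of the search — the dominant effect at small gene counts.
Permutations are driven entirely by the user-supplied seed and are
bit-reproducible.

Final modules are the *maximal* significant candidates
(`selectFinalModules()`): among candidates with \(p < \alpha\) (default
0.05, no multiple-testing correction across the grid — per-module
permutation significance is the reported quantity), any module strictly
contained in another significant module is dropped, so the output is an
antichain under set inclusion. Containment respects side labels by default
(a gene counted as sensitivity-increasing is not "contained" in a module
carrying it on the resistance side); `respectSides = FALSE` compares plain
gene unions.

# The simulator

`simulateInstance()` generates a complete benchmark instance with known
ground truth: a scale-free Barabási–Albert network (m = 2) — the degree
heterogeneity of real interactomes is the property that matters here — a
planted connected module grown by a random walk, alterations planted so a
target fraction of samples is covered (under `"exclusive"` planting every
covered sample carries exactly one planted alteration and every planted
gene covers at least one sample), Bernoulli background alterations
everywhere else, and a phenotype shifted by `effectSize` noise standard
deviations in covered samples before z-scoring. Planted gene rows are fully
determined by the planting step, so the realized coverage equals the
target. With `effectSize = 0` the phenotype is independent of all
alterations — the null construction used for calibration.

Reference regime (the defaults): 150 genes, 100 samples, background rate
0.05, coverage 0.3, effect size 2, noise sd 1, planted sizes 3–5. These
describe a clearly detectable pharmacogenomic association at screening
scale; the recovery benchmark searches the planted direction
(`sides = "increased"`), matching the one-direction planting.

What the simulator does *not* emulate: real mutation backgrounds are
heavy-tailed across genes (a few very frequently altered genes, many rare
ones) and correlated across samples (co-amplification, mutator phenotypes);
real networks have literature bias; drug response noise is not Gaussian.
Passing recovery tests here demonstrates correctness of the optimization
and calibration machinery under a clean generative model, not performance
on screening data.

## A known limitation: spurious extension at small planted sizes

When the search size exceeds the planted size, an exact maximizer appends a
neighboring gene whenever its marginal gain — newly covered weights minus
overlap penalties — is positive. After z-scoring, uncovered samples have
negative mean weight, so the expected gain is clearly negative and
per-gene extension probability is a few percent; but scale-free hubs give a
planted module dozens of eligible neighbors, so a minority of replicates
still gains one or two spurious genes. Three-gene modules suffer the
largest relative F1 loss per spurious gene, and in our benchmark their mean
F1 at `k = planted + 2` degrades by slightly more than 0.1 (larger planted
sizes stay within 0.1). We report this honestly rather than raising the
default penalty: \(\lambda\) is a modeling choice, not a tuning dial for
benchmarks.

# Evaluation utilities

* `moduleTargetDistance()` — minimum unweighted hop distance from each
  module gene to any drug target, averaged per side and overall (edge
  confidence scores are used only for thresholding at load time). Genes
  unreachable from every target are excluded from means and counted. Both
  per-drug means and pooled per-gene distances can be derived from the
  returned per-gene vector.
* `assignGroups()` / `anovaThreeGroup()` — the three-group validation:
  samples altered in decreased-side genes only, increased-side genes only,
  or unaltered, compared by fixed-effects one-way ANOVA on an independent
  response; samples altered on both sides do not fit any group and are
  excluded (a toggle tests them as a fourth group). Fewer than two groups
  with two samples each yields a not-testable sentinel.
* `benjaminiHochberg()` — step-up FDR adjustment for families of ANOVA
  p-values.
* `suggestDrugPairs()` — combination-therapy screening: drug pairs whose
  modules share at least `minShared` genes with *opposite* side labels
  (sensitivity for one drug, resistance for the other), with the witnessing
  genes listed; an optional Jaccard threshold on the module overlap is off
  by default since plain witness counting is the more interpretable rule.

# Problem sizes used by the test suite

The oracle sweep verifies the search against brute force on 200 random
instances of up to 10 genes and 15 samples (k ≤ 4, both models, penalty on
and off) — sizes chosen so exhaustive enumeration stays trivially correct
and the whole sweep runs in about a minute. Recovery uses 50 replicates per
planted size at the reference regime; calibration uses 200 null replicates
of 12 genes × 30 samples with 100 permutations each, keeping every
permutation solve sub-millisecond. These sizes are the package's own
benchmark definition and are reproduced by `scripts/acceptance.R`.

# Other limitations

* Alterations are binary; continuous dosage or VAF-weighted alterations are
  out of scope.
* The module search is exponential in the worst case; it is exact, not
  polynomial. Practical sizes (a few hundred network genes after frequency
  filtering, k ≤ 8) solve in seconds, but adversarial dense instances can
  hit the time limit, and such solutions are flagged.
* Associations are not causal claims; systematically co-occurring
  alterations (e.g. co-amplified neighbors) are interchangeable to a set
  cover and only one representative may be selected.
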