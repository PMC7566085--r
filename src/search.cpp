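// Exact optimizer for the connected two-sided module problem.
//
// Enumerates connected vertex subsets with the ESU scheme (each connected
// subset visited exactly once, rooted at its minimum-index gene) and prunes
// with an admissible bound: any extension of a partial module by r further
// genes can gain at most the sum of the r largest per-gene coverage bounds
// ub(g) = sum_{p in cov(g)} |w(p)|, since a newly covered sample contributes
// at most |w(p)| and penalties only subtract.  Genes are relabeled in
// decreasing ub order so strong incumbents are found early and the top-r
// bound is a prefix scan.

#include <Rcpp.h>
#include <chrono>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Search {
  int n = 0, ns = 0, k = 1, penMode = 0, model = 0, sides = 0;
  bool exactSize = false;
  double lambda = 0.0, gap = 0.0;
  const double tol = 1e-12;

  std::vector<std::vector<int>> adj, cov;
  // pot[p]: largest possible contribution of newly covering sample p under
  // the allowed side assignments (|w| both, max(w,0) inc-only, ...)
  std::vector<double> w, absw, pot, ptv, ub;

  // state for the primary (combined / increased-side) enumeration
  std::vector<int> covCount, coveredStack, curGenes;
  double U = 0.0, fInc = 0.0, fDec = 0.0;
  std::vector<char> inS, seen;

  // state for the nested decreased-side enumeration (separate model)
  std::vector<int> covCount2, coveredStack2, curGenes2;
  double U2 = 0.0, fDec2 = 0.0;
  std::vector<char> inS2, seen2;

  std::vector<int> cInc, cDec;  // split-evaluation scratch, indexed by sample

  double best = 0.0;
  bool found = false;
  std::vector<int> bestInc, bestDec;

  long long nodes = 0;
  std::chrono::steady_clock::time_point deadline;
  bool timedOut = false;

  bool timeUp() {
    if (timedOut) return true;
    if ((++nodes & 2047) == 0 &&
        std::chrono::steady_clock::now() > deadline)
      timedOut = true;
    return timedOut;
  }

  double threshold() const {
    if (!found) return -1e300;
    return best + gap * std::fabs(best) + tol;
  }

  // sum of the r largest per-gene bounds over genes outside the current
  // selection(s); genes are ub-sorted by index, so a prefix scan suffices
  double topUb(int r, bool excludeInner) const {
    double t = 0.0;
    int taken = 0;
    for (int g = 0; g < n && taken < r; ++g) {
      if (inS[g] || (excludeInner && inS2[g])) continue;
      if (ub[g] <= 0.0) break;
      t += ub[g];
      ++taken;
    }
    return t;
  }

  void add(int g) {
    inS[g] = 1;
    curGenes.push_back(g);
    for (int p : cov[g]) {
      if (covCount[p]++ == 0) {
        coveredStack.push_back(p);
        U += pot[p];
        fInc += w[p];
        fDec -= w[p];
      } else {
        fInc -= ptv[p];
        fDec -= ptv[p];
      }
    }
  }

  void rem(int g) {
    inS[g] = 0;
    curGenes.pop_back();
    for (int p : cov[g]) {
      if (--covCount[p] == 0) {
        coveredStack.pop_back();
        U -= pot[p];
        fInc -= w[p];
        fDec += w[p];
      } else {
        fInc += ptv[p];
        fDec += ptv[p];
      }
    }
  }

  void add2(int g) {
    inS2[g] = 1;
    curGenes2.push_back(g);
    for (int p : cov[g]) {
      if (covCount2[p]++ == 0) {
        coveredStack2.push_back(p);
        U2 += pot[p];
        fDec2 -= w[p];
      } else {
        fDec2 -= ptv[p];
      }
    }
  }

  void rem2(int g) {
    inS2[g] = 0;
    curGenes2.pop_back();
    for (int p : cov[g]) {
      if (--covCount2[p] == 0) {
        coveredStack2.pop_back();
        U2 -= pot[p];
        fDec2 += w[p];
      } else {
        fDec2 += ptv[p];
      }
    }
  }

  void record(const std::vector<int>& inc, const std::vector<int>& dec,
              double obj) {
    best = obj;
    bestInc = inc;
    bestDec = dec;
    found = true;
  }

  // ---- combined model: best side split of the current connected set ----

  void evalCombined() {
    int s = (int)curGenes.size();
    if (exactSize && s != k) return;
    if (found && U <= best + tol) return;  // no split can beat the incumbent
    if (sides == 1) {  // increased-only: single allowed assignment
      if (fInc > best + tol || !found) record(curGenes, {}, fInc);
      return;
    }
    if (sides == 2) {  // decreased-only
      if (fDec > best + tol || !found) record({}, curGenes, fDec);
      return;
    }
    int m = (int)coveredStack.size();
    for (int i = 0; i < m; ++i) {
      int p = coveredStack[i];
      cInc[p] = covCount[p];
      cDec[p] = 0;
    }
    unsigned curMask = 0u;
    unsigned total = 1u << s;
    for (unsigned i = 0; i < total; ++i) {
      if (i > 0) {
        unsigned gray = i ^ (i >> 1);
        unsigned flip = gray ^ curMask;
        int j = 0;
        while (!((flip >> j) & 1u)) ++j;
        bool toDec = (gray >> j) & 1u;
        int g = curGenes[j];
        if (toDec) {
          for (int p : cov[g]) { --cInc[p]; ++cDec[p]; }
        } else {
          for (int p : cov[g]) { ++cInc[p]; --cDec[p]; }
        }
        curMask = gray;
      }
      double obj = 0.0;
      for (int t = 0; t < m; ++t) {
        int p = coveredStack[t];
        if (cInc[p] > 0) obj += w[p] - ptv[p] * (cInc[p] - 1);
        if (cDec[p] > 0) obj += -w[p] - ptv[p] * (cDec[p] - 1);
      }
      if (obj > best + tol || (!found && obj > -1e299)) {
        if (!found || obj > best + tol) {
          std::vector<int> inc, dec;
          for (int j = 0; j < s; ++j) {
            if ((curMask >> j) & 1u) dec.push_back(curGenes[j]);
            else inc.push_back(curGenes[j]);
          }
          record(inc, dec, obj);
        }
      }
    }
  }

  void extendCombined(int root, std::vector<int> ext) {
    while (!ext.empty()) {
      if (timeUp()) return;
      int u = ext.back();
      ext.pop_back();
      add(u);
      evalCombined();
      int s = (int)curGenes.size();
      if (s < k && U + topUb(k - s, false) > threshold()) {
        std::vector<int> ext2 = ext;
        std::vector<int> newly;
        for (int x : adj[u]) {
          if (x > root && !seen[x]) {
            seen[x] = 1;
            newly.push_back(x);
            ext2.push_back(x);
          }
        }
        extendCombined(root, ext2);
        for (int x : newly) seen[x] = 0;
      }
      rem(u);
    }
  }

  void runCombined() {
    for (int v = 0; v < n; ++v) {
      if (timeUp()) return;
      if (ub[v] + topUb(k - 1, false) <= threshold() && !exactSize) {
        // genes are ub-sorted: no later root can open a better branch
        // (bound only shrinks), but exact-size runs must still visit
        break;
      }
      std::fill(seen.begin(), seen.end(), 0);
      seen[v] = 1;
      add(v);
      evalCombined();
      if (k > 1 && U + topUb(k - 1, false) > threshold()) {
        std::vector<int> ext;
        for (int u : adj[v]) {
          if (u > v) {
            seen[u] = 1;
            ext.push_back(u);
          }
        }
        extendCombined(v, ext);
      }
      rem(v);
    }
  }

  // ---- separate model: nested enumeration, dec side inside inc side ----

  void innerEval(int budget) {
    int s2 = (int)curGenes2.size();
    if (exactSize && s2 != budget) return;
    double obj = fInc + fDec2;
    if (obj > best + tol || !found) record(curGenes, curGenes2, obj);
  }

  void extendInner(int root, int budget, std::vector<int> ext) {
    while (!ext.empty()) {
      if (timeUp()) return;
      int u = ext.back();
      ext.pop_back();
      add2(u);
      innerEval(budget);
      int s2 = (int)curGenes2.size();
      if (s2 < budget &&
          fInc + U2 + topUb(budget - s2, true) > threshold()) {
        std::vector<int> ext2 = ext;
        std::vector<int> newly;
        for (int x : adj[u]) {
          if (x > root && !seen2[x] && !inS[x]) {
            seen2[x] = 1;
            newly.push_back(x);
            ext2.push_back(x);
          }
        }
        extendInner(root, budget, ext2);
        for (int x : newly) seen2[x] = 0;
      }
      rem2(u);
    }
  }

  void innerRun(int budget) {
    if (budget < 1) return;
    for (int v = 0; v < n; ++v) {
      if (timeUp()) return;
      if (inS[v]) continue;
      std::fill(seen2.begin(), seen2.end(), 0);
      seen2[v] = 1;
      add2(v);
      innerEval(budget);
      if (budget > 1 &&
          fInc + U2 + topUb(budget - 1, true) > threshold()) {
        std::vector<int> ext;
        for (int u : adj[v]) {
          if (u > v && !inS[u]) {
            seen2[u] = 1;
            ext.push_back(u);
          }
        }
        extendInner(v, budget, ext);
      }
      rem2(v);
    }
  }

  void evalOuterSeparate() {
    int s = (int)curGenes.size();
    if (!exactSize || s == k) {
      double obj = fInc;
      if ((obj > best + tol || !found) && !(exactSize && s == 0 && k > 0))
        if (s > 0 || !exactSize) record(curGenes, {}, obj);
    }
    if (sides == 0 && s < k && U + topUb(k - s, false) > threshold())
      innerRun(k - s);
  }

  void extendSeparate(int root, std::vector<int> ext) {
    while (!ext.empty()) {
      if (timeUp()) return;
      int u = ext.back();
      ext.pop_back();
      add(u);
      evalOuterSeparate();
      int s = (int)curGenes.size();
      if (s < k && U + topUb(k - s, false) > threshold()) {
        std::vector<int> ext2 = ext;
        std::vector<int> newly;
        for (int x : adj[u]) {
          if (x > root && !seen[x]) {
            seen[x] = 1;
            newly.push_back(x);
            ext2.push_back(x);
          }
        }
        extendSeparate(root, ext2);
        for (int x : newly) seen[x] = 0;
      }
      rem(u);
    }
  }

  void runSeparate() {
    // S_inc empty: pure decreased-side modules
    if (sides != 1) innerRun(k);
    if (sides == 2) return;
    for (int v = 0; v < n; ++v) {
      if (timeUp()) return;
      std::fill(seen.begin(), seen.end(), 0);
      seen[v] = 1;
      add(v);
      evalOuterSeparate();
      if (k > 1 && U + topUb(k - 1, false) > threshold()) {
        std::vector<int> ext;
        for (int u : adj[v]) {
          if (u > v) {
            seen[u] = 1;
            ext.push_back(u);
          }
        }
        extendSeparate(v, ext);
      }
      rem(v);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_solve_module(List adjList, List covList, NumericVector weights,
                      int k, int model, int penMode, double lambda,
                      double timeLimit, double gap, bool exactSize,
                      int sidesMode) {
  Search S;
  S.n = adjList.size();
  S.ns = weights.size();
  S.k = k;
  S.model = model;
  S.penMode = penMode;
  S.lambda = lambda;
  S.gap = gap;
  S.exactSize = exactSize;
  S.sides = sidesMode;

  if (k > 25) stop("module size k above 25 is not supported");

  std::vector<std::vector<int>> adj0(S.n), cov0(S.n);
  for (int g = 0; g < S.n; ++g) {
    IntegerVector a = adjList[g];
    adj0[g].assign(a.begin(), a.end());
    IntegerVector c = covList[g];
    cov0[g].assign(c.begin(), c.end());
  }
  S.w.assign(weights.begin(), weights.end());
  S.absw.resize(S.ns);
  S.pot.resize(S.ns);
  S.ptv.resize(S.ns);
  for (int p = 0; p < S.ns; ++p) {
    S.absw[p] = std::fabs(S.w[p]);
    S.pot[p] = sidesMode == 1 ? std::max(S.w[p], 0.0)
             : sidesMode == 2 ? std::max(-S.w[p], 0.0)
                              : S.absw[p];
    S.ptv[p] = penMode == 0 ? 0.0
             : penMode == 1 ? lambda * S.absw[p]
                            : lambda;
  }

  // relabel genes in decreasing order of their coverage bound
  std::vector<double> ub0(S.n, 0.0);
  for (int g = 0; g < S.n; ++g)
    for (int p : cov0[g]) ub0[g] += S.pot[p];
  std::vector<int> order(S.n);
  for (int g = 0; g < S.n; ++g) order[g] = g;
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return ub0[a] > ub0[b]; });
  std::vector<int> rank(S.n);
  for (int i = 0; i < S.n; ++i) rank[order[i]] = i;
  S.adj.resize(S.n);
  S.cov.resize(S.n);
  S.ub.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    int g = order[i];
    S.ub[i] = ub0[g];
    S.cov[i] = cov0[g];
    S.adj[i].reserve(adj0[g].size());
    for (int x : adj0[g]) S.adj[i].push_back(rank[x]);
    std::sort(S.adj[i].begin(), S.adj[i].end());
  }

  S.covCount.assign(S.ns, 0);
  S.covCount2.assign(S.ns, 0);
  S.cInc.assign(S.ns, 0);
  S.cDec.assign(S.ns, 0);
  S.inS.assign(S.n, 0);
  S.inS2.assign(S.n, 0);
  S.seen.assign(S.n, 0);
  S.seen2.assign(S.n, 0);

  if (!exactSize) {
    S.best = 0.0;
    S.found = true;  // the empty module is always feasible with W = 0
  } else {
    S.best = -1e300;
    S.found = false;
  }

  S.deadline = std::chrono::steady_clock::now() +
               std::chrono::duration_cast<std::chrono::steady_clock::duration>(
                   std::chrono::duration<double>(timeLimit));

  if (model == 0) S.runCombined();
  else S.runSeparate();

  IntegerVector inc(S.bestInc.size()), dec(S.bestDec.size());
  for (size_t i = 0; i < S.bestInc.size(); ++i) inc[i] = order[S.bestInc[i]];
  for (size_t i = 0; i < S.bestDec.size(); ++i) dec[i] = order[S.bestDec[i]];

  std::string status = !S.found ? "infeasible"
                     : S.timedOut ? "feasible_time_limited"
                                  : "optimal";
  return List::create(_["inc"] = inc, _["dec"] = dec,
                      _["objective"] = S.found ? S.best : NA_REAL,
                      _["status"] = status,
                      _["nodes"] = (double)S.nodes);
}
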