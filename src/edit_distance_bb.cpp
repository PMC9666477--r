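// Exact merge-tree edit distance by branch and bound over ancestry-preserving
// one-to-one vertex matchings (the mapping semantics of the R oracle).
//
// Cost of a complete matching: unmatched vertices whose subtree holds matched
// vertices in exactly one topmost position are ghosted (their edge weight is
// absorbed into the matched descendant's aggregated edge), every other
// unmatched vertex is deleted/inserted at its edge weight, and each matched
// pair pays the absolute difference of its ghost-aggregated weights.
//
// Admissible pruning bound at a partial assignment:
//   D1/D2   committed deletions/insertions (topmost matched antichain >= 2,
//           or a fully decided empty subtree);
//   gaps    committed pair costs from weight intervals fixed at match time;
//   J       a joint leaf assignment: a leaf can never be ghosted, so every
//           undecided A leaf and every free B leaf pays its edge weight
//           unless matched; J is the optimal assignment value under
//           optimistic pair gaps (Jonker-Volgenant shortest augmenting
//           paths), with escape lanes for matches against internal vertices;
//   glob    the weight-partition bound |(S1 - D1) - (S2 - D2)|.
//   LB = D1 + D2 + max(glob, gaps + J).
// The search seeds its incumbent with a greedy recursive matching and
// branches only once per class of interchangeable sibling candidates.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdio>
#include <functional>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

const double INF = 1e30;

struct Tree {
  int n;
  int root;
  std::vector<int> par;   // -1 for root
  std::vector<double> w;  // edge weight above each vertex (0 at root)
  std::vector<std::vector<int>> kids;
  std::vector<char> anc;  // anc[i*n+j]: i strict ancestor of j
  std::vector<char> isLeaf;
  std::vector<double> subw;  // subtree weight incl own edge
  std::vector<int> shapeId;  // equal iff subtrees isomorphic with equal weights
  double total;

  bool is_anc(int i, int j) const { return anc[(size_t)i * n + j] != 0; }
};

Tree build_tree(const IntegerVector& parR, const NumericVector& wR) {
  Tree t;
  t.n = parR.size();
  t.par.resize(t.n);
  t.w.resize(t.n);
  t.kids.assign(t.n, {});
  t.total = 0.0;
  t.root = -1;
  for (int v = 0; v < t.n; ++v) {
    t.par[v] = parR[v] - 1;  // R: 1-based, 0 = root sentinel
    t.w[v] = wR[v];
    if (t.par[v] < 0) {
      t.root = v;
      t.w[v] = 0.0;
    } else {
      t.kids[t.par[v]].push_back(v);
      t.total += t.w[v];
    }
  }
  t.anc.assign((size_t)t.n * t.n, 0);
  for (int v = 0; v < t.n; ++v)
    for (int u = t.par[v]; u >= 0; u = t.par[u]) t.anc[(size_t)u * t.n + v] = 1;
  t.isLeaf.assign(t.n, 0);
  for (int v = 0; v < t.n; ++v)
    if (t.kids[v].empty()) t.isLeaf[v] = 1;
  t.subw.assign(t.n, 0.0);
  std::function<double(int)> acc = [&](int v) {
    double s = (v == t.root) ? 0.0 : t.w[v];
    for (int k : t.kids[v]) s += acc(k);
    t.subw[v] = s;
    return s;
  };
  acc(t.root);
  // canonical subtree encodings -> dense ids
  std::vector<std::string> enc(t.n);
  std::function<void(int)> mk = [&](int v) {
    for (int k : t.kids[v]) mk(k);
    char buf[40];
    std::snprintf(buf, sizeof(buf), "%.12g", v == t.root ? 0.0 : t.w[v]);
    if (t.kids[v].empty()) {
      enc[v] = std::string("L") + buf;
    } else {
      std::vector<std::string> parts;
      for (int k : t.kids[v]) parts.push_back(enc[k]);
      std::sort(parts.begin(), parts.end());
      std::string s = "(";
      for (size_t i = 0; i < parts.size(); ++i) {
        if (i) s += ",";
        s += parts[i];
      }
      enc[v] = s + ")" + buf;
    }
  };
  mk(t.root);
  t.shapeId.assign(t.n, 0);
  std::vector<std::string> uniq;
  for (int v = 0; v < t.n; ++v) {
    size_t j = 0;
    while (j < uniq.size() && uniq[j] != enc[v]) ++j;
    if (j == uniq.size()) uniq.push_back(enc[v]);
    t.shapeId[v] = (int)j;
  }
  return t;
}

// square assignment problem, shortest augmenting path (Jonker-Volgenant).
// cost is row-major n x n; returns the optimal total.
double solve_lap(int n, const std::vector<double>& cost) {
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, n), way(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    p[n] = i;
    int j0 = n;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 0; j < n; ++j) {
        if (used[j]) continue;
        double cur = cost[(size_t)i0 * n + j] - u[i0] - v[j];
        if (cur < minv[j]) {
          minv[j] = cur;
          way[j] = j0;
        }
        if (minv[j] < delta) {
          delta = minv[j];
          j1 = j;
        }
      }
      if (j1 < 0) break;  // all remaining INF: should not happen (dummies)
      for (int j = 0; j <= n; ++j) {
        if (used[j]) {
          u[p[j]] += delta;
          v[j] -= delta;
        } else {
          minv[j] -= delta;
        }
      }
      j0 = j1;
    } while (p[j0] != n);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0 != n);
  }
  double total = 0.0;
  for (int j = 0; j < n; ++j)
    if (p[j] != n && p[j] >= 0) total += cost[(size_t)p[j] * n + j];
  return total;
}

struct Search {
  const Tree* A;
  const Tree* B;
  std::vector<int> order;       // preorder of non-root A vertices, heavy first
  std::vector<int> posInOrder;  // -1 for root
  std::vector<int> subSize;     // non-root vertices per A subtree (incl self)
  std::vector<int> partner;     // A: -1 undecided, -2 unmatched, else B vertex
  std::vector<char> used;       // B side
  std::vector<int> aDec1, aDec2;
  std::vector<int> mpairA, mpairB;
  std::vector<int> bestA, bestB;
  double pairGapSum;
  double best;
  double tol;
  double nodeCount, maxNodes;
  bool aborted;
  // scratch
  std::vector<int> rowsL, colsL;
  std::vector<double> capRow, capCol, lapCost;
  std::vector<int> mbRow;

  void build_order() {
    std::function<void(int)> visit = [&](int v) {
      if (v != A->root) order.push_back(v);
      std::vector<std::pair<double, int>> ks;
      for (int k : A->kids[v]) ks.push_back({-A->subw[k], k});
      std::sort(ks.begin(), ks.end());
      for (auto& p : ks) visit(p.second);
    };
    visit(A->root);
    posInOrder.assign(A->n, -1);
    for (size_t i = 0; i < order.size(); ++i) posInOrder[order[i]] = (int)i;
    subSize.assign(A->n, 0);
    std::function<int(int)> cnt = [&](int v) {
      int s = (v == A->root) ? 0 : 1;
      for (int k : A->kids[v]) s += cnt(k);
      subSize[v] = s;
      return s;
    };
    cnt(A->root);
  }

  int nearest_matched_anc_A(int a) {
    int u = A->par[a];
    while (u != A->root && partner[u] < 0) u = A->par[u];
    return u;
  }
  double chainA(int a, int stop) {
    double s = 0.0;
    for (int u = A->par[a]; u != stop; u = A->par[u]) s += A->w[u];
    return s;
  }
  double chainB(int b, int stop) {
    double s = 0.0;
    for (int u = B->par[b]; u != stop && u != B->root && !used[u]; u = B->par[u])
      s += B->w[u];
    return s;
  }

  double pruneAt;  // current pruning threshold (best - tol - eps)

  double lower_bound(int i) {
    double D1 = 0.0, D2 = 0.0;
    rowsL.clear();
    colsL.clear();
    for (int u = 0; u < A->n; ++u) {
      if (u == A->root) continue;
      if (partner[u] == -2) {
        if (aDec1[u] >= 2) D1 += A->w[u];
        else if (aDec1[u] == 0 && posInOrder[u] + subSize[u] <= i) D1 += A->w[u];
      } else if (partner[u] == -1 && A->isLeaf[u]) {
        rowsL.push_back(u);
      }
    }
    for (int u = 0; u < B->n; ++u) {
      if (u == B->root || used[u]) continue;
      if (aDec2[u] >= 2) D2 += B->w[u];
      else if (aDec2[u] == 0 && B->isLeaf[u]) colsL.push_back(u);
    }
    double glob = std::abs((A->total - D1) - (B->total - D2));
    // staged evaluation: if the cheap part already prunes, skip the LAP
    double cheap = D1 + D2 + std::max(glob, pairGapSum);
    if (cheap >= pruneAt) return cheap;

    // joint leaf assignment
    int nr = (int)rowsL.size(), nc = (int)colsL.size();
    double J = 0.0;
    if (nr + nc > 0) {
      capRow.resize(nr);
      mbRow.resize(nr);
      for (int r = 0; r < nr; ++r) {
        int a = rowsL[r];
        int ma = nearest_matched_anc_A(a);
        capRow[r] = A->w[a] + chainA(a, ma);
        mbRow[r] = (ma == A->root) ? B->root : partner[ma];
      }
      capCol.resize(nc);
      for (int c = 0; c < nc; ++c) capCol[c] = B->w[colsL[c]] + chainB(colsL[c], -1);
      // escape lanes: cheapest admissible match against an internal vertex
      std::vector<double> escRow(nr), escCol(nc);
      for (int r = 0; r < nr; ++r) {
        int a = rowsL[r];
        double e = A->w[a];
        for (int y = 0; y < B->n && e > 1e-15; ++y) {
          if (y == B->root || used[y] || B->isLeaf[y] || aDec2[y] != 0) continue;
          if (!B->is_anc(mbRow[r], y)) continue;
          double capY = B->w[y] + chainB(y, -1);
          double g = std::max(0.0, std::max(A->w[a] - capY, B->w[y] - capRow[r]));
          if (g < e) e = g;
        }
        escRow[r] = std::min(A->w[a], e);
      }
      for (int c = 0; c < nc; ++c) {
        int b = colsL[c];
        double e = B->w[b];
        for (size_t k = i; k < order.size() && e > 1e-15; ++k) {
          int x = order[k];
          if (A->isLeaf[x]) continue;
          int ma = nearest_matched_anc_A(x);
          int mb = (ma == A->root) ? B->root : partner[ma];
          if (!B->is_anc(mb, b)) continue;
          double capX = A->w[x] + chainA(x, ma);
          double g = std::max(0.0, std::max(B->w[b] - capX, A->w[x] - capCol[c]));
          if (g < e) e = g;
        }
        escCol[c] = std::min(B->w[b], e);
      }
      // square LAP of size nr + nc with per-row/col escape dummies
      int N = nr + nc;
      lapCost.assign((size_t)N * N, INF);
      for (int r = 0; r < nr; ++r) {
        int a = rowsL[r];
        for (int c = 0; c < nc; ++c) {
          int b = colsL[c];
          if (!B->is_anc(mbRow[r], b)) continue;
          lapCost[(size_t)r * N + c] = std::max(
              0.0, std::max(A->w[a] - capCol[c], B->w[b] - capRow[r]));
        }
        lapCost[(size_t)r * N + nc + r] = escRow[r];
      }
      for (int c = 0; c < nc; ++c) lapCost[(size_t)(nr + c) * N + c] = escCol[c];
      // unused dummies pair with each other for free
      for (int dr = 0; dr < nc; ++dr)
        for (int dc = 0; dc < nr; ++dc)
          lapCost[(size_t)(nr + dr) * N + nc + dc] = 0.0;
      J = solve_lap(N, lapCost);
    }

    double resid = std::max(glob, pairGapSum + J);
    return D1 + D2 + resid;
  }

  double evaluate() {
    double cost = 0.0;
    for (int u = 0; u < A->n; ++u) {
      if (u == A->root) continue;
      if (partner[u] < 0 && aDec1[u] != 1) cost += A->w[u];
    }
    for (int u = 0; u < B->n; ++u) {
      if (u == B->root) continue;
      if (!used[u] && aDec2[u] != 1) cost += B->w[u];
    }
    for (size_t k = 0; k < mpairA.size(); ++k) {
      int a = mpairA[k], b = mpairB[k];
      double Wa = A->w[a];
      for (int u = A->par[a]; u != A->root && partner[u] < 0; u = A->par[u])
        if (aDec1[u] == 1) Wa += A->w[u];
      double Wb = B->w[b];
      for (int u = B->par[b]; u != B->root && !used[u]; u = B->par[u])
        if (aDec2[u] == 1) Wb += B->w[u];
      cost += std::abs(Wa - Wb);
    }
    return cost;
  }

  void apply_pair(int a, int b, int ma, int mb) {
    partner[a] = b;
    used[b] = 1;
    for (int u = A->par[a]; u != ma; u = A->par[u]) aDec1[u] += 1;
    for (int u = B->par[b]; u != mb; u = B->par[u]) aDec2[u] += 1;
    mpairA.push_back(a);
    mpairB.push_back(b);
  }
  void undo_pair(int a, int b, int ma, int mb) {
    mpairA.pop_back();
    mpairB.pop_back();
    for (int u = A->par[a]; u != ma; u = A->par[u]) aDec1[u] -= 1;
    for (int u = B->par[b]; u != mb; u = B->par[u]) aDec2[u] -= 1;
    used[b] = 0;
    partner[a] = -1;
  }

  void greedy_descend(int a, int b) {
    std::vector<std::tuple<double, int, int>> cand;
    for (int i : A->kids[a])
      for (int j : B->kids[b])
        cand.push_back({std::abs(A->subw[i] - B->subw[j]) +
                            std::abs(A->w[i] - B->w[j]),
                        i, j});
    std::sort(cand.begin(), cand.end());
    std::vector<char> ua(A->n, 0), ub(B->n, 0);
    for (auto& c : cand) {
      int i = std::get<1>(c), j = std::get<2>(c);
      if (ua[i] || ub[j]) continue;
      ua[i] = ub[j] = 1;
      apply_pair(i, j, a == A->root ? A->root : a, b == B->root ? B->root : b);
      greedy_descend(i, j);
    }
  }

  void seed_incumbent() {
    greedy_descend(A->root, B->root);
    double c = evaluate();
    if (c < best) {
      best = c;
      bestA = mpairA;
      bestB = mpairB;
    }
    while (!mpairA.empty()) {
      int a = mpairA.back(), b = mpairB.back();
      int ma = nearest_matched_anc_excl(a);
      int mb = (ma == A->root) ? B->root : partner[ma];
      undo_pair(a, b, ma, mb);
    }
  }
  int nearest_matched_anc_excl(int a) {
    int u = A->par[a];
    while (u != A->root && partner[u] < 0) u = A->par[u];
    return u;
  }


  // ---- incumbent refinement: local search over explicit pair lists ----
  double eval_pairs(const std::vector<int>& pa, const std::vector<int>& pb) {
    std::vector<char> m1(A->n, 0), m2(B->n, 0);
    for (size_t k = 0; k < pa.size(); ++k) {
      m1[pa[k]] = 1;
      m2[pb[k]] = 1;
    }
    std::vector<int> f1(A->n, 0), f2(B->n, 0);
    for (size_t k = 0; k < pa.size(); ++k) {
      for (int u = A->par[pa[k]]; u != A->root && !m1[u]; u = A->par[u]) f1[u] += 1;
      for (int u = B->par[pb[k]]; u != B->root && !m2[u]; u = B->par[u]) f2[u] += 1;
    }
    double cost = 0.0;
    for (int u = 0; u < A->n; ++u)
      if (u != A->root && !m1[u] && f1[u] != 1) cost += A->w[u];
    for (int u = 0; u < B->n; ++u)
      if (u != B->root && !m2[u] && f2[u] != 1) cost += B->w[u];
    for (size_t k = 0; k < pa.size(); ++k) {
      double Wa = A->w[pa[k]];
      for (int u = A->par[pa[k]]; u != A->root && !m1[u]; u = A->par[u])
        if (f1[u] == 1) Wa += A->w[u];
      double Wb = B->w[pb[k]];
      for (int u = B->par[pb[k]]; u != B->root && !m2[u]; u = B->par[u])
        if (f2[u] == 1) Wb += B->w[u];
      cost += std::abs(Wa - Wb);
    }
    return cost;
  }

  bool pairs_feasible(const std::vector<int>& pa, const std::vector<int>& pb,
                      int a, int b) {
    for (size_t k = 0; k < pa.size(); ++k) {
      if (pa[k] == a || pb[k] == b) return false;
      if (A->is_anc(pa[k], a) != B->is_anc(pb[k], b)) return false;
      if (A->is_anc(a, pa[k]) != B->is_anc(b, pb[k])) return false;
    }
    return true;
  }

  void local_search() {
    if (A->n + B->n < 16) return;
    std::vector<int> pa = bestA, pb = bestB;
    double cur = best;
    for (int iter = 0; iter < 80; ++iter) {
      double bestDelta = -1e-12;
      int mvKind = -1, mvIdx = -1, mvA = -1, mvB = -1;
      // move 1: drop a pair
      for (size_t k = 0; k < pa.size(); ++k) {
        std::vector<int> qa = pa, qb = pb;
        qa.erase(qa.begin() + k);
        qb.erase(qb.begin() + k);
        double c = eval_pairs(qa, qb);
        if (c - cur < bestDelta) {
          bestDelta = c - cur;
          mvKind = 0;
          mvIdx = (int)k;
        }
      }
      // move 2: rematch one side of a pair
      for (size_t k = 0; k < pa.size(); ++k) {
        std::vector<int> qa = pa, qb = pb;
        int a0 = qa[k], b0 = qb[k];
        qa.erase(qa.begin() + k);
        qb.erase(qb.begin() + k);
        for (int b = 0; b < B->n; ++b) {
          if (b == B->root || b == b0) continue;
          if (!pairs_feasible(qa, qb, a0, b)) continue;
          qa.push_back(a0);
          qb.push_back(b);
          double c = eval_pairs(qa, qb);
          qa.pop_back();
          qb.pop_back();
          if (c - cur < bestDelta) {
            bestDelta = c - cur;
            mvKind = 1;
            mvIdx = (int)k;
            mvA = a0;
            mvB = b;
          }
        }
        for (int a = 0; a < A->n; ++a) {
          if (a == A->root || a == a0) continue;
          if (!pairs_feasible(qa, qb, a, b0)) continue;
          qa.push_back(a);
          qb.push_back(b0);
          double c = eval_pairs(qa, qb);
          qa.pop_back();
          qb.pop_back();
          if (c - cur < bestDelta) {
            bestDelta = c - cur;
            mvKind = 2;
            mvIdx = (int)k;
            mvA = a;
            mvB = b0;
          }
        }
      }
      // move 3: add a new pair
      for (int a = 0; a < A->n; ++a) {
        if (a == A->root) continue;
        bool usedA = false;
        for (int x : pa)
          if (x == a) { usedA = true; break; }
        if (usedA) continue;
        for (int b = 0; b < B->n; ++b) {
          if (b == B->root) continue;
          if (!pairs_feasible(pa, pb, a, b)) continue;
          pa.push_back(a);
          pb.push_back(b);
          double c = eval_pairs(pa, pb);
          pa.pop_back();
          pb.pop_back();
          if (c - cur < bestDelta) {
            bestDelta = c - cur;
            mvKind = 3;
            mvA = a;
            mvB = b;
          }
        }
      }
      if (mvKind < 0) break;
      if (mvKind == 0) {
        pa.erase(pa.begin() + mvIdx);
        pb.erase(pb.begin() + mvIdx);
      } else if (mvKind == 1 || mvKind == 2) {
        pa.erase(pa.begin() + mvIdx);
        pb.erase(pb.begin() + mvIdx);
        pa.push_back(mvA);
        pb.push_back(mvB);
      } else {
        pa.push_back(mvA);
        pb.push_back(mvB);
      }
      cur += bestDelta;
    }
    if (cur < best) {
      best = cur;
      bestA = pa;
      bestB = pb;
    }
  }

  void dfs(int i) {
    if (aborted) return;
    nodeCount += 1.0;
    if (nodeCount > maxNodes) {
      aborted = true;
      return;
    }
    if ((size_t)i == order.size()) {
      double c = evaluate();
      if (c < best) {
        best = c;
        bestA = mpairA;
        bestB = mpairB;
      }
      return;
    }
    pruneAt = best - tol - 1e-12;
    if (lower_bound(i) >= pruneAt) return;

    int a = order[i];
    int ma = nearest_matched_anc_A(a);
    int mb = (ma == A->root) ? B->root : partner[ma];
    double pwA = chainA(a, ma);

    std::vector<std::pair<double, int>> cands;
    std::vector<long long> seen;
    for (int b = 0; b < B->n; ++b) {
      if (b == B->root || used[b]) continue;
      if (aDec2[b] != 0) continue;  // can no longer be matched
      if (!B->is_anc(mb, b)) continue;
      bool ok = true;
      for (size_t k = 0; k < mpairA.size() && ok; ++k) {
        int x = mpairA[k], y = mpairB[k];
        if (A->is_anc(x, a) != B->is_anc(y, b)) ok = false;
        else if (B->is_anc(b, y)) ok = false;  // a is never an ancestor of x
      }
      if (!ok) continue;
      long long key = (long long)(B->par[b] + 1) * (B->n + 1) + B->shapeId[b];
      bool dup = false;
      for (long long s : seen)
        if (s == key) {
          dup = true;
          break;
        }
      if (dup) continue;
      seen.push_back(key);
      cands.push_back({std::abs(A->w[a] - B->w[b]) +
                           0.25 * std::abs(A->subw[a] - B->subw[b]),
                       b});
    }
    std::sort(cands.begin(), cands.end());

    for (auto& cb : cands) {
      int b = cb.second;
      double pwB = chainB(b, mb);
      double gap = std::max(
          0.0, std::max(A->w[a] - (B->w[b] + pwB), B->w[b] - (A->w[a] + pwA)));
      apply_pair(a, b, ma, mb);
      pairGapSum += gap;
      dfs(i + 1);
      pairGapSum -= gap;
      undo_pair(a, b, ma, mb);
      if (aborted) return;
    }

    partner[a] = -2;
    dfs(i + 1);
    partner[a] = -1;
  }
};

}  // namespace

// [[Rcpp::export]]
List edit_distance_bb(IntegerVector par1, NumericVector w1, IntegerVector par2,
                      NumericVector w2, double max_nodes, double tol = 0.0) {
  Tree A = build_tree(par1, w1);
  Tree B = build_tree(par2, w2);
  if (A.root < 0 || B.root < 0) stop("Both trees must have a root.");

  Search s;
  s.A = &A;
  s.B = &B;
  s.partner.assign(A.n, -1);
  s.partner[A.root] = B.root;
  s.used.assign(B.n, 0);
  s.used[B.root] = 1;
  s.aDec1.assign(A.n, 0);
  s.aDec2.assign(B.n, 0);
  s.pairGapSum = 0.0;
  s.best = A.total + B.total;  // the empty mapping is always valid
  s.tol = tol;
  s.nodeCount = 0.0;
  s.maxNodes = max_nodes;
  s.aborted = false;
  s.build_order();
  s.seed_incumbent();
  s.local_search();
  s.dfs(0);

  IntegerMatrix mp(s.bestA.size(), 2);
  for (size_t k = 0; k < s.bestA.size(); ++k) {
    mp(k, 0) = s.bestA[k] + 1;
    mp(k, 1) = s.bestB[k] + 1;
  }
  return List::create(
      Named("distance") = s.best,
      Named("lower") = s.aborted ? std::abs(A.total - B.total) : s.best,
      Named("status") = s.aborted ? 1 : 0,
      Named("nodes") = s.nodeCount,
      Named("mapping") = mp);
}
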