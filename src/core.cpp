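#include <Rcpp.h>
#include <cstdint>
#include <cfloat>
#include <cmath>
#include <vector>
#include <array>
#include <algorithm>

using namespace Rcpp;

namespace {

// Sentinel for "state unreachable" in Sankoff leaf vectors.  Internal node
// vectors never inherit it (a min over a child vector is always attained at
// an observed state), so additions cannot overflow 32-bit ints.
const int BIG = 100000000;

// Unrooted binary tree as an adjacency table: nodes 0..nnode-1, tips are
// 0..ntip-1 (tip i carries taxon i+1), internal nodes have three neighbour
// slots, unused slots / inactive nodes hold -1.
struct AdjTree {
  int nnode, ntip;
  std::vector<int> nb; // 3*nnode

  int deg(int v) const {
    int d = 0;
    for (int j = 0; j < 3; ++j) if (nb[3*v+j] >= 0) ++d;
    return d;
  }
  void replace_nb(int v, int oldu, int newu) {
    for (int j = 0; j < 3; ++j)
      if (nb[3*v+j] == oldu) { nb[3*v+j] = newu; return; }
    stop("internal error: neighbour not found");
  }
};

AdjTree tree_from_R(const IntegerMatrix& m, int ntip) {
  AdjTree t;
  t.nnode = m.nrow();
  t.ntip = ntip;
  t.nb.assign(3*t.nnode, -1);
  for (int i = 0; i < t.nnode; ++i)
    for (int j = 0; j < 3; ++j)
      t.nb[3*i+j] = m(i, j) - 1; // R uses 0 for empty, 1-based ids
  return t;
}

IntegerMatrix tree_to_R(const AdjTree& t) {
  IntegerMatrix m(t.nnode, 3);
  for (int i = 0; i < t.nnode; ++i)
    for (int j = 0; j < 3; ++j)
      m(i, j) = t.nb[3*i+j] + 1;
  return m;
}

// Reverse DFS preorder from `root` = children-before-parents ordering.
void postorder(const AdjTree& t, int root,
               std::vector<int>& order, std::vector<int>& parent) {
  order.clear();
  parent.assign(t.nnode, -2);
  std::vector<int> st, pre;
  st.reserve(t.nnode); pre.reserve(t.nnode);
  st.push_back(root);
  parent[root] = -1;
  while (!st.empty()) {
    int v = st.back(); st.pop_back();
    pre.push_back(v);
    for (int j = 0; j < 3; ++j) {
      int u = t.nb[3*v+j];
      if (u >= 0 && u != parent[v]) { parent[u] = v; st.push_back(u); }
    }
  }
  order.assign(pre.rbegin(), pre.rend());
}

// Fitch set algorithm for one pattern, rooted at leaf order.back().
// pat[v] in 0..S, 0 = missing (full state set).
int fitch_one(const AdjTree& t, const std::vector<int>& order,
              const std::vector<int>& parent, const int* pat,
              uint32_t full, std::vector<uint32_t>& W) {
  int changes = 0;
  int root = order.back();
  int nord = (int) order.size();
  for (int oi = 0; oi < nord - 1; ++oi) {
    int v = order[oi];
    if (v < t.ntip) {
      int c = pat[v];
      W[v] = (c == 0) ? full : (1u << (c - 1));
    } else {
      uint32_t acc = 0;
      bool first = true;
      for (int j = 0; j < 3; ++j) {
        int u = t.nb[3*v+j];
        if (u < 0 || u == parent[v]) continue;
        if (first) { acc = W[u]; first = false; }
        else {
          uint32_t in = acc & W[u];
          if (in) acc = in; else { acc |= W[u]; ++changes; }
        }
      }
      W[v] = acc;
    }
  }
  int c = pat[root];
  uint32_t rm = (c == 0) ? full : (1u << (c - 1));
  int child = -1;
  for (int j = 0; j < 3; ++j)
    if (t.nb[3*root+j] >= 0) { child = t.nb[3*root+j]; break; }
  if (!(rm & W[child])) ++changes;
  return changes;
}

// Sankoff dynamic program for one pattern under an S x S step matrix
// (row-major in `cost`), rooted at leaf order.back().
int sankoff_one(const AdjTree& t, const std::vector<int>& order,
                const std::vector<int>& parent, const int* pat,
                const int* cost, int S, std::vector<int>& V) {
  int root = order.back();
  int nord = (int) order.size();
  for (int oi = 0; oi < nord - 1; ++oi) {
    int v = order[oi];
    int* Vv = &V[(size_t) v * S];
    if (v < t.ntip) {
      int c = pat[v];
      if (c == 0) { for (int a = 0; a < S; ++a) Vv[a] = 0; }
      else { for (int a = 0; a < S; ++a) Vv[a] = BIG; Vv[c-1] = 0; }
    } else {
      for (int a = 0; a < S; ++a) Vv[a] = 0;
      for (int j = 0; j < 3; ++j) {
        int u = t.nb[3*v+j];
        if (u < 0 || u == parent[v]) continue;
        const int* Vu = &V[(size_t) u * S];
        for (int a = 0; a < S; ++a) {
          const int* ca = &cost[(size_t) a * S];
          int best = BIG;
          for (int b = 0; b < S; ++b) {
            int x = ca[b] + Vu[b];
            if (x < best) best = x;
          }
          Vv[a] += best;
        }
      }
    }
  }
  int c = pat[root];
  int child = -1;
  for (int j = 0; j < 3; ++j)
    if (t.nb[3*root+j] >= 0) { child = t.nb[3*root+j]; break; }
  const int* Vu = &V[(size_t) child * S];
  int ans = BIG;
  for (int a = 0; a < S; ++a) {
    if (c != 0 && a != c - 1) continue;
    const int* ca = &cost[(size_t) a * S];
    int best = BIG;
    for (int b = 0; b < S; ++b) {
      int x = ca[b] + Vu[b];
      if (x < best) best = x;
    }
    if (best < ans) ans = best;
  }
  return ans;
}

IntegerVector score_all(const AdjTree& t, const IntegerMatrix& pat,
                        const IntegerMatrix& cost, bool uniform, int root) {
  std::vector<int> order, parent;
  postorder(t, root, order, parent);
  int k = pat.ncol(), S = cost.nrow(), ntip = pat.nrow();
  const int* pp = INTEGER(pat);
  IntegerVector out(k);
  if (uniform) {
    uint32_t full = (S >= 32) ? 0xffffffffu : ((1u << S) - 1u);
    std::vector<uint32_t> W(t.nnode);
    for (int i = 0; i < k; ++i)
      out[i] = fitch_one(t, order, parent, pp + (size_t) i * ntip, full, W);
  } else {
    std::vector<int> cc((size_t) S * S);
    for (int a = 0; a < S; ++a)
      for (int b = 0; b < S; ++b)
        cc[(size_t) a * S + b] = cost(a, b);
    std::vector<int> V((size_t) t.nnode * S);
    for (int i = 0; i < k; ++i)
      out[i] = sankoff_one(t, order, parent, pp + (size_t) i * ntip,
                           cc.data(), S, V);
  }
  return out;
}

double dot_iw(const IntegerVector& s, const NumericVector& w) {
  double tot = 0;
  for (int i = 0; i < s.size(); ++i) tot += (double) s[i] * w[i];
  return tot;
}

// Enumerate SPR moves: prune the subtree on the `s` side of edge (p, s)
// (p internal), smooth p out, regraft onto edge {a, b} of the remainder.
// `dist` = number of nodes on the path between the original attachment
// edge {x, y} and the regraft edge (adjacent edges -> 1).  The regraft
// edge {x, y} itself (identity move) is never produced.
void spr_moves_of(const AdjTree& t, int radius,
                  std::vector<std::array<int,5> >& out) {
  std::vector<int> dn(t.nnode);
  std::vector<int> queue;
  queue.reserve(t.nnode);
  for (int s = 0; s < t.nnode; ++s) {
    if (t.deg(s) == 0) continue;
    for (int jp = 0; jp < 3; ++jp) {
      int p = t.nb[3*s+jp];
      if (p < 0 || t.deg(p) != 3) continue;
      int x = -1, y = -1;
      for (int j = 0; j < 3; ++j) {
        int u = t.nb[3*p+j];
        if (u != s) { if (x < 0) x = u; else y = u; }
      }
      std::fill(dn.begin(), dn.end(), -1);
      queue.clear();
      dn[x] = 0; dn[y] = 0;
      queue.push_back(x); queue.push_back(y);
      for (size_t qi = 0; qi < queue.size(); ++qi) {
        int v = queue[qi];
        for (int j = 0; j < 3; ++j) {
          int u = t.nb[3*v+j];
          if (u < 0 || u == p || dn[u] >= 0) continue;
          int dist = dn[v] + 1;
          dn[u] = dist;
          queue.push_back(u);
          if (dist <= radius)
            out.push_back({{p, s, v, u, dist}});
        }
      }
    }
  }
}

void apply_spr(AdjTree& t, int p, int s, int a, int b) {
  int x = -1, y = -1;
  for (int j = 0; j < 3; ++j) {
    int u = t.nb[3*p+j];
    if (u != s) { if (x < 0) x = u; else y = u; }
  }
  t.replace_nb(x, p, y);
  t.replace_nb(y, p, x);
  t.replace_nb(a, b, p);
  t.replace_nb(b, a, p);
  t.nb[3*p+0] = s; t.nb[3*p+1] = a; t.nb[3*p+2] = b;
}

} // namespace

// [[Rcpp::export]]
IntegerVector c_score_tree(IntegerMatrix nb, int ntip, IntegerMatrix pat,
                           IntegerMatrix cost, bool uniform, int root) {
  AdjTree t = tree_from_R(nb, ntip);
  return score_all(t, pat, cost, uniform, root - 1);
}

// [[Rcpp::export]]
IntegerMatrix c_spr_moves(IntegerMatrix nb, int ntip, int radius) {
  AdjTree t = tree_from_R(nb, ntip);
  std::vector<std::array<int,5> > mv;
  spr_moves_of(t, radius, mv);
  IntegerMatrix out((int) mv.size(), 5);
  for (size_t i = 0; i < mv.size(); ++i) {
    out(i, 0) = mv[i][0] + 1;
    out(i, 1) = mv[i][1] + 1;
    out(i, 2) = mv[i][2] + 1;
    out(i, 3) = mv[i][3] + 1;
    out(i, 4) = mv[i][4];
  }
  colnames(out) = CharacterVector::create("p", "s", "a", "b", "dist");
  return out;
}

// [[Rcpp::export]]
IntegerMatrix c_apply_spr(IntegerMatrix nb, int ntip, int p, int s,
                          int a, int b) {
  AdjTree t = tree_from_R(nb, ntip);
  apply_spr(t, p - 1, s - 1, a - 1, b - 1);
  return tree_to_R(t);
}

// Best-improvement SPR hill climbing on the weighted pattern total.
// Returns the local optimum plus every accepted intermediate tree with its
// per-pattern score vector (the final tree is the last accepted one).
// [[Rcpp::export]]
List c_hill_climb(IntegerMatrix nb, int ntip, IntegerMatrix pat,
                  IntegerMatrix cost, bool uniform, NumericVector w,
                  int radius) {
  AdjTree cur = tree_from_R(nb, ntip);
  IntegerVector sc = score_all(cur, pat, cost, uniform, 0);
  double tot = dot_iw(sc, w);
  IntegerVector start_sc = clone(sc);
  double start_tot = tot;
  List vtrees, vscores;
  std::vector<double> vtot;
  std::vector<std::array<int,5> > moves;
  while (true) {
    moves.clear();
    spr_moves_of(cur, radius, moves);
    double best = tot;
    bool found = false;
    AdjTree bestT;
    IntegerVector bestS;
    for (size_t i = 0; i < moves.size(); ++i) {
      AdjTree cand = cur;
      apply_spr(cand, moves[i][0], moves[i][1], moves[i][2], moves[i][3]);
      IntegerVector s2 = score_all(cand, pat, cost, uniform, 0);
      double t2 = dot_iw(s2, w);
      if (t2 < best) { best = t2; bestT = cand; bestS = s2; found = true; }
    }
    if (!found) break;
    cur = bestT; sc = bestS; tot = best;
    vtrees.push_back(tree_to_R(cur));
    vscores.push_back(sc);
    vtot.push_back(tot);
    Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["tree"] = tree_to_R(cur), _["scores"] = sc, _["total"] = tot,
    _["start_scores"] = start_sc, _["start_total"] = start_tot,
    _["visited"] = vtrees, _["visited_scores"] = vscores,
    _["visited_totals"] = wrap(vtot));
}

// Randomized stepwise addition: taxa inserted in the given order, each new
// taxon attached to the edge minimizing the weighted parsimony total, ties
// broken uniformly at random (R's RNG stream).
// [[Rcpp::export]]
IntegerMatrix c_stepwise_addition(int ntip, IntegerMatrix pat,
                                  IntegerMatrix cost, bool uniform,
                                  NumericVector w, IntegerVector order0) {
  if (ntip < 4) stop("need at least 4 taxa");
  int nnode = 2 * ntip - 2;
  AdjTree t;
  t.nnode = nnode; t.ntip = ntip;
  t.nb.assign(3 * nnode, -1);
  std::vector<int> ord(ntip);
  for (int i = 0; i < ntip; ++i) ord[i] = order0[i] - 1;
  int c0 = ntip; // first internal node: star over the first three taxa
  for (int i = 0; i < 3; ++i) {
    t.nb[3*c0+i] = ord[i];
    t.nb[3*ord[i]+0] = c0;
  }
  int root = ord[0];
  for (int j = 3; j < ntip; ++j) {
    int tip = ord[j];
    int q = ntip + (j - 2);
    std::vector<std::pair<int,int> > edges;
    for (int v = 0; v < nnode; ++v)
      for (int sl = 0; sl < 3; ++sl) {
        int u = t.nb[3*v+sl];
        if (u > v) edges.push_back(std::make_pair(v, u));
      }
    double best = DBL_MAX;
    std::vector<int> ties;
    for (size_t e = 0; e < edges.size(); ++e) {
      int a = edges[e].first, b = edges[e].second;
      t.replace_nb(a, b, q);
      t.replace_nb(b, a, q);
      t.nb[3*q+0] = tip; t.nb[3*q+1] = a; t.nb[3*q+2] = b;
      t.nb[3*tip+0] = q;
      IntegerVector s = score_all(t, pat, cost, uniform, root);
      double tt = dot_iw(s, w);
      if (tt < best) { best = tt; ties.clear(); ties.push_back((int) e); }
      else if (tt == best) ties.push_back((int) e);
      t.replace_nb(a, q, b);
      t.replace_nb(b, q, a);
      t.nb[3*q+0] = t.nb[3*q+1] = t.nb[3*q+2] = -1;
      t.nb[3*tip+0] = -1;
    }
    int pi = (int) std::floor(R::unif_rand() * ties.size());
    if (pi >= (int) ties.size()) pi = (int) ties.size() - 1;
    int a = edges[ties[pi]].first, b = edges[ties[pi]].second;
    t.replace_nb(a, b, q);
    t.replace_nb(b, a, q);
    t.nb[3*q+0] = tip; t.nb[3*q+1] = a; t.nb[3*q+2] = b;
    t.nb[3*tip+0] = q;
  }
  return tree_to_R(t);
}

// Offer one tree (its per-pattern scores on the original alignment) to all
// bootstrap replicates.  W is the k x B matrix of resampled pattern weights.
// With use_abort the scan follows `ord` (descending first-tree scores) and
// stops as soon as   sum_{i<=j} s_i w_i + sum_{i>j} bound_i w_i  exceeds the
// replicate's incumbent score; minbw[b] = sum_i bound_i W[i,b] is passed in.
// [[Rcpp::export]]
List c_reps_offer(IntegerVector scores, IntegerMatrix W, IntegerVector ord,
                  IntegerVector bounds, NumericVector minbw,
                  NumericVector best, bool use_abort) {
  int k = scores.size(), B = W.ncol();
  NumericVector newbest = clone(best);
  LogicalVector improved(B);
  for (int b = 0; b < B; ++b) {
    const int* wb = &W[(size_t) b * k];
    if (use_abort) {
      double acc = 0;
      bool aborted = false;
      for (int jj = 0; jj < k; ++jj) {
        int i = ord[jj] - 1;
        acc += (double) (scores[i] - bounds[i]) * wb[i];
        if (minbw[b] + acc > best[b]) { aborted = true; break; }
      }
      if (!aborted) {
        double exact = minbw[b] + acc;
        if (exact < newbest[b]) { newbest[b] = exact; improved[b] = true; }
      }
    } else {
      double exact = 0;
      for (int i = 0; i < k; ++i) exact += (double) scores[i] * wb[i];
      if (exact < newbest[b]) { newbest[b] = exact; improved[b] = true; }
    }
  }
  return List::create(_["best"] = newbest, _["improved"] = improved);
}
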