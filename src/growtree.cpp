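// Core tree growth for inverse-variance weighted meta-analytic regression
// trees.  Two growers share the candidate-split machinery:
//   * fixed-effect (FE): best-first recursive partitioning, each split
//     minimises Q_left + Q_right in its node (equivalently maximises the
//     local between-subgroups Q);
//   * random-effects (RE): sequential partitioning, each candidate split is
//     scored by the whole-tree Q*_B after re-pooling the DerSimonian-Laird
//     residual heterogeneity for the resulting partition.
// Moderators arrive as a numeric matrix; kind 0 = ordered (continuous,
// ordinal, binary; threshold splits at observed midpoints), kind 1 = nominal
// (level codes 1..L; all proper bipartitions of the observed levels).
// Tie-breaks are deterministic: better score, else lower node id, lower
// moderator index, lower threshold / earlier subset in enumeration order.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Cand {
  bool ok = false;
  int var = -1;        // 0-based
  int kind = 0;
  double thresh = 0.0;
  uint64_t lmask = 0;  // nominal: bit l set -> level code l goes left
  double childQ = 0.0; // Q_left + Q_right
  int nl = 0, nr = 0;
};

struct Term {
  int id;                    // CART node id (root 1, children 2i, 2i+1)
  std::vector<int> mem;      // 0-based study indices
  double sw, swd, swd2, sw2; // FE weight sums
  double Q, C;               // within-node Q, DL C component
  Cand best;
  bool best_done = false;
};

inline double qof(double sw, double swd, double swd2) {
  double q = swd2 - swd * swd / sw;
  return q > 0.0 ? q : 0.0;
}

void node_stats(Term &t, const NumericVector &d, const NumericVector &v) {
  t.sw = t.swd = t.swd2 = t.sw2 = 0.0;
  for (int k : t.mem) {
    double w = 1.0 / v[k];
    t.sw += w;
    t.swd += w * d[k];
    t.swd2 += w * d[k] * d[k];
    t.sw2 += w * w;
  }
  t.Q = qof(t.sw, t.swd, t.swd2);
  t.C = t.sw - t.sw2 / t.sw;
}

// Enumerate candidate splits of `mem` on moderator `var`, calling
// fn(thresh, lmask, nl, nr, Ql, Qr, Cl, Cr) for each admissible one, in the
// deterministic order used for tie-breaking.
template <typename F>
void for_candidates(const std::vector<int> &mem, int var, int kd,
                    const NumericVector &d, const NumericVector &v,
                    const NumericMatrix &X, int minbucket, F fn) {
  const int n = (int)mem.size();
  if (n < 2 * minbucket) return;
  if (kd == 0) { // ordered: thresholds at midpoints of consecutive values
    std::vector<int> ord(mem);
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      double xa = X(a, var), xb = X(b, var);
      if (xa != xb) return xa < xb;
      return a < b;
    });
    double swl = 0, swdl = 0, swd2l = 0, sw2l = 0;
    double swt = 0, swdt = 0, swd2t = 0, sw2t = 0;
    for (int k : mem) {
      double w = 1.0 / v[k];
      swt += w; swdt += w * d[k]; swd2t += w * d[k] * d[k]; sw2t += w * w;
    }
    for (int i = 0; i < n - 1; ++i) {
      int k = ord[i];
      double w = 1.0 / v[k];
      swl += w; swdl += w * d[k]; swd2l += w * d[k] * d[k]; sw2l += w * w;
      double xlo = X(ord[i], var), xhi = X(ord[i + 1], var);
      if (!(xlo < xhi)) continue;
      int nl = i + 1, nr = n - nl;
      if (nl < minbucket || nr < minbucket) continue;
      double swr = swt - swl, swdr = swdt - swdl, swd2r = swd2t - swd2l,
             sw2r = sw2t - sw2l;
      fn((xlo + xhi) / 2.0, (uint64_t)0, nl, nr,
         qof(swl, swdl, swd2l), qof(swr, swdr, swd2r),
         swl - sw2l / swl, swr - sw2r / swr);
    }
  } else { // nominal: proper bipartitions of observed levels
    const int MAXLEV = 32;
    double lsw[MAXLEV] = {0}, lswd[MAXLEV] = {0}, lswd2[MAXLEV] = {0},
           lsw2[MAXLEV] = {0};
    int lcnt[MAXLEV] = {0};
    for (int k : mem) {
      int lv = (int)X(k, var);
      double w = 1.0 / v[k];
      lcnt[lv]++; lsw[lv] += w; lswd[lv] += w * d[k];
      lswd2[lv] += w * d[k] * d[k]; lsw2[lv] += w * w;
    }
    std::vector<int> pres;
    for (int l = 0; l < MAXLEV; ++l) if (lcnt[l] > 0) pres.push_back(l);
    const int L = (int)pres.size();
    if (L < 2) return;
    double swt = 0, swdt = 0, swd2t = 0, sw2t = 0;
    for (int l : pres) { swt += lsw[l]; swdt += lswd[l]; swd2t += lswd2[l]; sw2t += lsw2[l]; }
    // left set always contains the lowest observed level -> each bipartition once
    uint64_t nsub = ((uint64_t)1 << (L - 1)) - 1;
    for (uint64_t sub = 0; sub < nsub; ++sub) {
      uint64_t lmask = (uint64_t)1 << pres[0];
      int nl = lcnt[pres[0]];
      double swl = lsw[pres[0]], swdl = lswd[pres[0]],
             swd2l = lswd2[pres[0]], sw2l = lsw2[pres[0]];
      for (int j = 0; j < L - 1; ++j)
        if (sub & ((uint64_t)1 << j)) {
          int l = pres[j + 1];
          lmask |= (uint64_t)1 << l;
          nl += lcnt[l]; swl += lsw[l]; swdl += lswd[l];
          swd2l += lswd2[l]; sw2l += lsw2[l];
        }
      int nr = n - nl;
      if (nl < minbucket || nr < minbucket) continue;
      double swr = swt - swl, swdr = swdt - swdl, swd2r = swd2t - swd2l,
             sw2r = sw2t - sw2l;
      fn(0.0, lmask, nl, nr,
         qof(swl, swdl, swd2l), qof(swr, swdr, swd2r),
         swl - sw2l / swl, swr - sw2r / swr);
    }
  }
}

Cand best_fe_split(const Term &t, const NumericVector &d,
                   const NumericVector &v, const NumericMatrix &X,
                   const IntegerVector &kind, int minbucket) {
  Cand best;
  const int M = X.ncol();
  for (int m = 0; m < M; ++m) {
    for_candidates(t.mem, m, kind[m], d, v, X, minbucket,
      [&](double thresh, uint64_t lmask, int nl, int nr, double Ql, double Qr,
          double, double) {
        double cq = Ql + Qr;
        if (!best.ok || cq < best.childQ) {
          best.ok = true; best.var = m; best.kind = kind[m];
          best.thresh = thresh; best.lmask = lmask;
          best.childQ = cq; best.nl = nl; best.nr = nr;
        }
      });
  }
  return best;
}

inline bool goes_left(const NumericMatrix &X, int k, const Cand &c) {
  if (c.kind == 0) return X(k, c.var) <= c.thresh;
  return (c.lmask >> (int)X(k, c.var)) & 1;
}

} // namespace

// [[Rcpp::export]]
List cpp_grow(NumericVector d, NumericVector v, NumericMatrix X,
              IntegerVector kind, int minbucket, int maxL, bool re) {
  const int K = d.size();
  const int M = X.ncol();

  std::vector<Term> terms;
  Term root; root.id = 1;
  root.mem.resize(K);
  for (int k = 0; k < K; ++k) root.mem[k] = k;
  node_stats(root, d, v);
  terms.push_back(root);

  // node records, creation order
  std::vector<int> n_id{1}, n_parent{0}, n_n{K};
  std::vector<double> n_Q{root.Q}, n_mean{root.swd / root.sw}, n_sw{root.sw};

  // split records
  std::vector<int> s_node, s_var, s_kind, s_nl, s_nr;
  std::vector<double> s_thresh, s_score, s_tau2;
  std::vector<std::vector<int>> s_left, s_right;

  IntegerMatrix memb(K, maxL); // column s = labels after s splits
  for (int k = 0; k < K; ++k) memb(k, 0) = 1;

  std::vector<int> gidx(K, 0); // study -> index in terms
  double Qsum = root.Q, Csum = root.C;

  while ((int)terms.size() < maxL) {
    int J = (int)terms.size();
    int pick = -1;
    Cand pickc;
    double pickscore = 0.0, picktau2 = 0.0;
    bool have = false;

    // iterate candidate parents in increasing node id (tie-break order)
    std::vector<int> order(J);
    for (int j = 0; j < J; ++j) order[j] = j;
    std::sort(order.begin(), order.end(),
              [&](int a, int b) { return terms[a].id < terms[b].id; });

    if (!re) {
      for (int j : order) {
        Term &t = terms[j];
        if (!t.best_done) { t.best = best_fe_split(t, d, v, X, kind, minbucket); t.best_done = true; }
        if (!t.best.ok) continue;
        double gain = t.Q - t.best.childQ; // local between-subgroups Q
        if (!have || gain > pickscore) {
          have = true; pick = j; pickc = t.best; pickscore = gain;
        }
      }
    } else {
      const double *dd = d.begin(), *vv = v.begin();
      for (int j : order) {
        Term &t = terms[j];
        double Qoth = Qsum - t.Q, Coth = Csum - t.C;
        double dftot = (double)(K - (J + 1));
        const int np = (int)t.mem.size();
        // cache of the other-terminals contribution at the last tau2
        double cache_tau2 = -1.0, cache_qb = 0, cache_s0 = 0, cache_s1 = 0;
        for (int m = 0; m < M; ++m) {
          const double *xm = &X(0, m);
          Cand cc; cc.var = m; cc.kind = kind[m];
          for_candidates(t.mem, m, kind[m], d, v, X, minbucket,
            [&](double thresh, uint64_t lmask, int nl, int nr, double Ql,
                double Qr, double Cl, double Cr) {
              double Ctot = Coth + Cl + Cr;
              double tau2 = 0.0;
              if (Ctot > 0.0) {
                tau2 = (Qoth + Ql + Qr - dftot) / Ctot;
                if (tau2 < 0.0) tau2 = 0.0;
              }
              // whole-tree Q*_B for the candidate partition: sum of
              // s1^2/s0 over subgroups minus the grand-mean term,
              // accumulated group by group
              double qb = 0, stot = 0, sdtot = 0;
              if (tau2 == cache_tau2) {
                qb = cache_qb; stot = cache_s0; sdtot = cache_s1;
              } else {
                for (int oj = 0; oj < J; ++oj) {
                  if (oj == j) continue;
                  double s0 = 0, s1 = 0;
                  for (int k : terms[oj].mem) {
                    double w = 1.0 / (vv[k] + tau2);
                    s0 += w; s1 += w * dd[k];
                  }
                  qb += s1 * s1 / s0; stot += s0; sdtot += s1;
                }
                cache_tau2 = tau2; cache_qb = qb;
                cache_s0 = stot; cache_s1 = sdtot;
              }
              double l0 = 0, l1 = 0, r0 = 0, r1 = 0;
              if (kind[m] == 0) {
                for (int i = 0; i < np; ++i) {
                  int k = t.mem[i];
                  double w = 1.0 / (vv[k] + tau2), wd = w * dd[k];
                  if (xm[k] <= thresh) { l0 += w; l1 += wd; }
                  else { r0 += w; r1 += wd; }
                }
              } else {
                for (int i = 0; i < np; ++i) {
                  int k = t.mem[i];
                  double w = 1.0 / (vv[k] + tau2), wd = w * dd[k];
                  if ((lmask >> (int)xm[k]) & 1) { l0 += w; l1 += wd; }
                  else { r0 += w; r1 += wd; }
                }
              }
              qb += l1 * l1 / l0 + r1 * r1 / r0;
              stot += l0 + r0; sdtot += l1 + r1;
              qb -= sdtot * sdtot / stot;
              if (!have || qb > pickscore) {
                have = true; pick = j; pickscore = qb; picktau2 = tau2;
                cc.ok = true; cc.thresh = thresh; cc.lmask = lmask;
                cc.nl = nl; cc.nr = nr; pickc = cc;
              }
            });
        }
      }
    }

    if (!have) break;

    // perform the chosen split
    Term &p = terms[pick];
    Term left, right;
    left.id = 2 * p.id; right.id = 2 * p.id + 1;
    for (int k : p.mem)
      (goes_left(X, k, pickc) ? left.mem : right.mem).push_back(k);
    node_stats(left, d, v);
    node_stats(right, d, v);

    n_id.push_back(left.id); n_parent.push_back(p.id);
    n_n.push_back((int)left.mem.size()); n_Q.push_back(left.Q);
    n_mean.push_back(left.swd / left.sw); n_sw.push_back(left.sw);
    n_id.push_back(right.id); n_parent.push_back(p.id);
    n_n.push_back((int)right.mem.size()); n_Q.push_back(right.Q);
    n_mean.push_back(right.swd / right.sw); n_sw.push_back(right.sw);

    s_node.push_back(p.id); s_var.push_back(pickc.var + 1);
    s_kind.push_back(pickc.kind); s_thresh.push_back(pickc.thresh);
    s_nl.push_back((int)left.mem.size()); s_nr.push_back((int)right.mem.size());
    s_score.push_back(pickscore); s_tau2.push_back(re ? picktau2 : NA_REAL);
    std::vector<int> lv, rv;
    if (pickc.kind == 1) {
      for (int l = 0; l < 32; ++l) {
        bool inl = (pickc.lmask >> l) & 1;
        bool seen = false;
        for (int k : p.mem) if ((int)X(k, pickc.var) == l) { seen = true; break; }
        if (!seen) continue;
        (inl ? lv : rv).push_back(l);
      }
    }
    s_left.push_back(lv); s_right.push_back(rv);

    Qsum += left.Q + right.Q - p.Q;
    Csum += left.C + right.C - p.C;

    int newslot = (int)terms.size();
    for (int k : right.mem) gidx[k] = newslot;
    terms.push_back(right);
    terms[pick] = left; // left keeps parent's slot; gidx unchanged for left

    int S = (int)s_node.size();
    for (int k = 0; k < K; ++k)
      memb(k, S) = terms[gidx[k]].id;
  }

  int S = (int)s_node.size();
  IntegerMatrix membS(K, S + 1);
  for (int k = 0; k < K; ++k)
    for (int s = 0; s <= S; ++s) membS(k, s) = memb(k, s);

  List lefts(S), rights(S);
  for (int s = 0; s < S; ++s) {
    lefts[s] = wrap(s_left[s]);
    rights[s] = wrap(s_right[s]);
  }

  return List::create(
      _["node_id"] = wrap(n_id), _["node_parent"] = wrap(n_parent),
      _["node_n"] = wrap(n_n), _["node_Q"] = wrap(n_Q),
      _["node_mean"] = wrap(n_mean), _["node_sw"] = wrap(n_sw),
      _["split_node"] = wrap(s_node), _["split_var"] = wrap(s_var),
      _["split_kind"] = wrap(s_kind), _["split_thresh"] = wrap(s_thresh),
      _["split_left"] = lefts, _["split_right"] = rights,
      _["split_nl"] = wrap(s_nl), _["split_nr"] = wrap(s_nr),
      _["split_score"] = wrap(s_score), _["split_tau2"] = wrap(s_tau2),
      _["memb"] = membS);
}

// Route rows of X through (a subtree of) a grown tree.  Unseen nominal
// levels go to the child with more training studies, ties to the left.
// [[Rcpp::export]]
IntegerVector cpp_route(IntegerVector s_node, IntegerVector s_var,
                        IntegerVector s_kind, NumericVector s_thresh,
                        List s_left, List s_right, IntegerVector s_nl,
                        IntegerVector s_nr, NumericMatrix X) {
  const int n = X.nrow(), S = s_node.size();
  IntegerVector out(n);
  std::vector<std::vector<int>> lv(S), rv(S);
  for (int s = 0; s < S; ++s) {
    lv[s] = as<std::vector<int>>(s_left[s]);
    rv[s] = as<std::vector<int>>(s_right[s]);
  }
  for (int i = 0; i < n; ++i) {
    int node = 1;
    bool moved = true;
    while (moved) {
      moved = false;
      for (int s = 0; s < S; ++s) {
        if (s_node[s] != node) continue;
        bool left;
        int var = s_var[s] - 1;
        if (s_kind[s] == 0) {
          left = X(i, var) <= s_thresh[s];
        } else {
          int code = (int)X(i, var);
          bool inl = std::find(lv[s].begin(), lv[s].end(), code) != lv[s].end();
          bool inr = std::find(rv[s].begin(), rv[s].end(), code) != rv[s].end();
          if (inl) left = true;
          else if (inr) left = false;
          else left = s_nl[s] >= s_nr[s];
        }
        node = left ? 2 * node : 2 * node + 1;
        moved = true;
        break;
      }
    }
    out[i] = node;
  }
  return out;
}
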