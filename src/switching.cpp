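// Degree-preserving randomization of weighted graphs by weight transfer
// over two-edge switches.  Drives R's RNG so runs are reproducible under
// set.seed().

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

inline long long pair_key(int u, int v, int n) {
  if (u > v) std::swap(u, v);
  return static_cast<long long>(u) * n + v;
}

struct EdgeStore {
  int n;
  std::vector<int> eu, ev;
  std::vector<double> ew;
  std::unordered_map<long long, int> pos;

  EdgeStore(int n_, const IntegerMatrix& edges, const NumericVector& w)
      : n(n_) {
    int m = edges.nrow();
    eu.reserve(2 * m); ev.reserve(2 * m); ew.reserve(2 * m);
    pos.reserve(4 * m);
    for (int i = 0; i < m; ++i) {
      int u = edges(i, 0), v = edges(i, 1);
      if (u > v) std::swap(u, v);
      pos[pair_key(u, v, n)] = static_cast<int>(eu.size());
      eu.push_back(u); ev.push_back(v); ew.push_back(w[i]);
    }
  }

  int size() const { return static_cast<int>(eu.size()); }

  double weight_of(int u, int v) const {
    auto it = pos.find(pair_key(u, v, n));
    return it == pos.end() ? 0.0 : ew[it->second];
  }

  // set weight; <= 0 deletes the edge, absent edges are created
  void set_weight(int u, int v, double w) {
    long long k = pair_key(u, v, n);
    auto it = pos.find(k);
    if (it == pos.end()) {
      if (w > 0) {
        pos[k] = size();
        if (u > v) std::swap(u, v);
        eu.push_back(u); ev.push_back(v); ew.push_back(w);
      }
      return;
    }
    if (w > 0) {
      ew[it->second] = w;
      return;
    }
    // delete by swapping with the last edge
    int i = it->second, last = size() - 1;
    if (i != last) {
      eu[i] = eu[last]; ev[i] = ev[last]; ew[i] = ew[last];
      pos[pair_key(eu[i], ev[i], n)] = i;
    }
    eu.pop_back(); ev.pop_back(); ew.pop_back();
    pos.erase(k);
  }
};

inline int runif_int(int n) {           // uniform on 0..n-1
  int k = static_cast<int>(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

}  // namespace

// [[Rcpp::export]]
List rewire_core(int n, IntegerMatrix edges, NumericVector weights,
                 double n_proposals, int method, bool has_ub, double ub) {
  EdgeStore es(n, edges, weights);
  long long steps = static_cast<long long>(std::ceil(n_proposals));
  long long accepted = 0, discarded = 0;

  for (long long step = 0; step < steps; ++step) {
    int m = es.size();
    if (m < 2) continue;
    int i = runif_int(m);
    int j = runif_int(m - 1);
    if (j >= i) ++j;
    // endpoint roles randomized by a fair coin per edge
    int A, C, B, D;
    if (unif_rand() < 0.5) { A = es.eu[i]; C = es.ev[i]; }
    else                   { A = es.ev[i]; C = es.eu[i]; }
    if (unif_rand() < 0.5) { B = es.eu[j]; D = es.ev[j]; }
    else                   { B = es.ev[j]; D = es.eu[j]; }
    if (A == B || A == D || C == B || C == D) continue;  // share a vertex
    double wAC = es.ew[i], wBD = es.ew[j];
    double wAD = es.weight_of(A, D), wBC = es.weight_of(B, C);
    // transfer from heavy to weak edges only (strict)
    if (!(wAC > wAD && wBD > wBC)) continue;

    double wbar;
    if (method == 0) {  // max_weight: largest transfer keeping all in bounds
      wbar = std::min(wAC, wBD);
      if (has_ub) wbar = std::min(wbar, std::min(ub - wAD, ub - wBC));
      if (wbar <= 0) continue;
    } else {            // constant_variance (Eq.-6-type solution)
      wbar = 0.5 * (wAC + wBD - wAD - wBC);
      bool out = (wAC - wbar < 0) || (wBD - wbar < 0);
      if (has_ub && ((wAD + wbar > ub) || (wBC + wbar > ub))) out = true;
      if (out) { ++discarded; continue; }  // whole step discarded
    }
    double nAC = wAC - wbar, nBD = wBD - wbar;
    double nAD = wAD + wbar, nBC = wBC + wbar;
    es.set_weight(A, C, nAC);
    es.set_weight(B, D, nBD);
    es.set_weight(A, D, nAD);
    es.set_weight(B, C, nBC);
    ++accepted;
  }

  int m_out = es.size();
  IntegerMatrix out_edges(m_out, 2);
  NumericVector out_w(m_out);
  for (int i = 0; i < m_out; ++i) {
    out_edges(i, 0) = es.eu[i];
    out_edges(i, 1) = es.ev[i];
    out_w[i] = es.ew[i];
  }
  return List::create(_["edges"] = out_edges, _["weights"] = out_w,
                      _["proposals"] = static_cast<double>(steps),
                      _["accepted"] = static_cast<double>(accepted),
                      _["discarded"] = static_cast<double>(discarded));
}
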